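# Shared fixture builders. All fixtures are constructed in code.

# A dense climate series where every variable takes a constant value.
constant_series <- function(value = 10, years = 2000:2010) {
  tidyr::expand_grid(year = years, month = 1:12) |>
    dplyr::mutate(temperature = value, precipitation = abs(value),
                  runoff = abs(value))
}

# A series whose annual values follow var-specific linear trends, no
# seasonality; value depends on the year only.
trend_series <- function(years = 1990:2010, intercept = 10, slope = 0.1) {
  tidyr::expand_grid(year = years, month = 1:12) |>
    dplyr::mutate(temperature = intercept + slope * (year - years[1]),
                  precipitation = temperature + 20,
                  runoff = temperature + 5)
}

# A hand-built agent tibble; known histories default to empty.
make_population <- function(age, type = "alpha", t_tru = 1,
                            known_history = NULL) {
  n <- length(age)
  type <- rep_len(type, n)
  t_tru <- rep_len(t_tru, n)
  kh <- if (is.null(known_history)) rep(list(integer(0)), n) else known_history
  tibble::tibble(id = seq_len(n), age = as.integer(age),
                 age_class = age_class_of(age), type = type,
                 t_tru = t_tru, known_history = kh)
}

# Community in which every agent has lived through the whole record: used
# for the perfect-knowledge benchmark.
elder_community <- function(n = 20) {
  community_config(population_size = n,
                   age_class_proportions = c(Y = 0, M = 0, O = 1),
                   min_initial_age = 68, mortality_enabled = FALSE)
}

# Brute-force re-implementations used as oracles against the package's
# vectorized paths.
brute_recorded_change <- function(series, var, month, current_year, baseline_years) {
  vals <- vapply(baseline_years, function(y) {
    series[[var]][series$year == y & series$month == month]
  }, numeric(1))
  series[[var]][series$year == current_year & series$month == month] -
    sum(vals) / length(vals)
}

brute_community_perception <- function(p, w) {
  keep <- which(!is.na(p))
  if (length(keep) == 0) return(0)
  ws <- 0; acc <- 0
  for (i in keep) {
    ws <- ws + w[i]
    acc <- acc + w[i] * p[i]
  }
  if (ws > 0) acc / ws else mean(p[keep])
}

brute_lk_provider <- function(population, eligibility = "cardinality") {
  n <- nrow(population)
  metric <- vapply(population$known_history, function(h) {
    if (length(h) == 0) return(-1)
    if (eligibility == "cardinality") length(h) else max(h) - min(h)
  }, numeric(1))
  score <- population$age / max(population$age) * population$t_tru
  out <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    best <- NA_integer_
    for (j in seq_len(n)) {
      if (j == i || metric[j] <= metric[i]) next
      if (is.na(best) || score[j] > score[best] ||
          (score[j] == score[best] && population$id[j] < population$id[best])) {
        best <- j
      }
    }
    out[i] <- if (is.na(best)) NA_integer_ else population$id[best]
  }
  tibble::tibble(id = population$id, provider_id = out)
}

# sample() treats a length-1 numeric as 1:x; this never does.
resample <- function(x, size) x[sample.int(length(x), size)]
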