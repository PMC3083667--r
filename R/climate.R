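#' Configuration for the synthetic monthly climate generator
#'
#' Builds the per-variable settings used by [generate_synthetic_climate()].
#' Each variable is modelled as a linear trend in its annual mean, anchored so
#' that the noise-free 5-year annual means of the first and last five full
#' years equal `start_mean` and `end_mean`, plus a sinusoidal seasonal cycle
#' (period 12 months) and i.i.d. Gaussian noise. Flux variables
#' (precipitation, runoff) are clipped at zero after summing the components.
#'
#' The default calibration targets are endpoint 5-year means for a western
#' Alaska coastal site: temperature rising from -4.4 to 3.9 (degrees),
#' precipitation from 23.9 to 45.0 and runoff from 5.6 to 13.0 (depth per
#' month). Seasonal amplitudes and noise standard deviations are package
#' defaults chosen to give a realistic sub-arctic seasonal cycle and
#' inter-annual variability; all are overridable.
#'
#' @param variables A data frame with one row per climate variable and columns
#'   `variable`, `start_mean`, `end_mean`, `seasonal_amplitude`, `noise_sd`,
#'   `nonnegative`, `peak_month`. Defaults cover the three canonical
#'   variables.
#' @param start_year,end_year Calendar years spanned by the series (inclusive).
#'   Must satisfy `end_year - start_year >= 9` so that disjoint 5-year
#'   endpoint windows exist.
#' @param seed Integer seed making the generated series reproducible.
#' @return A list of class `climate_gen_config`.
#' @examples
#' cfg <- climate_gen_config(seed = 1)
#' series <- generate_synthetic_climate(cfg)
#' @export
climate_gen_config <- function(variables = default_climate_variables(),
                               start_year = 1960, end_year = 2090,
                               seed = 1L) {
  variables <- tibble::as_tibble(variables)
  required <- c("variable", "start_mean", "end_mean", "seasonal_amplitude",
                "noise_sd", "nonnegative", "peak_month")
  missing_cols <- setdiff(required, names(variables))
  if (length(missing_cols) > 0) {
    abort(paste0("climate variable table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!setequal(variables$variable, CLIMATE_VARIABLES)) {
    abort("climate variable table must contain exactly temperature, precipitation and runoff")
  }
  if (any(variables$noise_sd < 0)) abort("noise_sd must be >= 0")
  if (any(variables$seasonal_amplitude < 0)) abort("seasonal_amplitude must be >= 0")
  if (!all(variables$peak_month %in% 1:12)) abort("peak_month must be in 1..12")
  if (end_year < start_year + 9) {
    abort("end_year must be at least start_year + 9 to define 5-year endpoint means")
  }
  structure(
    list(variables = variables,
         start_year = as.integer(start_year),
         end_year = as.integer(end_year),
         seed = as.integer(seed)),
    class = "climate_gen_config"
  )
}

#' @rdname climate_gen_config
#' @export
default_climate_variables <- function() {
  tibble::tibble(
    variable = CLIMATE_VARIABLES,
    start_mean = c(-4.4, 23.9, 5.6),
    end_mean = c(3.9, 45.0, 13.0),
    seasonal_amplitude = c(15, 12, 5),
    noise_sd = c(2, 6, 2),
    nonnegative = c(FALSE, TRUE, TRUE),
    peak_month = c(7L, 8L, 6L)
  )
}

#' Generate a synthetic monthly climate series
#'
#' Produces a dense monthly table of temperature, precipitation and runoff
#' over the configured year range. For each variable the monthly value is
#' `trend(year) + amplitude * cos(2 * pi * (month - peak_month) / 12) + noise`,
#' where the trend is linear in the calendar year and anchored so that with
#' zero noise the annual means of the first and last five years average to
#' the configured `start_mean` and `end_mean` exactly. The seasonal term sums
#' to zero over any calendar year, so it does not perturb annual means.
#' Variables flagged `nonnegative` are clipped at zero after summing.
#'
#' The same configuration (including seed) always yields the identical series.
#'
#' @param cfg A [climate_gen_config()].
#' @return A tibble with columns `year`, `month`, `temperature`,
#'   `precipitation`, `runoff`; one row per (year, month).
#' @export
generate_synthetic_climate <- function(cfg) {
  stopifnot(inherits(cfg, "climate_gen_config"))
  years <- cfg$start_year:cfg$end_year
  grid <- tidyr::expand_grid(year = years, month = 1:12)
  n <- nrow(grid)
  # Annual-mean trend through the 5-year window centres: the mean of a linear
  # function over years y1..y1+4 equals its value at y1+2.
  c0 <- cfg$start_year + 2
  c1 <- cfg$end_year - 2
  out <- grid
  withr::with_seed(cfg$seed, {
    for (i in seq_len(nrow(cfg$variables))) {
      vr <- cfg$variables[i, ]
      slope <- (vr$end_mean - vr$start_mean) / (c1 - c0)
      trend <- vr$start_mean + slope * (grid$year - c0)
      seasonal <- vr$seasonal_amplitude *
        cos(2 * pi * (grid$month - vr$peak_month) / 12)
      noise <- if (vr$noise_sd > 0) rnorm(n, sd = vr$noise_sd) else numeric(n)
      vals <- trend + seasonal + noise
      if (vr$nonnegative) vals <- pmax(vals, 0)
      out[[vr$variable]] <- vals
    }
  })
  out
}

#' Validate a monthly climate series table
#'
#' Checks that a data frame is a dense monthly climate series: columns
#' `year`, `month`, `temperature`, `precipitation`, `runoff`, all numeric,
#' exactly one row per (year, month) with months 1..12 for every year in
#' range, and non-negative precipitation and runoff.
#'
#' @param series A data frame to validate.
#' @return The series as a tibble, ordered by year then month (invisibly
#'   usable in pipelines). Errors describe the first problem found, naming
#'   the first missing (year, month) cell if the grid has gaps.
#' @export
validate_climate_series <- function(series) {
  series <- tibble::as_tibble(series)
  required <- c("year", "month", CLIMATE_VARIABLES)
  missing_cols <- setdiff(required, names(series))
  if (length(missing_cols) > 0) {
    abort(paste0("climate table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  for (col in required) {
    if (!is.numeric(series[[col]])) {
      abort(paste0("climate table column '", col, "' is not numeric"))
    }
    if (anyNA(series[[col]])) {
      abort(paste0("climate table column '", col, "' contains missing values"))
    }
  }
  if (!all(series$month %in% 1:12)) abort("month values must be integers in 1..12")
  years <- seq(min(series$year), max(series$year))
  expected <- tidyr::expand_grid(year = years, month = 1:12)
  gaps <- anti_join(expected, series, by = c("year", "month"))
  if (nrow(gaps) > 0) {
    abort(sprintf("climate table is missing %d-%02d", gaps$year[1], gaps$month[1]))
  }
  if (nrow(series) != nrow(expected)) {
    abort("climate table has duplicate (year, month) rows")
  }
  if (any(series$precipitation < 0)) abort("precipitation must be >= 0")
  if (any(series$runoff < 0)) abort("runoff must be >= 0")
  arrange(series, .data$year, .data$month)
}

#' Read and write climate tables as CSV
#'
#' The on-disk format is a UTF-8 CSV with header
#' `year,month,temperature,precipitation,runoff` and one row per
#' (year, month). `load_climate_table()` validates density and numeric
#' content; `write_climate_table()` is its round-tripping counterpart.
#'
#' @param path Path to a CSV file.
#' @return `load_climate_table()` returns a validated climate tibble;
#'   `write_climate_table()` returns `path` invisibly.
#' @export
load_climate_table <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_double()))
  prob <- readr::problems(raw)
  if (nrow(prob) > 0) {
    abort(paste0("non-numeric or malformed cell in climate table at row ",
                 prob$row[1], ", column ", prob$col[1]))
  }
  validate_climate_series(raw)
}

#' @rdname load_climate_table
#' @param series A climate series data frame.
#' @export
write_climate_table <- function(series, path) {
  series <- validate_climate_series(series)
  readr::write_csv(series, path)
  invisible(path)
}

#' Historical mean of one variable for one calendar month
#'
#' The backward-looking average against which both agents and the recorded
#' change compare the current observation: the arithmetic mean of the
#' variable's value in the given calendar month over a set of years.
#'
#' @param series A climate series data frame.
#' @param var One of `"temperature"`, `"precipitation"`, `"runoff"`.
#' @param month Calendar month, 1..12.
#' @param years Integer vector of years to average over; must be nonempty and
#'   within the series range. An empty set raises a condition of class
#'   `tied_no_history`, which callers use to mark perceptions undefined.
#' @return The mean value (scalar).
#' @export
historical_monthly_mean <- function(series, var, month, years) {
  var <- match.arg(var, CLIMATE_VARIABLES)
  stopifnot(length(month) == 1, month %in% 1:12)
  if (length(years) == 0) {
    abort("no history: the year set is empty", class = "tied_no_history")
  }
  if (!all(years %in% series$year)) {
    abort("years outside the climate series range")
  }
  vals <- series[[var]][series$year %in% years & series$month == month]
  mean(vals)
}

#' Recorded change in a climate variable
#'
#' The "community truth" a perception is compared against: the difference
#' between the current month's value and the historical mean of that calendar
#' month over the baseline years. By default the baseline is every year in
#' the series strictly before `current_year`, so the baseline grows as the
#' simulation advances.
#'
#' @inheritParams historical_monthly_mean
#' @param current_year Year of the current observation; must be in the series.
#' @param baseline_years Years forming the baseline; defaults to all series
#'   years strictly before `current_year`.
#' @return The recorded change `q` (scalar).
#' @export
recorded_change <- function(series, var, month, current_year,
                            baseline_years = NULL) {
  var <- match.arg(var, CLIMATE_VARIABLES)
  if (!current_year %in% series$year) {
    abort("current_year is not in the climate series")
  }
  if (is.null(baseline_years)) {
    baseline_years <- unique(series$year[series$year < current_year])
  }
  current <- series[[var]][series$year == current_year & series$month == month]
  current - historical_monthly_mean(series, var, month, baseline_years)
}
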