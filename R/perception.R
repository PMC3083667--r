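#' Default perception and knowledge-transfer weight tables
#'
#' Two weighting schemes drive aggregation and transfer:
#'
#' * `w_p`, the influence an agent's perception carries in the community
#'   consensus, by age class and type. Older alpha agents carry full weight
#'   (1.0); younger gamma agents carry none (0.0).
#' * `w_k`, the fraction of knowledge passed from a provider to a recipient,
#'   by the two agents' types. Full knowledge passes between two alphas;
#'   a gamma provider transfers minimal knowledge; a gamma recipient receives
#'   none.
#'
#' @return A list with elements `w_p` (tibble: `age_class`, `type`, `weight`)
#'   and `w_k` (tibble: `recipient`, `provider`, `weight`).
#' @examples
#' default_weights()$w_p
#' @export
default_weights <- function() {
  list(
    w_p = tibble::tibble(
      age_class = rep(AGE_CLASSES, each = 3),
      type = rep(AGENT_TYPES, times = 3),
      weight = c(0.6, 0.3, 0.0,   # younger
                 0.8, 0.4, 0.1,   # middle-aged
                 1.0, 0.8, 0.7)   # older
    ),
    w_k = tibble::tibble(
      recipient = rep(AGENT_TYPES, each = 3),
      provider = rep(AGENT_TYPES, times = 3),
      weight = c(1.0, 0.8, 0.5,   # alpha recipient
                 0.8, 0.5, 0.3,   # beta recipient
                 0.0, 0.0, 0.0)   # gamma recipient
    )
  )
}

#' Influence weight of each agent on community perception
#'
#' Looks up `w_p` by (age class, type) for every agent.
#'
#' @param population Agent tibble.
#' @param weights Weight tables from [default_weights()] (overridable).
#' @return Numeric vector of weights aligned with the population rows.
#' @export
perception_weight <- function(population, weights = default_weights()) {
  key <- paste(population$age_class, population$type)
  tab <- weights$w_p
  idx <- match(key, paste(tab$age_class, tab$type))
  if (anyNA(idx)) abort("agent with unknown (age class, type) combination")
  tab$weight[idx]
}

#' Knowledge-transfer weight between agent types
#'
#' Looks up `w_k` by recipient and provider type (rows = recipient,
#' columns = provider in the canonical table).
#'
#' @param recipient_type,provider_type Character vectors of agent types.
#' @param weights Weight tables from [default_weights()].
#' @return Numeric vector of transfer weights.
#' @export
knowledge_transfer_weight <- function(recipient_type, provider_type,
                                      weights = default_weights()) {
  tab <- weights$w_k
  idx <- match(paste(recipient_type, provider_type),
               paste(tab$recipient, tab$provider))
  if (anyNA(idx)) abort("unknown agent type")
  tab$weight[idx]
}

#' Build an agent's known history of experienced years
#'
#' An agent can only have experienced years since it turned 18 that fall in
#' the climate record: candidates are years `y` with
#' `current_year - y <= age - 18`, `y >= series_start` and `y < current_year`.
#' Each candidate is admitted if the agent's engagement fraction exceeds an
#' independent Uniform\[0, 1) draw, so agents who engage more with
#' traditional resources accumulate more complete histories. Once admitted a
#' year is remembered permanently.
#'
#' This function performs the initial build for a whole population (one draw
#' per agent-candidate pair, agents processed in row order);
#' [extend_known_history()] performs the single-year annual extension.
#'
#' @param population Agent tibble.
#' @param current_year The simulation year at which histories are built.
#' @param series_start First year of the climate record.
#' @return The population with the `known_history` list-column filled.
#' @export
build_known_history <- function(population, current_year, series_start) {
  population$known_history <- lapply(seq_len(nrow(population)), function(i) {
    first <- max(series_start, current_year - (population$age[i] - 18L))
    if (first > current_year - 1L) return(integer(0))
    cand <- first:(current_year - 1L)
    cand[population$t_tru[i] > runif(length(cand))]
  })
  population
}

#' @rdname build_known_history
#' @description `extend_known_history()` tests the single newly eligible
#'   candidate year (the year just completed) for every agent old enough to
#'   have experienced it, admitting it with the agent's current engagement
#'   fraction; previously admitted years are untouched.
#' @export
extend_known_history <- function(population, current_year) {
  eligible <- population$age >= 19L
  n <- sum(eligible)
  if (n == 0) return(population)
  delta <- runif(n)
  admit <- population$t_tru[eligible] > delta
  idx <- which(eligible)[admit]
  population$known_history[idx] <- lapply(population$known_history[idx],
                                          function(h) c(h, current_year - 1L))
  population
}

#' Individual perception of change in a climate variable
#'
#' Each agent compares the current month's observation (available to every
#' agent) with the mean of that calendar month over the years in its known
#' history. Agents with an empty history have no defined perception.
#'
#' @param population Agent tibble with `known_history` filled.
#' @param series Climate series data frame.
#' @param var One of the three climate variables.
#' @param month Calendar month 1..12.
#' @param current_year Year of the current observation.
#' @return A tibble with columns `id`, `variable`, `year`, `month`, `p`,
#'   `defined`; `p` is `NA` where undefined.
#' @export
individual_perception <- function(population, series, var, month, current_year) {
  var <- match.arg(var, CLIMATE_VARIABLES)
  current <- series[[var]][series$year == current_year & series$month == month]
  if (length(current) != 1) abort("current (year, month) not in the climate series")
  month_vals <- series[series$month == month, ]
  p <- vapply(population$known_history, function(h) {
    if (length(h) == 0) return(NA_real_)
    current - mean(month_vals[[var]][match(h, month_vals$year)])
  }, numeric(1))
  tibble::tibble(
    id = population$id,
    variable = var,
    year = as.integer(current_year),
    month = as.integer(month),
    p = p,
    defined = !is.na(p)
  )
}

# Shared provider-selection core. metric: per-agent history extent (count or
# span); score: (age / eldest age) * t_tru. For each agent, the provider is
# the highest-scoring other agent whose metric strictly exceeds its own
# (ties broken by smallest id); 0 when no agent qualifies.
lk_provider_index <- function(metric, score, id) {
  n <- length(metric)
  prov <- integer(n)
  ord <- order(metric, decreasing = TRUE)
  best <- 0L
  i <- 1L
  while (i <= n) {
    m <- metric[ord[i]]
    j <- i
    while (j <= n && metric[ord[j]] == m) j <- j + 1L
    grp <- ord[i:(j - 1L)]
    prov[grp] <- best
    for (k in grp) {
      if (best == 0L || score[k] > score[best] ||
          (score[k] == score[best] && id[k] < id[best])) {
        best <- k
      }
    }
    i <- j
  }
  prov
}

#' Select each agent's local-knowledge provider
#'
#' An agent only seeks knowledge from someone whose historical record covers
#' a longer time period than its own. Among those candidates the provider is
#' the agent maximising `(age / eldest age) x t_tru` — experience defined
#' jointly by age and engagement with traditional resources. Ties go to the
#' smallest agent id; an agent whose own record is unsurpassed gets no
#' provider.
#'
#' @param population Agent tibble with `known_history` filled.
#' @param eligibility How "longer time period" is measured: `"cardinality"`
#'   (number of known years, the default) or `"span"` (last minus first known
#'   year).
#' @return A tibble with columns `id` and `provider_id` (`NA` when no
#'   provider qualifies).
#' @export
select_lk_provider <- function(population, eligibility = c("cardinality", "span")) {
  eligibility <- match.arg(eligibility)
  metric <- vapply(population$known_history, function(h) {
    if (length(h) == 0) return(-1)
    if (eligibility == "cardinality") length(h) else max(h) - min(h)
  }, numeric(1))
  score <- (population$age / max(population$age)) * population$t_tru
  prov <- lk_provider_index(metric, score, population$id)
  provider_id <- rep(NA_integer_, nrow(population))
  provider_id[prov > 0L] <- population$id[prov[prov > 0L]]
  tibble::tibble(id = population$id, provider_id = provider_id)
}

#' Acquire years of knowledge from each agent's provider
#'
#' The persistent half of local-knowledge transfer: once per simulated year,
#' each agent that has a provider may adopt years from the provider's known
#' history that are missing from its own. Each missing year is acquired
#' independently with probability equal to the type-dependent transfer
#' weight, so two alpha agents (`w_k = 1`) share knowledge fully while a
#' gamma recipient (`w_k = 0`) acquires nothing. Acquisition is simultaneous
#' across the population — every transfer reads the histories as they stood
#' before this round — and acquired years are retained permanently, which is
#' how knowledge of the early record outlives the agents who experienced it.
#'
#' @param population Agent tibble with `known_history` filled.
#' @param providers Provider assignment from [select_lk_provider()].
#' @param weights Weight tables from [default_weights()].
#' @return The population with extended `known_history`.
#' @export
acquire_knowledge <- function(population, providers, weights = default_weights()) {
  prov_idx <- match(providers$provider_id, population$id)
  snapshot <- population$known_history
  for (i in seq_len(nrow(population))) {
    j <- prov_idx[i]
    if (is.na(j)) next
    w <- knowledge_transfer_weight(population$type[i], population$type[j], weights)
    if (w <= 0) next
    missing <- setdiff(snapshot[[j]], snapshot[[i]])
    if (length(missing) == 0) next
    gained <- missing[runif(length(missing)) < w]
    if (length(gained) > 0) {
      population$known_history[[i]] <- c(population$known_history[[i]], gained)
    }
  }
  population
}

#' Blend a perception with a provider's perception
#'
#' Convex combination of the recipient's own perception and the provider's,
#' weighted by the type-dependent transfer weight:
#' `p' = w_k * p_provider + (1 - w_k) * p_own`. A recipient without a defined
#' perception of its own adopts `w_k * p_provider`, gaining a defined
#' perception whenever `w_k > 0`. With `w_k = 0` (any gamma recipient) the
#' own record is returned unchanged.
#'
#' @param own_p,provider_p Numeric vectors of perceptions; `own_p` may be
#'   `NA` (undefined), `provider_p` must not be.
#' @param w_k Transfer weights in \[0, 1\].
#' @return A list with numeric `p` and logical `defined`.
#' @export
apply_knowledge_transfer <- function(own_p, provider_p, w_k) {
  if (anyNA(provider_p)) abort("provider perception must be defined")
  own_defined <- !is.na(own_p)
  p <- ifelse(own_defined,
              w_k * provider_p + (1 - w_k) * own_p,
              w_k * provider_p)
  defined <- own_defined | w_k > 0
  p[!defined] <- NA_real_
  list(p = p, defined = defined)
}

#' Community perception as a weighted consensus
#'
#' The community's perception of change is the influence-weighted mean of the
#' defined individual perceptions, `sum(w_i p_i) / sum(w_i)`. If every
#' participating weight is zero the unweighted mean of defined perceptions is
#' used; if no perception is defined the result is 0 and flagged degenerate
#' (attribute `degenerate`).
#'
#' @param p Numeric vector of perceptions (`NA` = undefined).
#' @param w Numeric vector of influence weights, same length as `p`.
#' @return Scalar community perception with logical attribute `degenerate`.
#' @export
community_perception <- function(p, w) {
  if (length(p) != length(w)) abort("perceptions and weights must align")
  defined <- !is.na(p)
  if (!any(defined)) {
    return(structure(0, degenerate = TRUE))
  }
  wsum <- sum(w[defined])
  val <- if (wsum > 0) {
    sum(w[defined] * p[defined]) / wsum
  } else {
    mean(p[defined])
  }
  structure(val, degenerate = FALSE)
}

#' Community vulnerability to change in a climate variable
#'
#' The discrepancy between recorded and perceived change, `v = q - P_c`;
#' larger magnitudes mean the community's perception departs further from
#' what is actually occurring.
#'
#' @param q Recorded change (numeric vector).
#' @param P_c Community perception (numeric vector).
#' @return A tibble with columns `v` and `v_abs`.
#' @export
vulnerability <- function(q, P_c) {
  v <- q - P_c
  tibble::tibble(v = v, v_abs = abs(v))
}
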