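#' Age class of an agent
#'
#' Agents aged 18-39 are younger (`Y`), 40-59 middle-aged (`M`) and 60 or
#' older (`O`). Age 60 belongs to `O` so the classes partition all ages >= 18.
#'
#' @param age Integer vector of ages; all must be >= 18.
#' @return Character vector of `"Y"`, `"M"`, `"O"`.
#' @export
age_class_of <- function(age) {
  if (any(age < 18)) abort("agents must be at least 18 years old")
  ifelse(age <= 39, "Y", ifelse(age <= 59, "M", "O"))
}

#' Community configuration
#'
#' Describes the agent population: its size, the mix of agent types
#' (alpha initiators, beta concerned non-initiators, gamma self-serving), the
#' age structure, and the mortality model. Mortality follows
#' `m = (age / max_age)^exponent` where `max_age` is the age of the current
#' eldest agent and the exponent defaults to Euler's number, so the eldest
#' agent dies with probability 1 at each annual update.
#'
#' Type and age-class proportions default to a plausible small remote
#' community; the published site demographics are not available numerically,
#' so both are configurable.
#'
#' @param population_size Number of agents (> 0); community sizes around
#'   150-270 are typical for the study setting.
#' @param type_proportions Named numeric vector over `alpha`, `beta`, `gamma`
#'   summing to 1.
#' @param age_class_proportions Named numeric vector over `Y`, `M`, `O`
#'   summing to 1. Ages are drawn uniformly within each class
#'   (Y: 18-39, M: 40-59, O: 60-`max_initial_age`).
#' @param max_initial_age Upper bound for initial ages in the `O` class.
#' @param min_initial_age Optional raised lower bound for initial ages in
#'   every class (classes whose range empties must carry no mass). Used e.g.
#'   for the perfect-knowledge benchmark, where every agent must be old
#'   enough to have experienced the whole climate record.
#' @param mortality_exponent Exponent of the mortality curve; default `exp(1)`.
#' @param mortality_enabled Set `FALSE` to freeze the population (used for the
#'   perfect-knowledge benchmark).
#' @param seed Optional integer seed for [initialize_community()];
#'   `NULL` uses the current RNG stream.
#' @return A list of class `community_config`.
#' @export
community_config <- function(population_size = 152,
                             type_proportions = c(alpha = 0.35, beta = 0.45, gamma = 0.20),
                             age_class_proportions = c(Y = 0.45, M = 0.35, O = 0.20),
                             max_initial_age = 80,
                             min_initial_age = 18,
                             mortality_exponent = exp(1),
                             mortality_enabled = TRUE,
                             seed = NULL) {
  if (population_size <= 0) abort("population_size must be positive")
  check_proportions <- function(p, names_expected, what) {
    if (!setequal(names(p), names_expected)) {
      abort(paste0(what, " must be named over ", paste(names_expected, collapse = ", ")))
    }
    p <- p[names_expected]
    if (any(p < 0)) abort(paste0(what, " must be non-negative"))
    if (abs(sum(p) - 1) > 1e-9) abort(paste0(what, " must sum to 1"))
    if (all(p == 0)) abort(paste0(what, " places no mass anywhere"))
    p
  }
  type_proportions <- check_proportions(type_proportions, AGENT_TYPES, "type_proportions")
  age_class_proportions <- check_proportions(age_class_proportions, AGE_CLASSES,
                                             "age_class_proportions")
  if (max_initial_age < 60) abort("max_initial_age must be at least 60")
  if (mortality_exponent <= 0) abort("mortality_exponent must be positive")
  if (min_initial_age < 18) abort("min_initial_age must be at least 18")
  class_hi <- c(Y = 39, M = 59, O = max_initial_age)
  empty <- class_hi < min_initial_age & age_class_proportions > 0
  if (any(empty)) {
    abort(paste0("min_initial_age empties age class(es) with positive mass: ",
                 paste(names(class_hi)[empty], collapse = ", ")))
  }
  structure(
    list(population_size = as.integer(population_size),
         type_proportions = type_proportions,
         age_class_proportions = age_class_proportions,
         max_initial_age = as.integer(max_initial_age),
         min_initial_age = as.integer(min_initial_age),
         mortality_exponent = mortality_exponent,
         mortality_enabled = isTRUE(mortality_enabled),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "community_config"
  )
}

#' Initialize the agent population
#'
#' Draws `population_size` agents with types from `type_proportions`, age
#' classes from `age_class_proportions`, integer ages uniform within class,
#' and each agent's traditional-resource-use fraction set to the scenario's
#' initial value for its class. Known histories start empty; they are filled
#' by [build_known_history()] at the first simulated step.
#'
#' @param cfg A [community_config()].
#' @param sc A scenario tibble from [scenario()].
#' @return A tibble of agents with columns `id`, `age`, `age_class`, `type`,
#'   `t_tru` and the list-column `known_history`.
#' @export
initialize_community <- function(cfg, sc) {
  stopifnot(inherits(cfg, "community_config"))
  draw <- function() {
    n <- cfg$population_size
    type <- sample(AGENT_TYPES, n, replace = TRUE, prob = cfg$type_proportions)
    cls <- sample(AGE_CLASSES, n, replace = TRUE, prob = cfg$age_class_proportions)
    lo <- pmax(c(Y = 18L, M = 40L, O = 60L)[cls], cfg$min_initial_age)
    hi <- c(Y = 39L, M = 59L, O = cfg$max_initial_age)[cls]
    age <- lo + floor(runif(n) * (hi - lo + 1L))
    tibble::tibble(
      id = seq_len(n),
      age = as.integer(age),
      age_class = age_class_of(age),
      type = type,
      t_tru = scheduled_tru(sc, age_class_of(age), 0),
      known_history = rep(list(integer(0)), n)
    )
  }
  if (is.null(cfg$seed)) draw() else withr::with_seed(cfg$seed, draw())
}

#' Annual mortality probability
#'
#' `m = (age / max_age)^exponent`: mortality rises with age relative to the
#' community's current eldest member, who dies with certainty. Applied once
#' every twelve simulated months.
#'
#' @param age Integer vector of ages, each between 18 and `max_age`.
#' @param max_age Age of the eldest agent in the community.
#' @param exponent Positive exponent; default Euler's number.
#' @return Probabilities in \[0, 1\].
#' @export
mortality_probability <- function(age, max_age, exponent = exp(1)) {
  if (any(age < 18)) abort("age must be >= 18")
  if (any(age > max_age)) abort("max_age must be at least every agent's age")
  if (exponent <= 0) abort("exponent must be positive")
  (age / max_age)^exponent
}

#' Annual decline in traditional resource use
#'
#' Engagement with traditional resources is a property of the age class:
#' each scenario prescribes, per class, an initial fraction and an annual
#' decline in percentage points, and every agent currently in a class takes
#' the class's scheduled value. After `years_elapsed` simulated years an
#' agent's engagement is therefore
#' `clamp(initial_tru - years_elapsed * annual_change / 100, 0, 1)` for its
#' current class — for an agent that stays in one class this is exactly one
#' percentage-point decrement per year.
#'
#' @param population Agent tibble.
#' @param sc A scenario tibble from [scenario()].
#' @param years_elapsed Whole years since the simulation start.
#' @return The population with updated `t_tru`.
#' @export
update_tru <- function(population, sc, years_elapsed = 1) {
  population$t_tru <- scheduled_tru(sc, population$age_class, years_elapsed)
  population
}

#' Annual demographic update
#'
#' One year of population turnover, in a fixed order: (1) every agent ages by
#' one year and age classes are refreshed; (2) if a scenario is supplied, the
#' scenario's annual decline in traditional resource use is applied; (3) each
#' agent dies independently with probability
#' `(age / max_age)^exponent`, the eldest age evaluated once before any death;
#' (4) each deceased agent is replaced by an 18-year-old of the same type
#' (the newcomer inherits the family's behavioural traits) whose engagement
#' fraction is the mean over surviving younger-class agents — or, if no
#' younger agent survives, the scenario's currently scheduled younger-class
#' value — and whose known history is empty. Population size never changes.
#'
#' @param population Agent tibble.
#' @param cfg A [community_config()] supplying the mortality model.
#' @param sc Optional scenario tibble; when given, the annual
#'   traditional-resource-use decline is applied between aging and mortality.
#' @param years_elapsed Whole years since simulation start *after* this
#'   update; used only for the scheduled fallback engagement value.
#' @return The updated population tibble (same number of rows).
#' @export
annual_demographic_update <- function(population, cfg, sc = NULL,
                                      years_elapsed = 0) {
  stopifnot(inherits(cfg, "community_config"), nrow(population) > 0)
  population$age <- population$age + 1L
  population$age_class <- age_class_of(population$age)
  if (!is.null(sc)) population <- update_tru(population, sc, years_elapsed)
  eldest <- max(population$age)
  if (cfg$mortality_enabled) {
    m <- mortality_probability(population$age, eldest, cfg$mortality_exponent)
    dead <- runif(nrow(population)) < m
  } else {
    dead <- rep(FALSE, nrow(population))
  }
  if (any(dead)) {
    young_survivors <- !dead & population$age_class == "Y"
    replacement_tru <- if (any(young_survivors)) {
      mean(population$t_tru[young_survivors])
    } else if (!is.null(sc)) {
      scheduled_tru(sc, "Y", years_elapsed)
    } else {
      mean(population$t_tru[!dead])
    }
    population$age[dead] <- 18L
    population$age_class[dead] <- "Y"
    population$t_tru[dead] <- replacement_tru
    population$known_history[dead] <- list(integer(0))
  }
  population
}
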