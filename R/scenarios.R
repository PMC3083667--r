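#' Scenarios of engagement with non-municipal water systems
#'
#' Six prescribed trajectories of per-age-class engagement with traditional
#' (non-municipal) water systems, expressed as the initial fraction of time
#' spent in traditional resource use (`initial_tru`) and an annual decline in
#' percentage points (`annual_change`):
#'
#' * **A** perfect knowledge: full engagement, no decline.
#' * **B** traditional resource use by all agents: near-full engagement, no
#'   decline.
#' * **C** diminishing use by younger agents (fast) and middle-aged agents
#'   (slow).
#' * **D** diminishing use by older agents (fast) and middle-aged agents
#'   (slow); younger agents retain full engagement.
#' * **E** gradual decline by all classes, rate depending on age.
#' * **F** rapid decline by all classes.
#'
#' Declines apply to every listed class; engagement is clamped to \[0, 1\].
#'
#' @param id Scenario identifier, one of `"A"`..`"F"`, or a data frame with
#'   columns `scenario`, `age_class`, `initial_tru`, `annual_change` to use a
#'   custom scenario directly.
#' @return A tibble with one row per age class and columns `scenario`,
#'   `age_class`, `initial_tru`, `annual_change`.
#' @examples
#' scenario("C")
#' @export
scenario <- function(id) {
  if (is.data.frame(id)) {
    sc <- tibble::as_tibble(id)
    required <- c("scenario", "age_class", "initial_tru", "annual_change")
    if (!all(required %in% names(sc))) {
      abort("a custom scenario needs columns scenario, age_class, initial_tru, annual_change")
    }
    if (!setequal(sc$age_class, AGE_CLASSES)) {
      abort("a scenario must define exactly the age classes Y, M, O")
    }
    if (any(sc$initial_tru < 0 | sc$initial_tru > 1)) {
      abort("initial_tru must lie in [0, 1]")
    }
    return(sc)
  }
  if (!is.character(id) || length(id) != 1 || !id %in% LETTERS[1:6]) {
    abort("unknown scenario id: expected one of A, B, C, D, E, F")
  }
  filter(default_scenarios(), .data$scenario == id)
}

#' @rdname scenario
#' @export
default_scenarios <- function() {
  tibble::tibble(
    scenario = rep(LETTERS[1:6], each = 3),
    age_class = rep(AGE_CLASSES, times = 6),
    initial_tru = c(1, 1, 1, rep(0.95, 15)),
    annual_change = c(0, 0, 0,      # A
                      0, 0, 0,      # B
                      5, 1, 0,      # C
                      0, 1, 5,      # D
                      4, 2.5, 1,    # E
                      15, 10, 5)    # F
  )
}

#' Scheduled traditional-resource-use fraction under a scenario
#'
#' The deterministic engagement fraction a scenario prescribes for an age
#' class after a number of simulated years: the initial value minus
#' `years_elapsed` annual percentage-point declines, clamped to \[0, 1\].
#'
#' @param sc A scenario tibble from [scenario()].
#' @param age_class Vector of age classes (`"Y"`, `"M"`, `"O"`).
#' @param years_elapsed Whole years since the simulation start.
#' @return Numeric vector of engagement fractions.
#' @export
scheduled_tru <- function(sc, age_class, years_elapsed) {
  idx <- match(age_class, sc$age_class)
  if (anyNA(idx)) abort("unknown age class")
  pmin(pmax(sc$initial_tru[idx] - years_elapsed * sc$annual_change[idx] / 100, 0), 1)
}
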