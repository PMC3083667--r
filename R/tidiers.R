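#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a simulation result
#'
#' `tidy()` returns the long per-step table as a plain tibble; `glance()`
#' condenses a result to one row of run-level summaries, including the mean
#' vulnerability magnitude over all steps and over the final simulated
#' decade (where long-run misperception is judged).
#'
#' @param x A `tied_run` or `tied_avg` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy tied_run
#' @export
tidy.tied_run <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.tied_run
#' @method tidy tied_avg
#' @export
tidy.tied_avg <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.tied_run
#' @method glance tied_run
#' @export
glance.tied_run <- function(x, ...) {
  meta <- attr(x, "meta")
  final <- filter(x, .data$year > max(.data$year) - 10)
  tibble::tibble(
    scenario = x$scenario[1],
    lk = x$lk[1],
    seed = meta$seed %||% NA_integer_,
    n_steps = length(unique(paste(x$year, x$month))),
    mean_abs_v = mean(x$v_abs),
    final_decade_mean_abs_v = mean(final$v_abs)
  )
}

#' @rdname tidy.tied_run
#' @method glance tied_avg
#' @export
glance.tied_avg <- function(x, ...) {
  final <- filter(x, .data$year > max(.data$year) - 10)
  tibble::tibble(
    scenario = x$scenario[1],
    lk = x$lk[1],
    n_replicates = x$n_replicates[1],
    n_steps = length(unique(paste(x$year, x$month))),
    mean_abs_v = mean(x$mean_v_abs),
    final_decade_mean_abs_v = mean(final$mean_v_abs)
  )
}

#' Final-decade mean vulnerability magnitude per variable
#'
#' The summary used to compare scenarios: the mean of the (replicate-mean)
#' absolute vulnerability over the last ten simulated years, per climate
#' variable.
#'
#' @param result A `tied_run` or `tied_avg` tibble.
#' @return A tibble with columns `variable` and `final_decade_mean_abs_v`.
#' @export
final_decade_summary <- function(result) {
  col <- if ("mean_v_abs" %in% names(result)) "mean_v_abs" else "v_abs"
  result %>%
    filter(.data$year > max(.data$year) - 10) %>%
    group_by(.data$variable) %>%
    summarise(final_decade_mean_abs_v = mean(.data[[col]]), .groups = "drop")
}
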