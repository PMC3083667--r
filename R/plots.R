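#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_ribbon facet_wrap
#'   labs theme_minimal
#' @export
ggplot2::autoplot

# Decimal time axis from (year, month): mid-month position.
decimal_year <- function(year, month) year + (month - 0.5) / 12

#' Plot vulnerability trajectories
#'
#' `autoplot()` on a single run draws the signed vulnerability over time,
#' one panel per climate variable; on an averaged result it draws the
#' replicate mean with a +/- 1 sd ribbon.
#'
#' @param object A `tied_run` or `tied_avg` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tied_run
#' @export
autoplot.tied_run <- function(object, ...) {
  df <- mutate(tibble::as_tibble(object),
               time = decimal_year(.data$year, .data$month))
  ggplot(df, aes(x = .data$time, y = .data$v)) +
    geom_line(linewidth = 0.3, colour = "grey30") +
    facet_wrap(~variable, ncol = 1, scales = "free_y") +
    labs(x = "year", y = "vulnerability (recorded minus perceived change)",
         title = sprintf("Scenario %s, local knowledge %s",
                         object$scenario[1],
                         if (object$lk[1]) "on" else "off")) +
    theme_minimal()
}

#' @rdname autoplot.tied_run
#' @method autoplot tied_avg
#' @export
autoplot.tied_avg <- function(object, ...) {
  df <- mutate(tibble::as_tibble(object),
               time = decimal_year(.data$year, .data$month))
  ggplot(df, aes(x = .data$time, y = .data$mean_v)) +
    geom_ribbon(aes(ymin = .data$mean_v - .data$sd_v,
                    ymax = .data$mean_v + .data$sd_v),
                fill = "grey80") +
    geom_line(linewidth = 0.3, colour = "grey20") +
    facet_wrap(~variable, ncol = 1, scales = "free_y") +
    labs(x = "year",
         y = "replicate-mean vulnerability (+/- 1 sd)",
         title = sprintf("Scenario %s, local knowledge %s, %d replicates",
                         object$scenario[1],
                         if (object$lk[1]) "on" else "off",
                         object$n_replicates[1])) +
    theme_minimal()
}

#' Plot a monthly climate series
#'
#' Monthly values with the annual mean overlaid, one panel per variable —
#' a quick check that a generated forcing has the intended trend and
#' seasonal structure.
#'
#' @param series A climate series data frame.
#' @return A ggplot object.
#' @export
plot_climate <- function(series) {
  series <- validate_climate_series(series)
  long <- tidyr::pivot_longer(series, dplyr::all_of(CLIMATE_VARIABLES),
                              names_to = "variable", values_to = "value")
  annual <- long %>%
    group_by(.data$variable, .data$year) %>%
    summarise(value = mean(.data$value), .groups = "drop")
  ggplot(mutate(long, time = decimal_year(.data$year, .data$month)),
         aes(x = .data$time, y = .data$value)) +
    geom_line(colour = "grey75", linewidth = 0.2) +
    geom_line(data = mutate(annual, time = .data$year + 0.5),
              colour = "grey10", linewidth = 0.5) +
    facet_wrap(~variable, ncol = 1, scales = "free_y") +
    labs(x = "year", y = "monthly value (annual mean overlaid)") +
    theme_minimal()
}
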