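#' Plot a simulated trajectory
#'
#' Per-type population densities through time on a log10 axis, the standard
#' way the ten-year iterations are displayed.
#'
#' @param object A `symbiont_traj` from [simulate_symbionts()].
#' @param log10 Use a log10 density axis (default `TRUE`; rare types span
#'   many orders of magnitude).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.symbiont_traj <- function(object, log10 = TRUE, ...) {
  d <- tidy.symbiont_traj(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$day, y = .data$density,
                                       colour = .data$type)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "day", y = expression(density ~ (cells ~ cm^-2)),
                  colour = "type") +
    ggplot2::theme_minimal()
  if (log10) p <- p + ggplot2::scale_y_log10()
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the seasonal drivers of a site
#'
#' @param forcings A [site_forcings()] pair.
#' @param days Days to evaluate (default one model year).
#' @param anomaly Optional [anomaly_schedule()] overlaid on SST.
#' @return A ggplot object, SI and SST in facets with free y scales.
#' @export
plot_forcings <- function(forcings, days = 0:360, anomaly = NULL) {
  d <- dplyr::bind_rows(
    tibble::tibble(day = days, driver = "SI (kW m-2 d-1)",
                   value = eval_forcing(forcings$si, days)),
    tibble::tibble(day = days, driver = "SST (degC)",
                   value = eval_sst(forcings$sst, days, anomaly)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$day, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~driver, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "day", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a shuffle report
#'
#' Change in ensemble-median relative abundance per type between the
#' baseline and warmed scenarios, with the detectability threshold marked.
#'
#' @param object A `shuffle_report` from [compare_scenarios()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.shuffle_report <- function(object, ...) {
  d <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), "type",
                  "rel_abund_baseline", "rel_abund_warmed"),
    -"type", names_to = "scenario", values_to = "rel_abund",
    names_prefix = "rel_abund_")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$type, y = .data$rel_abund,
                                  fill = .data$scenario)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = attr(object, "detect_threshold"),
                        linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "median relative abundance (final year)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
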