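#' Plot methods for pipeline result tables
#'
#' `autoplot()` methods give quick-look figures for the main result types:
#' mixed-layer depth and metalimnion envelope over time (`strat_summary`),
#' attenuation and intrinsic irradiance depths (`light_summary`),
#' whole-lake population mass (`population_series`), daily flux components
#' (`flux_series`) and seasonal anomalies (`seasonal_anomaly`). Depth axes
#' are reversed so the surface is on top.
#'
#' @param object a result tibble from the pipeline.
#' @param ... unused.
#' @return a ggplot object.
#' @name limnobloom-autoplot
NULL

#' @rdname limnobloom-autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.strat_summary <- function(object, ...) {
  ggplot(object, aes(x = .data$timestamp)) +
    geom_ribbon(
      data = ~ dplyr::filter(.x, .data$metalimnion_valid),
      aes(ymin = .data$metalimnion_lower, ymax = .data$metalimnion_upper),
      fill = "grey70", alpha = 0.6
    ) +
    geom_line(aes(y = .data$z_mix), colour = "black") +
    scale_y_reverse() +
    labs(x = NULL, y = "Depth (m)",
         title = "Mixed-layer depth and metalimnion envelope")
}

#' @rdname limnobloom-autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.light_summary <- function(object, ...) {
  long <- object %>%
    select("timestamp", "z_comp", "z_buoy", "z_sat", "z_eu") %>%
    tidyr::pivot_longer(-"timestamp", names_to = "depth_type",
                        values_to = "depth_m")
  ggplot(long, aes(x = .data$timestamp, y = .data$depth_m,
                   colour = .data$depth_type)) +
    geom_line(na.rm = TRUE) +
    scale_y_reverse() +
    labs(x = NULL, y = "Depth (m)", colour = NULL,
         title = "Euphotic and species-intrinsic irradiance depths")
}

#' @rdname limnobloom-autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.population_series <- function(object, ...) {
  ggplot(object, aes(x = .data$timestamp, y = .data$total_tons)) +
    geom_line() +
    geom_point(data = ~ dplyr::filter(.x, .data$below_detection),
               colour = "red", size = 1) +
    labs(x = NULL, y = "Population (t chlorophyll a)",
         title = "Whole-lake depth-integrated population")
}

#' @rdname limnobloom-autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.flux_series <- function(object, ...) {
  long <- object %>%
    select("date", "q_sw_net", "q_lw_in", "q_lw_out", "q_latent",
           "q_sensible", "q_net") %>%
    tidyr::pivot_longer(-"date", names_to = "component",
                        values_to = "flux_wm2")
  ggplot(long, aes(x = .data$date, y = .data$flux_wm2,
                   colour = .data$component)) +
    geom_line(alpha = 0.8) +
    labs(x = NULL, y = expression(W ~ m^-2), colour = NULL,
         title = "Surface heat-flux components (positive = lake heat gain)")
}

#' @rdname limnobloom-autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.seasonal_anomaly <- function(object, ...) {
  ggplot(object, aes(x = .data$year, y = .data$anomaly,
                     fill = .data$flagged)) +
    geom_col() +
    facet_wrap(~season) +
    scale_fill_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    labs(x = NULL, y = "Seasonal anomaly",
         title = "Seasonal anomalies (flagged beyond one SD)")
}

#' Growth-rate seasonality split by regime
#'
#' Net growth rates against day of year, coloured by whether the
#' population sat in the mixed layer or in the stratified metalimnion at
#' the interval start -- the bimodal growth pattern diagnostic.
#'
#' @param growth a [growth_series()] tibble.
#' @return a ggplot object.
#' @export
plot_growth_regimes <- function(growth) {
  dat <- growth %>%
    mutate(doy = as.numeric(format(as.Date(.data$t0), "%j"))) %>%
    filter(!is.na(.data$regime))
  ggplot(dat, aes(x = .data$doy, y = .data$mu, colour = .data$regime)) +
    geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    geom_point(alpha = 0.6) +
    scale_colour_manual(values = c(mixed = "steelblue",
                                   metalimnetic = "firebrick")) +
    labs(x = "Day of year", y = expression(mu ~ (day^-1)), colour = NULL,
         title = "Net growth rate by regime")
}
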