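# ggplot2 quick-look methods for the result objects.

#' Plot a temperature map
#'
#' Raster map of the final (r, z) temperature field, z increasing downward
#' from the transducer face.
#'
#' @param object A `dia_state` (e.g. `sim$field`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dia_state <- function(object, ...) {
  df <- tidy.dia_state(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$r * 1e3, .data$z * 1e3,
                                   fill = .data$temp_c)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(option = "inferno", name = "T (°C)") +
    ggplot2::labs(x = "r (mm)", y = "depth z (mm)",
                  title = sprintf("Temperature map, %s, t = %g s",
                                  object$grid$stack_label, object$time)) +
    ggplot2::theme_minimal()
}

#' Plot probe time series
#'
#' @param object A [simulate_heating()] result.
#' @param ... Unused.
#' @return A ggplot of temperature vs time per thermocouple.
#' @export
autoplot.dia_sim <- function(object, ...) {
  ggplot2::ggplot(object$series,
                  ggplot2::aes(.data$time_s, .data$temp_c,
                               colour = .data$probe)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "temperature (°C)",
                  colour = "probe",
                  title = sprintf("Probe heating, %s",
                                  object$field$grid$stack_label)) +
    ggplot2::theme_minimal()
}

#' Plot a trapped-energy sweep
#'
#' @param object A [trapped_sweep()] result.
#' @param ... Unused.
#' @return A ggplot of trapped fraction vs incidence angle.
#' @export
autoplot.dia_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$angle, 100 * .data$fraction)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "incidence angle (°)", y = "trapped energy (%)",
                  title = "Energy trapped between transducer and bone") +
    ggplot2::theme_minimal()
}
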