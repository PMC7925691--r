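#' Plot an event-triggered average against the mean event waveform
#'
#' @param object An `sta_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sta_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$current_pA,
                                   color = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Time from trigger peak (ms)", y = "Current (pA)",
      title = sprintf("Correlation strength %.3f (n = %d triggers)",
                      object$correlation_strength, object$n_trigger_events),
      color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a nearest-neighbor-distance CDF
#'
#' @param object An `nnd_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nnd_profile <- function(object, ...) {
  ggplot2::ggplot(object$cdf,
                  ggplot2::aes(.data$distance_um, .data$fraction)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Nearest-neighbor distance (µm)",
                  y = "Cumulative fraction of segments") +
    ggplot2::theme_minimal()
}

#' Plot an ROI label map
#'
#' @param object A `roi_map`.
#' @param ... Unused.
#' @return A ggplot raster of ROI labels.
#' @export
autoplot.roi_map <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = factor(.data$roi_id))) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Column", y = "Row", fill = "ROI") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Plot a correlation-scale fit
#'
#' @param object A `scale_fit`.
#' @param ... Unused.
#' @return A ggplot of scores vs distance with the fitted Gaussian decay.
#' @export
autoplot.scale_fit <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$distance_um)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$score), alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), color = "red") +
    ggplot2::labs(
      x = "Distance (µm)", y = "Noise-correlation score",
      title = sprintf("λ = %.2f µm", object$lambda_um)) +
    ggplot2::theme_minimal()
}

#' Plot receptor open probability over time
#'
#' @param object A `site_response`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.site_response <- function(object, ...) {
  ggplot2::ggplot(object$open_prob, ggplot2::aes(.data$t_ms, .data$p_open)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (ms)", y = "Open probability",
                  title = sprintf("Peak %.4f at %.1f ms (%s µm)",
                                  object$peak, object$latency_to_peak_ms,
                                  format(object$distance_um))) +
    ggplot2::theme_minimal()
}

#' Polar plot of a direction tuning curve
#'
#' @param responses Response amplitudes per direction.
#' @param directions Directions (deg).
#' @return A ggplot in polar coordinates with the DSI in the title.
#' @export
plot_tuning <- function(responses, directions) {
  tun <- direction_tuning(responses, directions)
  df <- tibble(direction = c(directions, directions[1]),
               response = c(responses, responses[1]))
  ggplot2::ggplot(df, ggplot2::aes(.data$direction, .data$response)) +
    ggplot2::geom_path() +
    ggplot2::coord_polar(start = -pi / 2, direction = -1) +
    ggplot2::scale_x_continuous(limits = c(0, 360),
                                breaks = seq(0, 315, by = 45)) +
    ggplot2::labs(x = NULL, y = "Response",
                  title = sprintf("DSI %.2f, θ = %s°",
                                  tun$dsi, format(round(tun$theta_deg)))) +
    ggplot2::theme_minimal()
}
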