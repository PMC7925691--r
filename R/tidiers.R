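#' Tidy an event-triggered-average result
#'
#' @param x An `sta_result` from [sepsc_triggered_average()].
#' @param ... Unused.
#' @return A long tibble: `component` ("sta" / "mean_sepsc"), `time_ms`,
#'   `current_pA`.
#' @export
tidy.sta_result <- function(x, ...) {
  bind_rows(
    mutate(x$sta, component = "sta"),
    mutate(x$mean_sepsc, component = "mean_sepsc")
  )[, c("component", "time_ms", "current_pA")]
}

#' @rdname tidy.sta_result
#' @export
glance.sta_result <- function(x, ...) {
  tibble(correlation_strength = x$correlation_strength,
         n_trigger_events = x$n_trigger_events)
}

#' Tidy a shuffle z-test result
#' @param x A `ztest_result` from [z_test()].
#' @param ... Unused.
#' @return The underlying one-row tibble.
#' @export
tidy.ztest_result <- function(x, ...) as_tibble(unclass(x))

#' @rdname tidy.ztest_result
#' @export
glance.ztest_result <- function(x, ...) {
  tibble(z_observed = x$z_observed, significant = x$significant)
}

#' Tidy a nearest-neighbor-distance profile
#' @param x An `nnd_profile` from [nnd()].
#' @param ... Unused.
#' @return Per-segment tibble including `nnd_um`.
#' @export
tidy.nnd_profile <- function(x, ...) as_tibble(x$segments)

#' @rdname tidy.nnd_profile
#' @export
glance.nnd_profile <- function(x, ...) {
  d <- x$segments$nnd_um
  tibble(n_segments = length(d), median_nnd_um = median(d),
         frac_within_1um = mean(d <= 1), frac_within_2um = mean(d <= 2))
}

#' Tidy an ROI map
#' @param x A `roi_map` from [segment_rois()].
#' @param ... Unused.
#' @return A tibble with `row`, `col`, `roi_id` for every labelled pixel.
#' @export
tidy.roi_map <- function(x, ...) {
  idx <- which(x$labels > 0, arr.ind = TRUE)
  tibble(row = idx[, 1], col = idx[, 2], roi_id = x$labels[idx])
}

#' @rdname tidy.roi_map
#' @export
glance.roi_map <- function(x, ...) {
  tibble(n_rois = nrow(x$seeds),
         n_multipixel = sum(x$seeds$n_pixels > 1),
         n_pixels_labelled = sum(x$labels > 0))
}

#' Tidy a correlation-scale fit
#' @param x A `scale_fit` from [fit_correlation_scale()].
#' @param ... Unused.
#' @return The (possibly binned) score-vs-distance data with the fitted
#'   curve in `fitted`.
#' @export
tidy.scale_fit <- function(x, ...) {
  mutate(x$data,
         fitted = x$amplitude *
           exp(-.data$distance_um^2 / (2 * x$sigma_um^2)) + x$offset)
}

#' @rdname tidy.scale_fit
#' @export
glance.scale_fit <- function(x, ...) {
  tibble(lambda_um = x$lambda_um, sigma_um = x$sigma_um,
         amplitude = x$amplitude, offset = x$offset, n = x$n)
}

#' Tidy a varicosity spatial/temporal fit
#' @param x A `varicosity_fit` from [fit_varicosity_profile()].
#' @param ... Unused.
#' @return A one-row tibble of the fitted parameters.
#' @export
tidy.varicosity_fit <- function(x, ...) {
  tibble(space_constant_um = x$space_constant_um, sx_um = x$sx_um,
         sy_um = x$sy_um, center_x_um = x$center_um[["x"]],
         center_y_um = x$center_um[["y"]], amplitude = x$amplitude,
         offset = x$offset, decay_tau_ms = x$decay_tau_ms)
}

#' @rdname tidy.varicosity_fit
#' @export
glance.varicosity_fit <- function(x, ...) {
  tibble(space_constant_um = x$space_constant_um,
         decay_tau_ms = x$decay_tau_ms)
}

#' Tidy a receptor site response
#' @param x A `site_response` from [receptor_response()].
#' @param ... Unused.
#' @return The occupancy/open-probability timeseries.
#' @export
tidy.site_response <- function(x, ...) as_tibble(x$open_prob)

#' @rdname tidy.site_response
#' @export
glance.site_response <- function(x, ...) {
  tibble(peak = x$peak, latency_to_peak_ms = x$latency_to_peak_ms,
         distance_um = x$distance_um)
}

#' Tidy a Hodges-Ajne test
#' @param x A `hodges_ajne` object.
#' @param ... Unused.
#' @return A one-row tibble: `m`, `n`, `p_value`, `method`.
#' @export
tidy.hodges_ajne <- function(x, ...) {
  tibble(m = x$m, n = x$n, p_value = x$p_value, method = x$method)
}

#' @rdname tidy.hodges_ajne
#' @export
glance.hodges_ajne <- function(x, ...) tidy.hodges_ajne(x)
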