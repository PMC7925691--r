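#' Zero-phase low-pass filter a current trace
#'
#' Applies a 4th-order Butterworth filter forward and backward
#' (zero phase lag), the standard conditioning step before quantal event
#' detection; recordings are typically filtered at 300 Hz.
#'
#' @param trace A [current_trace()].
#' @param cutoff Cutoff frequency (Hz); must be below the Nyquist frequency.
#' @return A filtered [current_trace()] of the same length and rate.
#' @export
lowpass <- function(trace, cutoff = 300) {
  fs <- trace_sample_rate(trace)
  if (cutoff >= fs / 2) {
    abort(sprintf("`cutoff` (%g Hz) must be below Nyquist (%g Hz).", cutoff, fs / 2))
  }
  if (cutoff <= 0) abort("`cutoff` must be > 0.")
  y <- butter_zerophase(trace$current_pA, fs, cutoff)
  trace_with_samples(trace, y)
}

# Zero-phase Butterworth low-pass: forward-backward filtering of order n is
# equivalent to applying the magnitude-squared response
# |H(f)|^2 = 1 / (1 + (f/fc)^(2n)) with zero phase, done here in the
# frequency domain (exact for periodic extension; traces are long relative
# to the filter memory so boundary effects are negligible).
butter_zerophase <- function(x, fs, cutoff, order = 4) {
  n <- length(x)
  if (n < 8) {
    bf <- signal::butter(order, 2 * cutoff / fs)
    return(as.numeric(signal::filtfilt(bf, x)))
  }
  freqs <- c(seq(0, floor(n / 2)), seq(-(ceiling(n / 2) - 1), -1)) * fs / n
  h2 <- 1 / (1 + (abs(freqs) / cutoff)^(2 * order))
  Re(stats::fft(stats::fft(x) * h2, inverse = TRUE)) / n
}

# peak delay (samples) of the difference-of-exponentials template
template_peak_offset <- function(rise_tau, decay_tau, sample_rate) {
  t_pk <- rise_tau * decay_tau / (decay_tau - rise_tau) * log(decay_tau / rise_tau)
  round(t_pk * sample_rate / 1000)
}

#' Detect quantal EPSC events by template subtraction
#'
#' Fast-rising deflections exceeding an amplitude threshold are detected on
#' the baseline-subtracted trace (rolling-median baseline). Overlapping
#' events riding on the decay of a predecessor are recovered by subtracting
#' a scaled difference-of-exponentials template with decay constant
#' `separation_decay` at each accepted event and re-searching the residual
#' until no further suprathreshold peaks remain. A 1-ms refractory period
#' is enforced between onsets.
#'
#' Amplitude thresholds of 5-7 pA and a 2.5-ms separation decay constant
#' are the usual operating point for quantal EPSCs in these cells.
#'
#' @param trace A [current_trace()] (positive-up EPSC convention); filter
#'   with [lowpass()] first for noisy recordings.
#' @param threshold Detection threshold (pA), > 0.
#' @param separation_decay Template decay constant used to split
#'   overlapping events (ms).
#' @param rise_tau Template rise constant (ms).
#' @param baseline_window Rolling-median baseline window (ms).
#' @param max_passes Maximum residual re-search passes.
#' @return A tibble of class `epsc_events`: `onset_s`, `peak_s`, `amp_pA`
#'   (threshold-crossing amplitude from the residual; refine with
#'   [event_metrics()]), `cell_id`. Events are in strictly increasing time
#'   order. Kinetic columns `rise_20_80_ms` / `decay_tau_ms` are `NA` until
#'   [event_metrics()] is run.
#' @export
detect_events <- function(trace, threshold = 5, separation_decay = 2.5,
                          rise_tau = 0.5, baseline_window = 50,
                          max_passes = 6L) {
  if (threshold <= 0) abort("`threshold` must be > 0.")
  fs <- trace_sample_rate(trace)
  y <- trace$current_pA
  n <- length(y)
  if (n == 0) return(empty_events(trace))

  k <- round(baseline_window / 1000 * fs)
  k <- max(3L, k + (k %% 2 == 0))  # odd
  if (n > k) {
    base <- runmed(y, k)
    # shrinking end-rule medians track events near the edges; extend the
    # first/last full-window baseline instead
    k2 <- (k - 1L) %/% 2L
    base[seq_len(k2)] <- base[k2 + 1L]
    base[(n - k2 + 1L):n] <- base[n - k2]
  } else {
    base <- rep(median(y), n)
  }
  d <- y - base

  tmpl <- quantal_template(rise_tau, separation_decay, fs)
  pk_off <- template_peak_offset(rise_tau, separation_decay, fs)
  refrac <- max(1L, round(0.001 * fs))

  local_maxima <- function(x) {
    nx <- length(x)
    if (nx < 3) return(integer(0))
    which(x[2:(nx - 1)] >= x[1:(nx - 2)] & x[2:(nx - 1)] > x[3:nx] &
            x[2:(nx - 1)] > threshold) + 1L
  }

  r <- d
  peaks <- integer(0)
  amps <- numeric(0)
  for (pass in seq_len(max_passes)) {
    cand <- local_maxima(r)
    # drop candidates within the refractory distance of accepted peaks
    if (length(peaks)) {
      keep <- vapply(cand, function(i) all(abs(i - peaks) > refrac), logical(1))
      cand <- cand[keep]
    }
    if (!length(cand)) break
    # within this pass, enforce refractory among new candidates (keep larger)
    ord <- cand[order(r[cand], decreasing = TRUE)]
    sel <- integer(0)
    for (i in ord) {
      if (!length(sel) || all(abs(i - sel) > refrac)) sel <- c(sel, i)
    }
    for (i in sort(sel)) {
      a <- r[i]
      # a same-pass predecessor's subtraction can pull a candidate back
      # under threshold; such residual bumps are not events
      if (a <= threshold) next
      i0 <- max(1L, i - pk_off)
      i1 <- min(n, i0 + length(tmpl) - 1L)
      off <- i0 - (i - pk_off)  # >0 when clipped at the left edge
      r[i0:i1] <- r[i0:i1] - a * tmpl[(1L + off):(i1 - i0 + 1L + off)]
      peaks <- c(peaks, i)
      amps <- c(amps, a)
    }
  }
  if (!length(peaks)) return(empty_events(trace))
  ord <- order(peaks)
  peaks <- peaks[ord]
  amps <- amps[ord]
  onsets <- pmax(1L, peaks - pk_off)
  tibble_events(onsets / fs - 1 / fs, peaks / fs - 1 / fs, amps, trace)
}

empty_events <- function(trace) {
  out <- tibble(onset_s = numeric(0), peak_s = numeric(0),
                amp_pA = numeric(0), rise_20_80_ms = numeric(0),
                decay_tau_ms = numeric(0),
                cell_id = character(0))
  class(out) <- c("epsc_events", class(out))
  out
}

tibble_events <- function(onset_s, peak_s, amp_pA, trace) {
  out <- tibble(onset_s = onset_s, peak_s = peak_s, amp_pA = amp_pA,
                rise_20_80_ms = NA_real_, decay_tau_ms = NA_real_,
                cell_id = trace_cell_id(trace))
  class(out) <- c("epsc_events", class(out))
  out
}

#' Measure peak amplitude, 20-80% rise time and decay constant per event
#'
#' The per-event baseline is the median of the 5 ms preceding onset; peak
#' amplitude is the baseline-subtracted maximum between onset and
#' `peak_search` ms after it; the 20-80% rise time is interpolated on the
#' rising limb; the decay constant comes from a single-exponential fit
#' (log-linear least squares) over the window from the peak to 5 decay
#' constants later, truncated at the next event's onset. Events whose
#' windows are clipped by the trace edges keep their row (they still count)
#' but their kinetic metrics are set to `NA` rather than extrapolated.
#'
#' @param trace The [current_trace()] the events were detected in.
#' @param events An `epsc_events` tibble from [detect_events()].
#' @param baseline_ms Pre-onset baseline window (ms).
#' @param decay_guess Initial decay constant for windowing (ms).
#' @param peak_search Window after onset searched for the peak (ms).
#' @return The events tibble with `amp_pA`, `rise_20_80_ms`,
#'   `decay_tau_ms` filled in.
#' @export
event_metrics <- function(trace, events, baseline_ms = 5, decay_guess = 2.5,
                          peak_search = 5) {
  fs <- trace_sample_rate(trace)
  y <- trace$current_pA
  n <- length(y)
  if (!nrow(events)) return(events)
  if (any(events$onset_s < 0) || any(events$peak_s > (n - 1) / fs)) {
    abort("Events lie outside the trace.")
  }
  bl_n <- max(1L, round(baseline_ms / 1000 * fs))
  next_onset <- c(events$onset_s[-1], Inf)

  res <- purrr::pmap(
    list(events$onset_s, events$peak_s, next_onset),
    function(on_s, pk_s, nxt_s) {
      i_on <- round(on_s * fs) + 1L
      # refine the peak near the supplied estimate (+/- 0.5 ms), or search
      # the whole post-onset window when none is given
      if (is.finite(pk_s) && pk_s >= on_s) {
        i_lo <- max(i_on, round(pk_s * fs) + 1L - round(5e-4 * fs))
        i_hi <- min(n, round(pk_s * fs) + 1L + round(5e-4 * fs))
      } else {
        i_lo <- i_on
        i_hi <- min(n, i_on + round(peak_search / 1000 * fs))
      }
      edge <- i_on - bl_n < 1L ||
        i_on + round(5 * decay_guess / 1000 * fs) > n
      bl <- median(y[max(1L, i_on - bl_n):max(1L, i_on - 1L)])
      seg <- y[i_lo:i_hi] - bl
      i_pk <- i_lo + which.max(seg) - 1L
      amp <- y[i_pk] - bl
      if (edge) {
        return(list(peak_s = (i_pk - 1) / fs, amp = amp,
                    rise = NA_real_, tau = NA_real_))
      }
      # 20-80% rise on the rising limb, linear interpolation
      limb <- y[i_on:i_pk] - bl
      t_limb <- (seq_along(limb) - 1) / fs * 1000
      cross <- function(frac) {
        thr <- frac * amp
        j <- which(limb >= thr)[1]
        if (is.na(j) || j == 1L) return(t_limb[1])
        t_limb[j - 1] + (thr - limb[j - 1]) / (limb[j] - limb[j - 1]) *
          (t_limb[j] - t_limb[j - 1])
      }
      rise <- cross(0.8) - cross(0.2)
      # single-exponential decay fit, peak -> 5 decay constants (or next onset)
      i_end <- min(n, i_pk + round(5 * decay_guess / 1000 * fs),
                   round(nxt_s * fs))
      tau <- NA_real_
      if (i_end - i_pk >= 4) {
        seg_d <- y[i_pk:i_end] - bl
        tt <- (seq_along(seg_d) - 1) / fs * 1000
        ok <- seg_d > 0.05 * amp
        if (sum(ok) >= 4) {
          fit <- lm(log(seg_d[ok]) ~ tt[ok])
          slope <- coef(fit)[2]
          if (is.finite(slope) && slope < 0) tau <- -1 / slope
        }
      }
      list(peak_s = (i_pk - 1) / fs, amp = amp,
           rise = if (is.finite(rise) && rise > 0) rise else NA_real_,
           tau = tau)
    })
  events$peak_s <- vapply(res, `[[`, numeric(1), "peak_s")
  events$amp_pA <- vapply(res, `[[`, numeric(1), "amp")
  events$rise_20_80_ms <- vapply(res, `[[`, numeric(1), "rise")
  events$decay_tau_ms <- vapply(res, `[[`, numeric(1), "tau")
  events
}

#' Instantaneous event frequency
#'
#' Reciprocal of successive inter-event intervals, timestamped at the later
#' event of each interval.
#'
#' @param events An `epsc_events` tibble (or any data frame with a
#'   `peak_s` or `onset_s` column).
#' @return A tibble with `time_s` and `freq_hz`; empty when fewer than two
#'   events are supplied.
#' @export
instantaneous_frequency <- function(events) {
  t_ev <- if ("peak_s" %in% names(events) && !anyNA(events$peak_s)) {
    events$peak_s
  } else events$onset_s
  if (length(t_ev) < 2) return(tibble(time_s = numeric(0), freq_hz = numeric(0)))
  tibble(time_s = t_ev[-1], freq_hz = 1 / diff(t_ev))
}

#' Average event waveform
#'
#' Aligns a snippet of the trace to each event (onset or peak) and averages
#' them after per-snippet baseline subtraction (median of the earliest 10 ms
#' of the pre-window). Events too close to the trace edges for a full
#' window are dropped from the average.
#'
#' @param trace A [current_trace()].
#' @param events An `epsc_events` tibble.
#' @param window Pre/post window (ms); a single value is used for both
#'   sides.
#' @param align `"onset"` or `"peak"`.
#' @return A tibble of class `epsc_waveform` with `time_ms` (0 at the
#'   alignment point) and `current_pA`; attribute `n_events` gives the
#'   number of snippets averaged.
#' @export
average_waveform <- function(trace, events, window = 20, align = c("onset", "peak")) {
  align <- match.arg(align)
  if (!nrow(events)) abort("No events to average.")
  fs <- trace_sample_rate(trace)
  w <- if (length(window) == 1) c(window, window) else window
  n_pre <- round(w[1] / 1000 * fs)
  n_post <- round(w[2] / 1000 * fs)
  t_al <- if (align == "peak") events$peak_s else events$onset_s
  idx <- round(t_al * fs) + 1L
  n <- nrow(trace)
  ok <- idx - n_pre >= 1L & idx + n_post <= n
  idx <- idx[ok]
  if (!length(idx)) abort("All event windows are clipped by the trace edges.")
  y <- trace$current_pA
  offs <- -n_pre:n_post
  snips <- vapply(idx, function(i) y[i + offs], numeric(length(offs)))
  # per-snippet baseline: earliest 10 ms of the pre-window
  bl_n <- max(1L, min(n_pre, round(0.010 * fs)))
  bl <- apply(snips[seq_len(bl_n), , drop = FALSE], 2, median)
  snips <- sweep(snips, 2, bl)
  out <- tibble(time_ms = offs / fs * 1000, current_pA = rowMeans(snips))
  attr(out, "n_events") <- length(idx)
  attr(out, "align") <- align
  class(out) <- c("epsc_waveform", class(out))
  out
}
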