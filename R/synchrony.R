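#' Event-triggered average across a recorded pair
#'
#' Computes the sEPSC-triggered average (STA): snippets of the *other*
#' cell's current aligned to the peaks of events detected in the reference
#' cell, averaged; the reference cell's own mean event waveform is computed
#' on the same time base. The ratio of the two peak amplitudes,
#' `peak(STA) / peak(mean event)`, is the **correlation strength** -- an
#' estimate of the fraction of quantal events shared between the two cells.
#' When every vesicle drives both cells with equal efficacy the ratio
#' approaches 1; for statistically independent inputs it approaches 0.
#'
#' @param ref_events `epsc_events` detected in the reference cell (must
#'   have valid `peak_s`).
#' @param ref_trace The reference cell's [current_trace()].
#' @param other_trace The second cell's [current_trace()]; must share the
#'   reference trace's sampling rate.
#' @param window Snippet half-width (ms) on each side of the trigger.
#' @param min_events Minimum number of trigger events required.
#' @return An object of class `sta_result`: list with `sta` and
#'   `mean_sepsc` waveform tibbles (`time_ms`, `current_pA`),
#'   `correlation_strength`, and `n_trigger_events`.
#' @export
#' @seealso [tidy.sta_result()], [autoplot.sta_result()]
sepsc_triggered_average <- function(ref_events, ref_trace, other_trace,
                                    window = 20, min_events = 10) {
  if (!nrow(ref_events)) abort("No trigger events.")
  if (nrow(ref_events) < min_events) {
    abort(sprintf("Need at least %d trigger events; got %d.",
                  min_events, nrow(ref_events)))
  }
  if (!isTRUE(all.equal(trace_sample_rate(ref_trace),
                        trace_sample_rate(other_trace)))) {
    abort("Sample rates of the two traces differ.")
  }
  mean_sepsc <- average_waveform(ref_trace, ref_events, window, align = "peak")
  sta <- average_waveform(other_trace, ref_events, window, align = "peak")
  strength <- max(sta$current_pA) / max(mean_sepsc$current_pA)
  structure(
    list(sta = as_tibble(sta), mean_sepsc = as_tibble(mean_sepsc),
         correlation_strength = strength,
         n_trigger_events = attr(sta, "n_events")),
    class = "sta_result"
  )
}

#' @export
print.sta_result <- function(x, ...) {
  cat(sprintf(
    "<sta_result> correlation strength %.3f (%d trigger events)\n",
    x$correlation_strength, x$n_trigger_events))
  invisible(x)
}

#' Chance probability of two independent trains co-firing in one bin
#'
#' For per-bin event probabilities `p_bin_a` and `p_bin_b` of two
#' independent trains, the percentage chance of a coincidence in a given
#' bin is their product times 100. With 3-Hz trains and 1-ms bins each
#' probability is 0.003, giving 0.003^2 * 100 = 0.0009%.
#'
#' @param p_bin_a,p_bin_b Per-bin event probabilities in `[0, 1]`.
#' @return Coincidence chance in percent.
#' @export
#' @examples
#' chance_coincidence(0.003, 0.003) # 9e-04 %
chance_coincidence <- function(p_bin_a, p_bin_b) {
  if (any(c(p_bin_a, p_bin_b) < 0) || any(c(p_bin_a, p_bin_b) > 1)) {
    abort("Probabilities must be in [0, 1].")
  }
  p_bin_a * p_bin_b * 100
}

#' Match coincident events across a recorded pair
#'
#' Greedy nearest-lag one-to-one pairing: candidate pairs are events whose
#' peaks fall within `window` ms of each other and whose amplitudes exceed
#' `min_amp` in *both* cells; candidates are accepted in order of
#' increasing absolute lag (ties toward the earlier cell-A event), each
#' event used at most once. Event properties are standardized per cell
#' (z-scored over the matched set) before return, so property correlations
#' are scale-free.
#'
#' @param events_a,events_b `epsc_events` tibbles with metrics filled in
#'   (see [event_metrics()]).
#' @param window Coincidence window (ms); the default 1 ms matches the
#'   bin width used for the chance-coincidence estimate.
#' @param min_amp Minimum peak amplitude in both cells (pA).
#' @return A tibble of class `matched_pairs` with standardized `amp_a`,
#'   `amp_b`, `rise_a`, `rise_b`, `decay_a`, `decay_b`, the raw amplitudes
#'   (`amp_raw_a`, `amp_raw_b`), `lag_ms` (b minus a peak time) and the
#'   source row indices `idx_a`, `idx_b`. Zero rows when nothing matches.
#' @export
match_events <- function(events_a, events_b, window = 1, min_amp = 5) {
  if (window <= 0) abort("`window` must be > 0.")
  ea <- which(events_a$amp_pA >= min_amp)
  eb <- which(events_b$amp_pA >= min_amp)
  empty <- tibble(idx_a = integer(0), idx_b = integer(0), lag_ms = numeric(0),
                  amp_a = numeric(0), amp_b = numeric(0),
                  rise_a = numeric(0), rise_b = numeric(0),
                  decay_a = numeric(0), decay_b = numeric(0),
                  amp_raw_a = numeric(0), amp_raw_b = numeric(0))
  class(empty) <- c("matched_pairs", class(empty))
  if (!length(ea) || !length(eb)) return(empty)
  ta <- events_a$peak_s[ea]
  tb <- events_b$peak_s[eb]
  w_s <- window / 1000
  # candidate pairs within the window
  cand <- purrr::map_dfr(seq_along(ta), function(i) {
    j <- which(abs(tb - ta[i]) <= w_s)
    if (!length(j)) return(NULL)
    tibble(i = i, j = j, lag = tb[j] - ta[i])
  })
  if (!nrow(cand)) return(empty)
  cand <- cand[order(abs(cand$lag), cand$i), ]
  used_a <- logical(length(ta))
  used_b <- logical(length(tb))
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    i <- cand$i[r]; j <- cand$j[r]
    if (!used_a[i] && !used_b[j]) {
      used_a[i] <- TRUE
      used_b[j] <- TRUE
      keep[r] <- TRUE
    }
  }
  cand <- cand[keep, ]
  cand <- cand[order(cand$i), ]
  z <- function(x) {
    s <- sd(x)
    if (!is.finite(s) || s == 0) return(x - mean(x))
    (x - mean(x)) / s
  }
  ia <- ea[cand$i]
  ib <- eb[cand$j]
  out <- tibble(
    idx_a = ia, idx_b = ib, lag_ms = cand$lag * 1000,
    amp_a = z(events_a$amp_pA[ia]), amp_b = z(events_b$amp_pA[ib]),
    rise_a = z(events_a$rise_20_80_ms[ia]), rise_b = z(events_b$rise_20_80_ms[ib]),
    decay_a = z(events_a$decay_tau_ms[ia]), decay_b = z(events_b$decay_tau_ms[ib]),
    amp_raw_a = events_a$amp_pA[ia], amp_raw_b = events_b$amp_pA[ib]
  )
  class(out) <- c("matched_pairs", class(out))
  out
}

#' Pearson correlation of matched-event properties
#'
#' @param pairs A `matched_pairs` tibble from [match_events()].
#' @return A tibble with one row per property (`amplitude`, `decay`,
#'   `rise`): Pearson `r` and the number of complete pairs `n`.
#' @export
property_correlation <- function(pairs) {
  if (nrow(pairs) < 4) abort("Need at least 4 matched pairs.")
  one <- function(a, b, label) {
    ok <- stats::complete.cases(a, b)
    if (sum(ok) < 4) return(tibble(property = label, r = NA_real_, n = sum(ok)))
    if (sd(a[ok]) == 0 || sd(b[ok]) == 0) {
      abort(sprintf("Zero variance in %s; correlation undefined.", label))
    }
    tibble(property = label, r = cor(a[ok], b[ok]), n = sum(ok))
  }
  bind_rows(one(pairs$amp_a, pairs$amp_b, "amplitude"),
            one(pairs$decay_a, pairs$decay_b, "decay"),
            one(pairs$rise_a, pairs$rise_b, "rise"))
}

#' Fisher z-transformation of a correlation coefficient
#'
#' `z = 0.5 * (ln(1 + r) - ln(1 - r))`, the variance-stabilizing transform
#' used before comparing correlation coefficients.
#'
#' @param r Correlation coefficient(s), `|r| < 1`.
#' @return The transformed value(s).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) abort("`r` must satisfy |r| < 1.")
  0.5 * (log(1 + r) - log(1 - r))
}

#' @rdname fisher_z
#' @param z A Fisher z value; `fisher_z_inv()` maps it back to `r`.
#' @export
fisher_z_inv <- function(z) tanh(z)

#' Shuffle matched pairs by a one-step circular shift
#'
#' The null distribution for the pair-property correlation is built by
#' offsetting one cell's property sequence by one event (circularly, so the
#' shuffled set keeps the same size): cell-B columns are rotated by one
#' index against cell A.
#'
#' @param pairs A `matched_pairs` tibble (at least 2 rows).
#' @return The tibble with all `_b` columns circularly shifted by one row.
#' @export
shuffle_pairs <- function(pairs) {
  n <- nrow(pairs)
  if (n < 2) abort("Need at least 2 pairs to shuffle.")
  rot <- c(n, seq_len(n - 1L))
  bcols <- grep("(_b$|_raw_b$)", names(pairs), value = TRUE)
  out <- pairs
  out[bcols] <- pairs[rot, bcols]
  out
}

#' Compare original and shuffled correlations with a z-test
#'
#' Both correlations are Fisher-z transformed and compared with
#' `z_observed = (z_orig - z_shuff) / sqrt(1/(n_orig - 3) + 1/(n_shuff - 3))`;
#' the difference is declared significant when `|z_observed|` exceeds
#' `critical` (1.96, the two-tailed 5% point of the standard normal, by
#' default).
#'
#' @param r_orig,r_shuff Pearson correlations of the original and shuffled
#'   pairings.
#' @param n_orig,n_shuff Corresponding sample sizes (each > 3).
#' @param critical Significance gate on `|z_observed|`.
#' @return An object of class `ztest_result` (also a one-row tibble):
#'   `r_orig`, `r_shuff`, `z_orig`, `z_shuff`, `n_orig`, `n_shuff`,
#'   `z_observed`, `significant`.
#' @export
z_test <- function(r_orig, n_orig, r_shuff, n_shuff, critical = 1.96) {
  if (n_orig <= 3 || n_shuff <= 3) abort("Sample sizes must exceed 3.")
  z_orig <- fisher_z(r_orig)
  z_shuff <- fisher_z(r_shuff)
  z_obs <- (z_orig - z_shuff) / sqrt(1 / (n_orig - 3) + 1 / (n_shuff - 3))
  out <- tibble(r_orig = r_orig, r_shuff = r_shuff,
                z_orig = z_orig, z_shuff = z_shuff,
                n_orig = n_orig, n_shuff = n_shuff,
                z_observed = z_obs, critical = critical,
                significant = abs(z_obs) > critical)
  class(out) <- c("ztest_result", class(out))
  out
}

#' Shuffle test for a matched-pair property correlation
#'
#' Convenience pipeline: Pearson r of the original pairing, r of the
#' one-step circular shuffle, and the Fisher-z comparison of the two.
#'
#' @param pairs A `matched_pairs` tibble.
#' @param property One of `"amplitude"`, `"decay"`, `"rise"`.
#' @param critical Significance gate (see [z_test()]).
#' @return A `ztest_result` row.
#' @export
property_ztest <- function(pairs, property = c("amplitude", "decay", "rise"),
                           critical = 1.96) {
  property <- match.arg(property)
  cols <- switch(property,
                 amplitude = c("amp_a", "amp_b"),
                 decay = c("decay_a", "decay_b"),
                 rise = c("rise_a", "rise_b"))
  a <- pairs[[cols[1]]]
  b <- pairs[[cols[2]]]
  ok <- stats::complete.cases(a, b)
  sh <- shuffle_pairs(pairs)
  bs <- sh[[cols[2]]]
  ok_s <- stats::complete.cases(a, bs)
  z_test(cor(a[ok], b[ok]), sum(ok), cor(a[ok_s], bs[ok_s]), sum(ok_s),
         critical = critical)
}

#' Empirical CDF table of event amplitudes
#'
#' Cumulative distribution of quantal amplitudes, for comparing event
#' populations (e.g. spontaneous vs desynchronized release) without a
#' parametric model.
#'
#' @param events An `epsc_events` tibble.
#' @param breaks Amplitude grid (pA); defaults to 0.5-pA steps across the
#'   observed range.
#' @return A tibble with `amp_pA` and `cum_fraction`.
#' @export
amplitude_cdf <- function(events, breaks = NULL) {
  a <- events$amp_pA[!is.na(events$amp_pA)]
  if (!length(a)) abort("No amplitudes.")
  if (is.null(breaks)) breaks <- seq(0, max(a) + 0.5, by = 0.5)
  tibble(amp_pA = breaks,
         cum_fraction = vapply(breaks, function(b) mean(a <= b), numeric(1)))
}
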