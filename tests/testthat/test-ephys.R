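test_that("low-pass filtering passes DC, rejects out-of-band tones, guards Nyquist", {
  fs <- 1e4
  dc <- current_trace(rep(7, 5000), fs)
  expect_equal(lowpass(dc, 300)$current_pA, rep(7, 5000), tolerance = 1e-6)

  t <- seq_len(2e4) / fs
  tone <- current_trace(sin(2 * pi * 1000 * t), fs)
  out <- lowpass(tone, 300)
  expect_lt(sqrt(mean(out$current_pA^2)) / sqrt(mean(tone$current_pA^2)), 0.05)

  expect_error(lowpass(tone, 5000), "Nyquist")
  expect_error(lowpass(tone, 6000), "Nyquist")
})

test_that("detection finds injected events and none in silence", {
  flat <- current_trace(rep(0, 1e4), 1e4)
  expect_equal(nrow(detect_events(flat, 5)), 0)
  expect_error(detect_events(flat, -1), "threshold")

  onsets <- seq(0.05, 0.95, by = 0.1)
  tr <- make_event_trace(onsets, rep(20, 10), noise_sd = 1, seed = 2)
  ev <- detect_events(lowpass(tr, 300), threshold = 5)
  expect_equal(nrow(ev), 10)
  expect_true(all(abs(ev$onset_s - onsets) < 0.001))
  expect_true(all(diff(ev$peak_s) > 0))
})

test_that("overlapping events 3 ms apart are split by template subtraction", {
  tr <- make_event_trace(c(0.1, 0.103), c(20, 15), noise_sd = 0)
  ev <- detect_events(tr, threshold = 5, separation_decay = 2.5)
  expect_equal(nrow(ev), 2)
  expect_true(all(abs(ev$onset_s - c(0.1, 0.103)) < 0.001))
  # second amplitude measured on the residual, not on the predecessor's decay
  expect_lt(abs(ev$amp_pA[2] - 15), 2)
})

test_that("event metrics recover amplitude, rise and decay of known shapes", {
  tr <- make_event_trace(0.1, 20)
  ev <- event_metrics(tr, detect_events(tr, 5))
  expect_equal(ev$amp_pA, 20, tolerance = 0.5 / 20)

  # symmetric triangular pulse: 20-80% span is 60% of the rising limb
  fs <- 1e4
  rise_n <- 100 # 10 ms rising limb
  y <- c(rep(0, 2000), seq(0, 20, length.out = rise_n + 1),
         seq(20, 0, length.out = rise_n + 1)[-1], rep(0, 2000))
  tri <- current_trace(y, fs)
  evt <- tibble::tibble(onset_s = 2000 / fs, peak_s = (2000 + rise_n) / fs,
                        amp_pA = 20, rise_20_80_ms = NA_real_,
                        decay_tau_ms = NA_real_, cell_id = NA_character_)
  m <- event_metrics(tri, evt)
  expect_equal(m$rise_20_80_ms, 0.6 * 10, tolerance = 0.02)

  # pure exponential decay tau = 2.5 ms
  t_ms <- seq(0, 30, by = 0.1)
  y <- c(rep(0, 500), 20 * exp(-t_ms / 2.5), rep(0, 500))
  expd <- current_trace(y, fs)
  evd <- tibble::tibble(onset_s = 0.05, peak_s = 0.05, amp_pA = 20,
                        rise_20_80_ms = NA_real_, decay_tau_ms = NA_real_,
                        cell_id = NA_character_)
  m2 <- event_metrics(expd, evd, decay_guess = 2.5)
  expect_equal(m2$decay_tau_ms, 2.5, tolerance = 0.1 / 2.5)
})

test_that("metrics are invariant to a DC offset", {
  onsets <- seq(0.05, 1.95, by = 0.15)
  tr <- make_event_trace(onsets, rep(18, length(onsets)), noise_sd = 1,
                         seed = 4)
  tr_off <- current_trace(tr$current_pA + 50, trace_sample_rate(tr))
  e1 <- event_metrics(tr, detect_events(tr, 5))
  e2 <- event_metrics(tr_off, detect_events(tr_off, 5))
  expect_equal(nrow(e1), nrow(e2))
  expect_equal(e1$amp_pA, e2$amp_pA, tolerance = 1e-6)
  expect_equal(e1$rise_20_80_ms, e2$rise_20_80_ms, tolerance = 1e-6)
})

test_that("edge events are counted but their kinetics are withheld", {
  tr <- make_event_trace(c(0.0005, 0.1), c(20, 20), duration = 0.2)
  ev <- event_metrics(tr, detect_events(tr, 5))
  expect_equal(nrow(ev), 2)
  expect_true(is.na(ev$rise_20_80_ms[1]))
  expect_false(is.na(ev$rise_20_80_ms[2]))
})

test_that("detection meets recall and false-positive bounds on synthetic traces", {
  # amplitude >= 3x threshold, noise 1.5 pA: recall >= 95%, FP <= 2/min
  out <- gen_paired_traces(paired_train_spec(
    duration = 120, rate_a = 3, rate_b = 0, amp_mean = 15, amp_sd = 0.01,
    noise_sd = 1.5, seed = 11))
  tr <- lowpass(out$trace_a, 300)
  ev <- detect_events(tr, threshold = 5)
  truth_t <- out$truth$onset_s[out$truth$cell == "a"]
  hit <- vapply(truth_t, function(t0) any(abs(ev$onset_s - t0) < 0.002),
                logical(1))
  matched <- vapply(ev$onset_s, function(t0) any(abs(truth_t - t0) < 0.002),
                    logical(1))
  expect_gte(mean(hit), 0.95)
  expect_lte(sum(!matched) / 2, 2) # false positives per minute
  expect_true(all(ev$amp_pA > 5))
  expect_true(all(diff(ev$onset_s) > 0))
})

test_that("instantaneous frequency is the reciprocal inter-event interval", {
  ev <- tibble::tibble(onset_s = c(0, 0.1, 0.2), peak_s = c(0, 0.1, 0.2))
  f <- instantaneous_frequency(ev)
  expect_equal(f$freq_hz, c(10, 10))
  expect_equal(f$time_s, c(0.1, 0.2))
  expect_equal(nrow(instantaneous_frequency(ev[1, ])), 0)

  # a 3-Hz Poisson train's mean instantaneous rate converges to 3 Hz
  truth <- gen_paired_traces(paired_train_spec(
    duration = 400, rate_a = 3, sample_rate = 200, noise_sd = 0,
    seed = 13))$truth
  ta <- truth[truth$cell == "a", ]
  fr <- instantaneous_frequency(tibble::tibble(onset_s = ta$onset_s,
                                               peak_s = ta$onset_s))
  # harmonic-mean structure: mean(1/IEI) overshoots the rate for finite n,
  # but the median IEI pins the rate; use the unbiased rate estimate
  expect_lt(abs(nrow(ta) / diff(range(ta$onset_s)) - 3) / 3, 0.1)
  expect_true(all(fr$freq_hz > 0))
})

test_that("averaged waveforms reproduce the template and shrink noise", {
  onsets <- seq(0.05, 4.95, by = 0.05)
  tr0 <- make_event_trace(onsets, rep(20, length(onsets)), noise_sd = 0)
  w <- average_waveform(tr0, detect_events(tr0, 5), window = 10,
                        align = "onset")
  single <- make_event_trace(0.05, 20, duration = 0.2)
  ws <- average_waveform(single, detect_events(single, 5), window = 10,
                         align = "onset")
  expect_equal(w$current_pA, ws$current_pA, tolerance = 1e-6)

  noise_resid <- function(n_events, seed) {
    on <- seq(0.05, by = 0.05, length.out = n_events)
    trn <- make_event_trace(on, rep(20, n_events), noise_sd = 2, seed = seed)
    evn <- tibble::tibble(onset_s = on, peak_s = on + 0.001)
    wn <- average_waveform(trn, evn, window = 10, align = "onset")
    sqrt(mean((wn$current_pA - ws$current_pA)^2))
  }
  r25 <- mean(vapply(1:3, function(s) noise_resid(25, s), numeric(1)))
  r100 <- mean(vapply(1:3, function(s) noise_resid(100, s), numeric(1)))
  expect_lt(r100, r25)

  expect_error(average_waveform(tr0, detect_events(tr0, 100)), "No events")
})
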