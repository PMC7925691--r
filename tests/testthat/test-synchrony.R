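test_that("STA equals the mean event waveform under full sharing", {
  out <- gen_paired_traces(paired_train_spec(
    duration = 60, shared_fraction = 1, coincidence_jitter = 0,
    noise_sd = 0, seed = 21))
  ev <- detect_events(out$trace_a, 5)
  sta <- sepsc_triggered_average(ev, out$trace_a, out$trace_b)
  expect_equal(sta$correlation_strength, 1, tolerance = 1e-3)
  # kinetically indistinguishable: pointwise agreement of the waveforms
  expect_lt(max(abs(sta$sta$current_pA - sta$mean_sepsc$current_pA)) /
              max(sta$mean_sepsc$current_pA), 0.01)
  expect_s3_class(glance(sta), "tbl_df")
})

test_that("STA errors on too few triggers or mismatched rates", {
  out <- gen_paired_traces(paired_train_spec(duration = 10, seed = 1))
  ev <- detect_events(lowpass(out$trace_a), 5)
  other <- current_trace(rep(0, 1000), 5000)
  expect_error(sepsc_triggered_average(ev, out$trace_a, other), "rates")
  expect_error(sepsc_triggered_average(ev[0, ], out$trace_a, out$trace_b),
               "events")
})

test_that("correlation strength is symmetric in the reference choice", {
  out <- gen_paired_traces(paired_train_spec(
    duration = 240, shared_fraction = 0.5, seed = 31))
  tr_a <- lowpass(out$trace_a)
  tr_b <- lowpass(out$trace_b)
  ev_a <- detect_events(tr_a, 5)
  ev_b <- detect_events(tr_b, 5)
  s_ab <- sepsc_triggered_average(ev_a, tr_a, tr_b)$correlation_strength
  s_ba <- sepsc_triggered_average(ev_b, tr_b, tr_a)$correlation_strength
  expect_lt(abs(s_ab - s_ba), 0.06)
})

test_that("chance coincidence is the product of per-bin probabilities (percent)", {
  expect_identical(chance_coincidence(0.003, 0.003), 0.003^2 * 100)
  expect_identical(chance_coincidence(0, 0.7), 0)
  expect_identical(chance_coincidence(1, 1), 100)
  expect_error(chance_coincidence(-0.1, 0.5), "0, 1")
  expect_error(chance_coincidence(0.5, 1.5), "0, 1")
})

test_that("event matching is one-to-one, windowed, and recalls shared truth", {
  # disjoint event times give no pairs
  ea <- tibble::tibble(peak_s = c(1, 2), amp_pA = c(10, 10),
                       rise_20_80_ms = 1, decay_tau_ms = 2)
  eb <- tibble::tibble(peak_s = c(10, 20), amp_pA = c(10, 10),
                       rise_20_80_ms = 1, decay_tau_ms = 2)
  expect_equal(nrow(match_events(ea, eb, window = 1)), 0)
  expect_error(match_events(ea, eb, window = 0), "window")

  out <- gen_paired_traces(paired_train_spec(
    duration = 300, shared_fraction = 0.5, coincidence_jitter = 0.2,
    seed = 41))
  tr_a <- lowpass(out$trace_a)
  tr_b <- lowpass(out$trace_b)
  ev_a <- event_metrics(tr_a, detect_events(tr_a, 5))
  ev_b <- event_metrics(tr_b, detect_events(tr_b, 5))
  pairs <- match_events(ev_a, ev_b, window = 1, min_amp = 5)
  truth <- out$truth
  sh_a <- truth$onset_s[truth$cell == "a" & truth$shared &
                          truth$amp_pA >= 5]
  # recall: a truth shared event is recovered if some matched pair's
  # cell-A event lies within 1 ms of it
  hit <- vapply(sh_a, function(t0) {
    any(abs(ev_a$onset_s[pairs$idx_a] - t0) < 0.001)
  }, logical(1))
  expect_gte(mean(hit), 0.95)
  expect_true(all(abs(pairs$lag_ms) <= 1))
  expect_equal(anyDuplicated(pairs$idx_a), 0)
  expect_equal(anyDuplicated(pairs$idx_b), 0)
  expect_true(all(pairs$amp_raw_a >= 5 & pairs$amp_raw_b >= 5))
})

test_that("property correlations behave at the limits", {
  mk_pairs <- function(a, b) {
    tibble::tibble(amp_a = a, amp_b = b, decay_a = a, decay_b = b,
                   rise_a = a, rise_b = b)
  }
  p1 <- mk_pairs(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  pc <- property_correlation(p1)
  expect_equal(pc$r, rep(1, 3))

  withr::with_seed(7, {
    p0 <- mk_pairs(rnorm(1e4), rnorm(1e4))
  })
  expect_lt(max(abs(property_correlation(p0)$r)), 0.03)

  expect_error(property_correlation(p1[1:3, ]), "at least 4")
  expect_error(property_correlation(mk_pairs(rep(1, 5), 1:5)), "variance")
})

test_that("Fisher z matches the closed form and inverts exactly", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5 * log(3))
  expect_equal(fisher_z(-0.5), -fisher_z(0.5))
  expect_error(fisher_z(1), "\\|r\\|")
  r <- seq(-0.999, 0.999, length.out = 201)
  expect_lt(max(abs(fisher_z_inv(fisher_z(r)) - r)), 1e-12)
})

test_that("the circular shuffle forms the cyclic group of order n", {
  p2 <- tibble::tibble(amp_a = c(1, 2), amp_b = c(10, 20),
                       decay_a = 0, decay_b = c(1, 2),
                       rise_a = 0, rise_b = c(5, 6))
  s2 <- shuffle_pairs(p2)
  expect_equal(s2$amp_b, c(20, 10))
  expect_error(shuffle_pairs(p2[1, ]), "at least 2")

  p3 <- tibble::tibble(amp_a = 1:3, amp_b = c(7, 8, 9),
                       decay_a = 0, decay_b = 1:3, rise_a = 0, rise_b = 1:3)
  s3 <- shuffle_pairs(shuffle_pairs(p3))
  expect_false(isTRUE(all.equal(s3$amp_b, p3$amp_b)))
  s3b <- shuffle_pairs(s3)
  expect_equal(s3b$amp_b, p3$amp_b)

  # shuffled correlation equals the circular lag-1 cross-correlation
  withr::with_seed(11, {
    x <- cumsum(rnorm(50))
  })
  x <- as.numeric(scale(x))
  p <- tibble::tibble(amp_a = x, amp_b = x, decay_a = x, decay_b = x,
                      rise_a = x, rise_b = x)
  sh <- shuffle_pairs(p)
  rot <- c(length(x), seq_len(length(x) - 1))
  expect_equal(cor(sh$amp_a, sh$amp_b), cor(x, x[rot]))
})

test_that("the shuffle z-test computes the two-sample Fisher statistic", {
  z0 <- z_test(0.4, 100, 0.4, 100)
  expect_equal(z0$z_observed, 0)
  expect_false(z0$significant)
  expect_error(z_test(0.5, 3, 0.1, 100), "exceed 3")

  zt <- z_test(0.5, 241, 0.05, 241)
  manual <- (fisher_z(0.5) - fisher_z(0.05)) / sqrt(2 / (241 - 3))
  expect_equal(zt$z_observed, manual)
  expect_true(zt$significant)
  expect_equal(zt$critical, 1.96)
})

test_that("property_ztest runs the original-vs-shuffle pipeline end to end", {
  withr::with_seed(13, {
    common <- rnorm(200)
    pairs <- tibble::tibble(
      amp_a = common + rnorm(200, 0, 0.5),
      amp_b = common + rnorm(200, 0, 0.5),
      decay_a = rnorm(200), decay_b = rnorm(200),
      rise_a = rnorm(200), rise_b = rnorm(200))
  })
  zt <- property_ztest(pairs, "amplitude")
  expect_true(zt$significant)
  expect_gt(zt$r_orig, 0.5)
  zd <- property_ztest(pairs, "decay")
  expect_false(zd$significant)
})

test_that("amplitude CDF tables are proper distribution functions", {
  ev <- tibble::tibble(amp_pA = c(5, 7, 9, 11))
  cdf <- amplitude_cdf(ev, breaks = c(4, 6, 8, 10, 12))
  expect_equal(cdf$cum_fraction, c(0, 0.25, 0.5, 0.75, 1))
  expect_true(all(diff(cdf$cum_fraction) >= 0))
})
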