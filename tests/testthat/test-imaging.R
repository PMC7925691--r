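test_that("preprocessing is exact on constants and conserves mass", {
  arr <- array(3, dim = c(6, 10, 10))
  st <- frame_stack(arr, 10, 0.45, stim_onset = 0.3)
  out <- preprocess_stack(st)
  expect_true(all(abs(out$data - 3) < 1e-9))
  expect_equal(dim(out$data)[2:3], c(8, 8)) # round(0.8 * 10)
  expect_equal(out$frame_rate, 20)
  expect_equal(out$pixel_size, 0.45 / 0.8, tolerance = 1e-9)

  # 3x3 Gaussian smoothing alone preserves the mass of an interior spike
  arr2 <- array(0, dim = c(2, 11, 11))
  arr2[, 6, 6] <- 1
  sm <- preprocess_stack(frame_stack(arr2, 10, 0.45, stim_onset = 0.1),
                         resize_factor = 1, time_window = 1,
                         resample_factor = 1)
  expect_equal(sum(sm$data[1, , ]), 1, tolerance = 0.01)

  expect_error(preprocess_stack(frame_stack(array(1, c(1, 4, 4)), 10, 1)),
               "2 frames")
})

test_that("dF/F follows its definition and flags bad baselines", {
  arr <- array(100, dim = c(20, 4, 4))
  arr[15, 2, 3] <- 200
  st <- frame_stack(arr, 10, 0.45, stim_onset = 1)
  d <- dff(st)
  expect_equal(d$data[1, 1, 1], 0)
  expect_equal(d$data[15, 2, 3], 1)
  expect_equal(d$baseline_f0[2, 3], 100)

  arr[, 1, 1] <- 0
  dz <- dff(frame_stack(arr, 10, 0.45, stim_onset = 1))
  expect_true(all(is.na(dz$data[, 1, 1])))
  expect_false(anyNA(dz$data[, 2, 2]))
})

test_that("noise-correlation scores separate shared from independent signals", {
  # identical residuals: strongly suprathreshold scores
  meds <- withr::with_seed(5, {
    vapply(1:100, function(i) {
      x <- matrix(rnorm(4 * 40), 4, 40)
      noise_correlation(x, x)
    }, numeric(1))
  })
  expect_gt(median(meds), 5)

  # independent residuals: mean ~ 0, SD ~ 1 over seeds
  scores <- withr::with_seed(6, {
    vapply(1:500, function(i) {
      noise_correlation(matrix(rnorm(160), 4, 40), matrix(rnorm(160), 4, 40))
    }, numeric(1))
  })
  expect_gt(mean(scores), -0.2)
  expect_lt(mean(scores), 0.2)
  expect_gt(sd(scores), 0.8)
  expect_lt(sd(scores), 1.2)

  expect_error(noise_correlation(matrix(1, 2, 10), matrix(1, 2, 10)),
               "degenerate")
})

test_that("segmentation recovers compact footprints and ignores noise", {
  gen <- gen_movie(movie_spec(n_sites = 2, grid = c(28, 28),
                              shot_noise_sd = 0.02, trials = 6, seed = 21))
  pl <- run_imaging_pipeline(gen, preprocess = FALSE, min_response = 0.1)
  big <- pl$rois$seeds[pl$rois$seeds$n_pixels >= 3, ]
  expect_equal(nrow(big), 2)
  for (s in 1:2) {
    expect_gte(best_jaccard(pl$rois, gen$truth_labels == s), 0.8)
  }

  # all-independent pixels: false merges are rare
  null_gen <- gen_movie(movie_spec(n_sites = 1, grid = c(20, 20),
                                   peak_dff = 0, trials = 4,
                                   directions = c(0, 90, 180, 270),
                                   seed = 33))
  pln <- run_imaging_pipeline(null_gen, preprocess = FALSE)
  merge_rate <- sum(pln$rois$seeds$n_pixels > 1) / nrow(pln$rois$seeds)
  expect_lt(merge_rate, 0.1)
})

test_that("the correlation-scale fit recovers a known Gaussian decay", {
  d <- seq(0, 6, by = 0.25)
  df <- tibble::tibble(distance_um = d, score = 4 * exp(-d^2 / 2))
  fit <- fit_correlation_scale(df)
  expect_equal(fit$lambda_um, sqrt(2), tolerance = 0.01 / sqrt(2))
  expect_equal(fit$sigma_um, 1, tolerance = 0.01)
  expect_equal(fit$amplitude, 4, tolerance = 0.01)

  flat <- tibble::tibble(distance_um = d, score = 1.3)
  expect_error(fit_correlation_scale(flat), "flat|amplitude")
  expect_error(fit_correlation_scale(df[1:3, ]), "5 distance")
})

test_that("the response index matches its defining identity", {
  expect_equal(response_index(5, 1, 2), 0) # R = M0 + 2 SD0
  expect_equal(response_index(3, 0, 0), 1) # zero baseline
  expect_true(is.na(response_index(-2, 0, 1)))
  r <- response_index(c(10, 2), 1, 0.5)
  expect_equal(r, c((10 - 2) / (10 + 2), 0))
})

test_that("direction tuning reproduces the limiting cases", {
  dirs <- seq(0, 315, by = 45)
  # symmetric tuning: DSI 0
  flat <- direction_tuning(rep(2.5, 8), dirs)
  expect_equal(flat$dsi, 0)
  expect_true(is.na(flat$theta_deg))
  # preferred-only tuning: DSI 1
  one <- direction_tuning(c(0, 0, 3, 0, 0, 0, 0, 0), dirs)
  expect_equal(one$dsi, 1)
  expect_equal(one$theta_deg, 90)
  # (3 - 1) / (3 + 1) = 0.5 at theta 0
  half <- direction_tuning(c(3, 0, 0, 0, 1, 0, 0, 0), dirs)
  expect_equal(half$dsi, 0.5)
  expect_equal(half$theta_deg, 0)
  # two equal lobes at 0 and 90: vector sum bisects
  diag <- direction_tuning(c(2, 0, 2, 0, 0, 0, 0, 0), dirs)
  expect_equal(diag$theta_deg, 45)
  # all-zero: flagged
  zero <- direction_tuning(rep(0, 8), dirs)
  expect_true(is.na(zero$dsi) && is.na(zero$theta_deg))
  expect_error(direction_tuning(c(-1, 1), c(0, 180)), "non-negative")
})

test_that("DSI is bounded and theta is scale-invariant", {
  dirs <- seq(0, 315, by = 45)
  withr::with_seed(8, {
    for (i in 1:50) {
      r <- runif(8)
      tun <- direction_tuning(r, dirs)
      expect_gte(tun$dsi, 0)
      expect_lte(tun$dsi, 1)
      tun2 <- direction_tuning(5.7 * r, dirs)
      expect_equal(tun$theta_deg, tun2$theta_deg)
      expect_equal(tun$dsi, tun2$dsi)
    }
  })
})

test_that("varicosity fits recover space constant, center, and decay", {
  px <- 0.28
  xs <- (1:40 - 0.5) * px
  ys <- (1:40 - 0.5) * px
  g <- outer(ys, xs, function(y, x) {
    0.6 * exp(-((x - 5.6)^2 + (y - 5.6)^2) / (2 * 0.87^2))
  })
  fit <- fit_varicosity_profile(g, px)
  expect_equal(fit$space_constant_um, 0.87, tolerance = 0.01 / 0.87)

  # off-center source: fitted center within 0.1 um of truth
  g2 <- outer(ys, xs, function(y, x) {
    0.6 * exp(-((x - 3.1)^2 + (y - 7.9)^2) / (2 * 0.87^2))
  })
  fit2 <- fit_varicosity_profile(g2, px)
  expect_lt(abs(fit2$center_um[["x"]] - 3.1), 0.1)
  expect_lt(abs(fit2$center_um[["y"]] - 7.9), 0.1)

  tc <- tibble::tibble(time_s = seq(0, 2, by = 0.02),
                       dff = 0.5 * exp(-seq(0, 2, by = 0.02) / 0.140))
  fit3 <- fit_varicosity_profile(g, px, timecourse = tc)
  expect_equal(fit3$decay_tau_ms, 140, tolerance = 2 / 140)

  expect_error(fit_varicosity_profile(matrix(1, 3, 3)), "5 x 5")
})

test_that("the Hodges-Ajne test separates concentrated from balanced angles", {
  # all angles in one half-circle: m = 0 and the classical exact tail
  # P(m = 0) = n / 2^(n-1); for n = 10 that is 10/512
  conc <- hodges_ajne(rep(10, 10))
  expect_equal(conc$m, 0)
  expect_equal(conc$p_value, 10 / 512)
  expect_lt(hodges_ajne(rep(10, 12))$p_value, 0.01)

  bal <- hodges_ajne(c(0, 90, 180, 270, 45, 135, 225, 315))
  expect_equal(bal$m, 4)
  expect_equal(bal$p_value, 1)

  expect_error(hodges_ajne(c(1, 2, 3)), "at least 4")

  # near-uniform large sample: no evidence against uniformity
  unif <- hodges_ajne(seq(0, 359, by = 0.5))
  expect_gt(unif$p_value, 0.5)
})

test_that("paired condition comparison flags degenerate input and finds shifts", {
  same <- compare_conditions(c(1, 2, 3), c(1, 2, 3))
  expect_true(same$degenerate)
  expect_true(is.na(same$p_value))

  withr::with_seed(9, {
    ctrl <- rnorm(700, 0.35, 0.1)
    drug <- ctrl - 0.16 + rnorm(700, 0, 0.03)
  })
  res <- compare_conditions(ctrl, drug)
  expect_lt(res$p_value, 1e-10)
  expect_false(res$degenerate)
})

test_that("tidiers and autoplot methods produce well-formed output", {
  d <- seq(0, 6, by = 0.5)
  fit <- fit_correlation_scale(tibble::tibble(distance_um = d,
                                              score = 3 * exp(-d^2 / 2)))
  td <- tidy(fit)
  expect_true(all(c("distance_um", "score", "fitted") %in% names(td)))
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(glance(fit), "tbl_df")

  ha <- hodges_ajne(rep(45, 8))
  expect_named(tidy(ha), c("m", "n", "p_value", "method"))
  expect_s3_class(plot_tuning(c(3, 0, 0, 0, 1, 0, 0, 0),
                              seq(0, 315, by = 45)), "ggplot")
})

test_that("untuned release sites yield near-zero DSI end to end", {
  sp <- rbind(c(4.5, 4.5), c(13.5, 4.5), c(4.5, 13.5), c(13.5, 13.5))
  gen0 <- gen_movie(movie_spec(grid = c(40, 40), site_positions = sp,
                               tuning_kappa = 0, seed = 14))
  pl0 <- run_imaging_pipeline(gen0, preprocess = TRUE)
  t0 <- roi_tuning(pl0$rois, pl0$dffs)
  t0 <- t0[t0$responsive & t0$n_pixels >= 3, ]
  expect_gte(nrow(t0), 4)
  expect_true(all(t0$dsi < 0.15))
})
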