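test_that("segment resampling conserves cable length and counts", {
  sk <- make_line_skeleton(10)
  seg <- resample_segments(sk, 1)
  expect_equal(nrow(seg), 10)
  expect_equal(sum(seg$length_um), 10)
  expect_equal(seg$x, seq(0.5, 9.5, by = 1))
  expect_true(all(seg$y == 0) && all(seg$z == 0))

  # terminal remainder >= seg_len / 2 is kept
  sk2 <- make_line_skeleton(10.6)
  expect_equal(nrow(resample_segments(sk2, 1)), 11)
  sk3 <- make_line_skeleton(10.4)
  expect_equal(nrow(resample_segments(sk3, 1)), 10)

  expect_error(resample_segments(sk, 0), "seg_len")
})

test_that("curved branches resample to the arc-length prediction", {
  # quarter circle of radius 20 um: arc length 10*pi
  th <- seq(0, pi / 2, length.out = 200)
  sk <- as_skeleton(tibble::tibble(
    node_id = seq_along(th), type = 3L,
    x = 20 * cos(th), y = 20 * sin(th), z = 0, radius = 0.5,
    parent = c(-1L, seq_along(th)[-length(th)])))
  seg <- resample_segments(sk, 1)
  arc <- sum(sqrt(rowSums(diff(cbind(20 * cos(th), 20 * sin(th)))^2)))
  expect_lte(abs(nrow(seg) - arc / 1), 1)
  # cable length conserved up to the dropped sub-half-segment remainder
  expect_lt(abs(sum(seg$length_um) - arc), 1)
})

test_that("skeleton pairs round-trip through SWC", {
  pair <- gen_arbor_pair(arbor_pair_spec(field_radius = 40, branch_count = 6,
                                         seed = 2))
  path <- withr::local_tempfile(fileext = ".swc")
  write_swc(pair$skeleton_a, path)
  back <- read_swc(path)
  expect_equal(back$x, pair$skeleton_a$x, tolerance = 1e-6)
  expect_equal(back$parent, pair$skeleton_a$parent)
  dendrite <- back$type != 1L   # soma rows carry no stratum information
  expect_equal(back$arbor_label[dendrite],
               pair$skeleton_a$arbor_label[dendrite])
})

test_that("nearest-neighbor distances honor simple geometry", {
  sk <- make_line_skeleton(20)
  seg <- resample_segments(sk)
  same <- nnd(seg, seg)
  expect_true(all(same$segments$nnd_um == 0))

  off <- resample_segments(make_line_skeleton(20, y0 = 3))
  par <- nnd(seg, off)
  expect_equal(par$segments$nnd_um, rep(3, nrow(seg)))

  expect_error(nnd(seg[0, ], seg), "non-empty")
})

test_that("the grid index equals exhaustive search on random instances", {
  withr::with_seed(19, {
    for (rep in 1:10) {
      A <- cbind(runif(200, 0, 60), runif(200, 0, 60), runif(200, 0, 10))
      B <- cbind(runif(180, 10, 70), runif(180, -10, 50), runif(180, 0, 10))
      segs_a <- tibble::tibble(segment_id = 1:200, x = A[, 1], y = A[, 2],
                               z = A[, 3], length_um = 1, arbor_label = "ON",
                               cell_id = "a")
      segs_b <- tibble::tibble(segment_id = 1:180, x = B[, 1], y = B[, 2],
                               z = B[, 3], length_um = 1, arbor_label = "ON",
                               cell_id = "b")
      g <- nnd(segs_a, segs_b, method = "grid")$segments$nnd_um
      e <- nnd(segs_a, segs_b, method = "exhaustive")$segments$nnd_um
      expect_equal(g, e, tolerance = 1e-12)
    }
  })
})

test_that("overlap fractions are CDF values averaged over strata", {
  seg <- resample_segments(make_line_skeleton(20))
  p3 <- nnd(seg, resample_segments(make_line_skeleton(20, y0 = 3)))
  p0 <- nnd(seg, seg)
  expect_equal(overlap_fraction(p3, p3, 2), 0)
  expect_equal(overlap_fraction(p3, p3, 3), 1)
  expect_equal(overlap_fraction(p3, p3, 100), 1)
  expect_equal(overlap_fraction(p0, p3, 1), 0.5) # mean of 1 and 0
  # monotone in d, and negative d falls back to the contact bin
  ds <- c(0, 1, 2, 3, 4)
  fr <- overlap_fraction(p3, p0, ds)
  expect_true(all(diff(fr) >= 0))
  expect_equal(overlap_fraction(p3, p3, -1), overlap_fraction(p3, p3, 0))
})

test_that("NND profiles are directional and the CDF is proper", {
  pair <- gen_arbor_pair(arbor_pair_spec(field_radius = 50, branch_count = 10,
                                         cofasciculation = 0.5, seed = 7))
  res <- arbor_nnd(pair$skeleton_a, pair$skeleton_b, distances = 0:3)
  ab <- res$profiles$a_to_b$ON$segments$nnd_um
  ba <- res$profiles$b_to_a$ON$segments$nnd_um
  expect_false(length(ab) == length(ba) && isTRUE(all.equal(ab, ba)))
  for (pr in unlist(res$profiles, recursive = FALSE)) {
    expect_true(all(diff(pr$cdf$fraction) >= 0))
    expect_equal(tail(pr$cdf$fraction, 1), 1)
    expect_true(all(pr$segments$nnd_um >= 0))
  }
  expect_equal(nrow(res$overlap), 8)
})

test_that("structure-function comparison flags the matching distance", {
  # identical fractions and strengths: zero difference, p = 1
  fr <- tidyr::expand_grid(pair_id = 1:4, distance_um = 0:3)
  fr$fraction <- rep(c(0.1, 0.3, 0.5, 0.7), each = 4)[seq_len(nrow(fr))]
  fr$fraction <- ifelse(fr$distance_um == 1, 0.2 * fr$pair_id, fr$fraction)
  st <- tibble::tibble(pair_id = 1:4, strength = 0.2 * (1:4))
  out <- structure_function_compare(fr, st)
  d1 <- out[out$distance_um == 1, ]
  expect_equal(d1$mean_difference, 0)
  expect_equal(d1$p_value, 1)
  expect_true(d1$best_match)

  expect_error(structure_function_compare(fr, st[1:2, ]), "at least 3")
  st_gap <- tibble::tibble(pair_id = c(1, 2, 3, 9), strength = 0.1)
  expect_error(structure_function_compare(fr, st_gap), "strength")
})

test_that("correlation strength tracks the sub-micron overlap fraction", {
  # pairs constructed so that the shared vesicle fraction equals the
  # <= 1 um dendritic overlap: the physiology should match anatomy at 1 um
  cfs <- c(0.15, 0.45, 0.8)
  rows <- list()
  strengths <- numeric(length(cfs))
  for (i in seq_along(cfs)) {
    ap <- gen_arbor_pair(arbor_pair_spec(
      field_radius = 60, branch_count = 15, cofasciculation = cfs[i],
      seed = 50 + i))
    res <- arbor_nnd(ap$skeleton_a, ap$skeleton_b, distances = 0:3)
    ov <- res$overlap[res$overlap$direction == "a_to_b", ]
    frac1 <- ov$fraction[ov$distance_um == 1]
    tp <- gen_paired_traces(paired_train_spec(
      duration = 240, shared_fraction = frac1, seed = 60 + i))
    tr_a <- lowpass(tp$trace_a)
    tr_b <- lowpass(tp$trace_b)
    ev <- detect_events(tr_a, 5)
    strengths[i] <- sepsc_triggered_average(ev, tr_a, tr_b)$correlation_strength
    rows[[i]] <- tibble::tibble(pair_id = i, distance_um = ov$distance_um,
                                fraction = ov$fraction)
  }
  cmp <- structure_function_compare(
    dplyr::bind_rows(rows),
    tibble::tibble(pair_id = seq_along(cfs), strength = strengths))
  expect_equal(cmp$distance_um[cmp$best_match], 1)
})
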