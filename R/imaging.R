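#' Preprocess a fluorescence frame stack
#'
#' Standard conditioning for sensor movies: per-frame 3 x 3 Gaussian
#' smoothing, spatial down-sampling by `resize_factor` (bilinear), a 2-bin
#' temporal moving average, and linear-interpolation resampling onto a
#' uniform grid at `resample_factor` times the native frame rate.
#'
#' @param stack A [frame_stack()].
#' @param kernel_sigma SD (pixels) of the 3 x 3 Gaussian kernel.
#' @param resize_factor Spatial down-sampling factor.
#' @param time_window Moving-average window (frames).
#' @param resample_factor Temporal up-sampling factor after smoothing.
#' @return A preprocessed [frame_stack()] with updated `frame_rate` and
#'   `pixel_size`.
#' @export
preprocess_stack <- function(stack, kernel_sigma = 0.8, resize_factor = 0.8,
                             time_window = 2, resample_factor = 2) {
  d <- dim(stack$data)
  if (d[1] < 2) abort("Need at least 2 frames.")
  H <- d[2]; W <- d[3]; T_ <- d[1]
  g <- dnorm(-1:1, 0, kernel_sigma)
  kern <- outer(g, g)
  kern <- kern / sum(kern)
  arr <- aperm(stack$data, c(2, 3, 1))            # H x W x T
  arr <- EBImage::filter2(arr, kern, boundary = "replicate")
  newH <- max(1L, round(resize_factor * H))
  newW <- max(1L, round(resize_factor * W))
  arr <- EBImage::resize(arr, w = newH, h = newW, filter = "bilinear")
  X <- matrix(arr, newH * newW, T_, byrow = FALSE)
  X <- t(X)                                        # T x pixels
  # causal moving average over `time_window` frames
  if (time_window > 1) {
    Xs <- stats::filter(X, rep(1 / time_window, time_window), sides = 1)
    Xs[seq_len(time_window - 1L), ] <- X[seq_len(time_window - 1L), ]
    X <- Xs
  }
  t_old <- (seq_len(T_) - 0.5) / stack$frame_rate
  new_rate <- stack$frame_rate * resample_factor
  t_new <- seq(t_old[1], t_old[T_], by = 1 / new_rate)
  Wmat <- interp_matrix(t_old, t_new)
  X <- Wmat %*% X
  out <- array(as.numeric(X), dim = c(length(t_new), newH, newW))
  frame_stack(out, new_rate, stack$pixel_size / resize_factor,
              direction = stack$direction, trial_id = stack$trial_id,
              stim_onset = stack$stim_onset)
}

# dense linear-interpolation matrix mapping samples at t_old to t_new
interp_matrix <- function(t_old, t_new) {
  n <- length(t_old)
  Wm <- matrix(0, length(t_new), n)
  j <- findInterval(t_new, t_old, all.inside = TRUE)
  w <- (t_new - t_old[j]) / (t_old[j + 1] - t_old[j])
  w <- pmin(1, pmax(0, w))
  for (i in seq_along(t_new)) {
    Wm[i, j[i]] <- 1 - w[i]
    Wm[i, j[i] + 1] <- Wm[i, j[i] + 1] + w[i]
  }
  Wm
}

#' Baseline-normalized fluorescence change
#'
#' Computes `dF/F(t) = (F(t) - F0) / F0` per pixel, with `F0` the mean
#' fluorescence in a window (1 s by default) immediately preceding
#' stimulus onset. Pixels with non-positive baseline are flagged invalid
#' (`NA`).
#'
#' @param stack A [frame_stack()] with a finite `stim_onset`.
#' @param baseline_window Length of the pre-stimulus baseline window (s).
#' @return A [frame_stack()] whose `data` holds dF/F, with the baseline
#'   matrix in `$baseline_f0` and `$is_dff = TRUE`.
#' @export
dff <- function(stack, baseline_window = 1) {
  if (is.na(stack$stim_onset)) abort("`stim_onset` is required for dF/F.")
  t_s <- (seq_len(dim(stack$data)[1]) - 0.5) / stack$frame_rate
  sel <- t_s < stack$stim_onset & t_s >= stack$stim_onset - baseline_window
  if (!any(sel)) abort("Baseline window contains no pre-stimulus frames.")
  f0 <- apply(stack$data[sel, , , drop = FALSE], c(2, 3), mean)
  bad <- f0 <= 0
  f0_safe <- ifelse(bad, NA_real_, f0)
  d <- sweep(stack$data, c(2, 3), f0_safe, "-")
  d <- sweep(d, c(2, 3), f0_safe, "/")
  out <- frame_stack(d, stack$frame_rate, stack$pixel_size,
                     direction = stack$direction, trial_id = stack$trial_id,
                     stim_onset = stack$stim_onset)
  out$baseline_f0 <- f0
  out$is_dff <- TRUE
  out
}

#' Trial-to-trial residuals of a movie set
#'
#' For each stimulus direction, subtracts the across-trial mean movie from
#' every trial (leaving the trial-to-trial fluctuations around the mean
#' response) and flattens the result for noise-correlation analysis.
#'
#' @param dff_stacks A list of dF/F [frame_stack()]s (see [dff()]) sharing
#'   one geometry; trials of the same `direction` form a group.
#' @return An object of class `pixel_residuals`: list with `resid`
#'   (matrix pixels x (series * frames), column-major pixel order),
#'   `series_len`, `n_series`, `dims` = c(H, W).
#' @export
pixel_residuals <- function(dff_stacks) {
  dirs <- vapply(dff_stacks, function(s) as.numeric(s$direction), numeric(1))
  dims <- dim(dff_stacks[[1]]$data)
  groups <- split(seq_along(dff_stacks), dirs)
  res_list <- list()
  for (g in groups) {
    if (length(g) < 2) next  # residual undefined with one trial
    arr <- vapply(g, function(i) dff_stacks[[i]]$data,
                  array(0, dims))                          # T x H x W x trials
    mean_arr <- apply(arr, 1:3, mean)
    for (k in seq_along(g)) {
      r <- arr[, , , k] - mean_arr
      m <- matrix(aperm(r, c(2, 3, 1)), dims[2] * dims[3], dims[1])
      res_list[[length(res_list) + 1]] <- m
    }
  }
  if (!length(res_list)) abort("Need at least 2 trials per direction.")
  structure(
    list(resid = do.call(cbind, res_list), series_len = dims[1],
         n_series = length(res_list), dims = dims[2:3]),
    class = "pixel_residuals"
  )
}

# normalized cross-correlation scores for many pixel pairs at once.
# Each trial series is centered and normalized (so its lag-0 autoproduct is
# the Pearson r), then the series are concatenated with lag_max zeros of
# padding; shifting the padded rows computes every per-series CCF in one
# vectorized pass, summed across series.
pair_scores <- function(res, p_idx, q_idx, lag_max = NULL) {
  T_ <- res$series_len
  S <- res$n_series
  if (is.null(lag_max)) lag_max <- floor(T_ / 2)
  lag_max <- min(lag_max, T_ - 1L)
  lags <- -lag_max:lag_max
  P <- length(p_idx)
  pad <- matrix(0, P, lag_max)
  norm_block <- function(idx, cols) {
    X <- res$resid[idx, cols, drop = FALSE]
    X <- X - rowMeans(X)
    X / (sqrt(rowMeans(X^2)) * sqrt(T_))
  }
  Xp <- matrix(0, P, 0)
  Yp <- matrix(0, P, 0)
  for (s in seq_len(S)) {
    cols <- ((s - 1) * T_ + 1):(s * T_)
    Xp <- cbind(Xp, norm_block(p_idx, cols), pad)
    Yp <- cbind(Yp, norm_block(q_idx, cols), pad)
  }
  N <- ncol(Xp)
  cc <- matrix(0, P, length(lags))
  for (li in seq_along(lags)) {
    tau <- lags[li]
    if (tau >= 0) {
      cc[, li] <- rowSums(Xp[, seq_len(N - tau), drop = FALSE] *
                            Yp[, seq.int(1 + tau, N), drop = FALSE])
    } else {
      cc[, li] <- rowSums(Xp[, seq.int(1 - tau, N), drop = FALSE] *
                            Yp[, seq_len(N + tau), drop = FALSE])
    }
  }
  cc <- cc / S
  mid <- lag_max + 1L
  sds <- apply(cc, 1, sd)
  (cc[, mid] - rowMeans(cc)) / sds
}

#' Noise-correlation score of two residual series
#'
#' The lag-zero value of the cross-correlation function between two
#' trial-residual series, standardized by the mean and SD of the
#' cross-correlation function over lags:
#' `C = (c_tau0 - M_c) / SD_c`. Scores near 0 with unit SD are expected
#' for independent pixels; shared signal concentrates correlation at lag
#' zero and drives the score up. A score threshold of 2.5 is the usual
#' gate for merging pixels into one region of interest.
#'
#' @param x,y Residual series: numeric vectors, or matrices with one
#'   series per row (e.g. one row per trial). Rows are centered and the
#'   per-trial cross-correlation functions averaged before scoring.
#' @param lag_max Maximum lag (samples); defaults to half the series.
#' @return The score (scalar).
#' @export
noise_correlation <- function(x, y, lag_max = NULL) {
  if (is.vector(x)) x <- matrix(x, 1)
  if (is.vector(y)) y <- matrix(y, 1)
  if (!identical(dim(x), dim(y))) abort("`x` and `y` must have equal dimensions.")
  res <- structure(
    list(resid = rbind(as.vector(t(x)), as.vector(t(y))),
         series_len = ncol(x), n_series = nrow(x), dims = c(1, 2)),
    class = "pixel_residuals")
  sc <- pair_scores(res, 1L, 2L, lag_max = lag_max)
  if (!is.finite(sc)) abort("Cross-correlation function is degenerate (constant signal).")
  sc
}

#' Segment pixels into ROIs by seeded noise-correlation growth
#'
#' Greedy seeded region growing: the unassigned pixel with the highest
#' response seeds a new ROI; its 8-connected neighbors (and, iteratively,
#' neighbors of accepted pixels) join while their noise-correlation score
#' *with the seed pixel* exceeds `threshold`. When no neighbor qualifies
#' the next unassigned pixel seeds the next ROI, until every eligible
#' pixel is labelled. Comparing candidates to the seed (rather than a
#' running mean) keeps the rule order-independent.
#'
#' @param residuals A [pixel_residuals()] object.
#' @param response H x W matrix used to rank seed pixels (e.g. maximum
#'   trial-averaged dF/F across directions).
#' @param threshold Score threshold for joining (default 2.5).
#' @param lag_max Passed to the score computation.
#' @param min_response Pixels below this response never seed an ROI and
#'   stay unassigned (label 0).
#' @return An object of class `roi_map`: list with `labels` (integer
#'   H x W), `seeds` tibble (`roi_id`, `row`, `col`, `response`,
#'   `n_pixels`), and `threshold`.
#' @export
segment_rois <- function(residuals, response, threshold = 2.5,
                         lag_max = NULL, min_response = -Inf) {
  dims <- residuals$dims
  H <- dims[1]; W <- dims[2]
  if (!H || !W) {
    return(structure(list(labels = matrix(integer(0), 0, 0),
                          seeds = tibble(), threshold = threshold),
                     class = "roi_map"))
  }
  stopifnot(all(dim(response) == dims))
  labels <- matrix(0L, H, W)
  ord <- order(response, decreasing = TRUE)
  ord <- ord[response[ord] >= min_response]
  px_rc <- function(p) c((p - 1L) %% H + 1L, (p - 1L) %/% H + 1L)
  neighbors8 <- function(p) {
    rc <- px_rc(p)
    dr <- rep(-1:1, times = 3)
    dc <- rep(-1:1, each = 3)
    rr <- rc[1] + dr
    cc <- rc[2] + dc
    ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W & !(dr == 0 & dc == 0)
    (cc[ok] - 1L) * H + rr[ok]
  }
  seeds <- list()
  roi <- 0L
  for (seed in ord) {
    if (labels[seed] != 0L) next
    roi <- roi + 1L
    labels[seed] <- roi
    members <- seed
    frontier <- seed
    repeat {
      cand <- unique(unlist(lapply(frontier, neighbors8)))
      cand <- cand[labels[cand] == 0L]
      if (!length(cand)) break
      sc <- pair_scores(residuals, rep(seed, length(cand)), cand,
                        lag_max = lag_max)
      acc <- cand[!is.na(sc) & sc > threshold]
      if (!length(acc)) break
      labels[acc] <- roi
      members <- c(members, acc)
      frontier <- acc
    }
    rc <- px_rc(seed)
    seeds[[roi]] <- tibble(roi_id = roi, row = rc[1], col = rc[2],
                           response = response[seed],
                           n_pixels = length(members))
  }
  structure(list(labels = labels, seeds = bind_rows(seeds),
                 threshold = threshold),
            class = "roi_map")
}

#' @export
print.roi_map <- function(x, ...) {
  multi <- sum(x$seeds$n_pixels > 1)
  cat(sprintf("<roi_map> %d ROIs (%d multi-pixel) over %dx%d px, threshold %.2f\n",
              nrow(x$seeds), multi, nrow(x$labels), ncol(x$labels),
              x$threshold))
  invisible(x)
}

#' Response-quality index
#'
#' `RI = (R - (M0 + 2 SD0)) / (R + (M0 + 2 SD0))`: the peak response
#' contrasted against the pre-stimulus mean plus two standard deviations.
#' An ROI is deemed responsive when any direction's RI exceeds 0.6.
#'
#' @param r Peak response amplitude(s) during the stimulus.
#' @param m0 Pre-stimulus mean (same units).
#' @param sd0 Pre-stimulus SD.
#' @return RI value(s); `NA` where the denominator is non-positive.
#' @export
response_index <- function(r, m0, sd0) {
  base <- m0 + 2 * sd0
  den <- r + base
  ifelse(is.finite(den) & den > 0, (r - base) / den, NA_real_)
}

#' Direction tuning from per-direction response amplitudes
#'
#' The preferred angle `theta` is the quadrant-correct vector-sum
#' direction, `atan2(sum(R_i sin i), sum(R_i cos i))`; the preferred and
#' null responses are the responses at the sampled directions nearest
#' `theta` and `theta + 180`, and
#' `DSI = (R_pref - R_null) / (R_pref + R_null)`, ranging from 0
#' (symmetric response) to 1 (response only in the preferred direction).
#' When the resultant vector vanishes (perfectly symmetric tuning) `theta`
#' is undefined (`NA`) and the direction of the largest response is used
#' to anchor the preferred/null lookup, which leaves the DSI at 0 for an
#' all-equal curve.
#'
#' @param responses Non-negative response amplitudes, one per direction.
#' @param directions Stimulus directions (deg), same length.
#' @return A one-row tibble: `dsi`, `theta_deg`, `r_pref`, `r_null`,
#'   `pref_dir`, `null_dir`, `resultant`.
#' @export
#' @examples
#' direction_tuning(c(3, 0, 0, 0, 1, 0, 0, 0), seq(0, 315, by = 45)) # DSI 0.5
direction_tuning <- function(responses, directions) {
  if (length(responses) != length(directions) || length(responses) < 2) {
    abort("Need responses for at least 2 directions.")
  }
  if (any(responses < 0)) abort("Responses must be non-negative.")
  if (all(responses == 0)) {
    return(tibble(dsi = NA_real_, theta_deg = NA_real_, r_pref = 0,
                  r_null = 0, pref_dir = NA_real_, null_dir = NA_real_,
                  resultant = 0))
  }
  th <- directions * pi / 180
  xs <- sum(responses * cos(th))
  ys <- sum(responses * sin(th))
  L <- sqrt(xs^2 + ys^2)
  degenerate <- L < 1e-9 * sum(responses)
  theta <- if (degenerate) NA_real_ else (atan2(ys, xs) * 180 / pi) %% 360
  anchor <- if (degenerate) directions[which.max(responses)] else theta
  ang_dist <- function(a, b) {
    d <- abs((a - b) %% 360)
    pmin(d, 360 - d)
  }
  d1 <- directions[which.min(ang_dist(directions, anchor))]
  d2 <- directions[which.min(ang_dist(directions, (anchor + 180) %% 360))]
  r1 <- responses[match(d1, directions)]
  r2 <- responses[match(d2, directions)]
  # "preferred" is by definition the larger of the axis pair, so the index
  # stays in [0, 1] even for multi-lobed curves whose resultant points at a
  # local dip
  if (r2 > r1) { tmp <- d1; d1 <- d2; d2 <- tmp; tmp <- r1; r1 <- r2; r2 <- tmp }
  pref_dir <- d1; null_dir <- d2; r_pref <- r1; r_null <- r2
  dsi <- if (r_pref + r_null > 0) (r_pref - r_null) / (r_pref + r_null) else NA_real_
  tibble(dsi = dsi, theta_deg = theta, r_pref = r_pref, r_null = r_null,
         pref_dir = pref_dir, null_dir = null_dir, resultant = L)
}

#' Per-ROI direction tuning from a movie set
#'
#' For each ROI, averages dF/F over member pixels, takes the across-trial
#' mean per direction, measures the peak response during the stimulus and
#' the pre-stimulus mean/SD, and combines [response_index()] and
#' [direction_tuning()].
#'
#' @param roi_map A [segment_rois()] result.
#' @param dff_stacks List of dF/F [frame_stack()]s (one per
#'   trial x direction).
#' @param ri_threshold Responsiveness gate on the best direction's RI.
#' @return A tibble with one row per ROI: `roi_id`, `n_pixels`, `dsi`,
#'   `theta_deg`, `ri_max`, `responsive`, plus a nested `responses`
#'   tibble (`direction`, `response`, `ri`).
#' @export
roi_tuning <- function(roi_map, dff_stacks, ri_threshold = 0.6) {
  labels <- roi_map$labels
  H <- nrow(labels); W <- ncol(labels)
  rois <- sort(unique(labels[labels > 0]))
  if (!length(rois)) return(tibble())
  dirs <- vapply(dff_stacks, function(s) as.numeric(s$direction), numeric(1))
  u_dirs <- sort(unique(dirs))
  # pixel-to-ROI averaging matrix: one pass of matrix algebra per stack
  Mx <- matrix(0, H * W, length(rois))
  for (k in seq_along(rois)) {
    members <- which(labels == rois[k])
    Mx[members, k] <- 1 / length(members)
  }
  # per-ROI traces, one T x roi matrix per stack
  stack_traces <- lapply(dff_stacks, function(st) {
    d <- st$data
    matrix(d, dim(d)[1], H * W) %*% Mx
  })
  st1 <- dff_stacks[[1]]
  t_s <- (seq_len(dim(st1$data)[1]) - 0.5) / st1$frame_rate
  stim <- t_s >= st1$stim_onset
  pre <- t_s < st1$stim_onset
  out <- purrr::map_dfr(seq_along(rois), function(k) {
    per_dir <- purrr::map_dfr(u_dirs, function(dd) {
      idx <- which(dirs == dd)
      trials_k <- vapply(idx, function(i) stack_traces[[i]][, k],
                         numeric(length(t_s)))
      mtr <- rowMeans(trials_k)
      r_pk <- max(mtr[stim])
      # baseline statistics pool the per-trial pre-stimulus signals; the
      # trial-averaged trace would understate the noise the response is
      # judged against
      pre_samples <- as.vector(trials_k[pre, , drop = FALSE])
      tibble(direction = dd, response = max(0, r_pk),
             ri = response_index(r_pk, mean(pre_samples), sd(pre_samples)))
    })
    tun <- direction_tuning(per_dir$response, per_dir$direction)
    tibble(roi_id = rois[k], n_pixels = sum(labels == rois[k]),
           dsi = tun$dsi, theta_deg = tun$theta_deg,
           ri_max = max(per_dir$ri, na.rm = TRUE),
           responsive = isTRUE(max(per_dir$ri, na.rm = TRUE) > ri_threshold),
           responses = list(per_dir))
  })
  out
}

#' Fit the spatial decay of noise correlations
#'
#' Least-squares fit of `A * exp(-d^2 / (2 sigma^2)) + b` to
#' noise-correlation scores versus pixel separation; the spatial scale is
#' reported as the 1/e half-width `lambda = sigma * sqrt(2)`.
#'
#' @param data Data frame with columns `distance_um` and `score`.
#' @param bin_width Optional bin width (um); when given, scores are
#'   averaged in distance bins before fitting.
#' @return An object of class `scale_fit`: `lambda_um`, `sigma_um`,
#'   `amplitude`, `offset`, `n`, and the binned/raw `data` used.
#' @export
fit_correlation_scale <- function(data, bin_width = NULL) {
  df <- tibble(distance_um = data$distance_um, score = data$score)
  df <- df[stats::complete.cases(df), ]
  if (!is.null(bin_width)) {
    df <- df |>
      mutate(bin = floor(.data$distance_um / bin_width)) |>
      group_by(.data$bin) |>
      summarise(distance_um = mean(.data$distance_um),
                score = mean(.data$score), .groups = "drop") |>
      select(-dplyr::any_of("bin"))
  }
  if (nrow(df) < 5) abort("Need scores in at least 5 distance bins.")
  if (diff(range(df$score)) < 1e-12) {
    abort("Scores are flat; no spatial decay to fit (amplitude ~ 0).")
  }
  a0 <- max(df$score) - min(df$score)
  b0 <- min(df$score)
  s0 <- max(df$distance_um) / 3
  fit <- tryCatch(
    minpack.lm::nlsLM(
      score ~ A * exp(-distance_um^2 / (2 * s^2)) + b,
      data = df, start = list(A = a0, s = s0, b = b0),
      lower = c(A = 0, s = 1e-6, b = -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) abort(paste("Correlation-scale fit failed:",
                                    conditionMessage(e))))
  cf <- coef(fit)
  if (cf[["A"]] < 1e-6 * max(abs(df$score), 1e-12)) {
    abort("Correlation-scale fit rejected: amplitude ~ 0.")
  }
  structure(
    list(lambda_um = unname(cf[["s"]]) * sqrt(2), sigma_um = unname(cf[["s"]]),
         amplitude = unname(cf[["A"]]), offset = unname(cf[["b"]]),
         n = nrow(df), data = df),
    class = "scale_fit"
  )
}

#' @export
print.scale_fit <- function(x, ...) {
  cat(sprintf("<scale_fit> lambda = %.3f um (sigma %.3f, A %.2f, b %.2f; n=%d)\n",
              x$lambda_um, x$sigma_um, x$amplitude, x$offset, x$n))
  invisible(x)
}

#' Spatial and temporal profile of a single release-site response
#'
#' Fits an elliptical (axis-aligned) 2D Gaussian plus offset to a map of
#' peak sensor responses; the space constant is the geometric mean of the
#' two fitted SDs (the "1 SD contour" scale). Optionally fits a single
#' exponential to the post-peak decay of a response timecourse.
#'
#' @param peak_map H x W matrix of peak dF/F values.
#' @param pixel_size Pixel size (um).
#' @param timecourse Optional tibble with `time_s` and `dff`; must have at
#'   least 10 frames after its peak.
#' @return An object of class `varicosity_fit`: `space_constant_um`,
#'   `sx_um`, `sy_um`, `center_um` (x, y), `amplitude`, `offset`,
#'   `decay_tau_ms` (`NA` without a timecourse).
#' @export
fit_varicosity_profile <- function(peak_map, pixel_size = 1,
                                   timecourse = NULL) {
  H <- nrow(peak_map); W <- ncol(peak_map)
  if (H < 5 || W < 5) abort("Peak map must be at least 5 x 5 pixels.")
  xs <- (seq_len(W) - 0.5) * pixel_size
  ys <- (seq_len(H) - 0.5) * pixel_size
  df <- tibble(x = rep(xs, each = H), y = rep(ys, times = W),
               z = as.vector(peak_map))
  df <- df[is.finite(df$z), ]
  imax <- which.max(df$z)
  start <- list(A = max(df$z) - min(df$z), x0 = df$x[imax], y0 = df$y[imax],
                sx = 2 * pixel_size, sy = 2 * pixel_size, b = min(df$z))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      z ~ A * exp(-((x - x0)^2 / (2 * sx^2) + (y - y0)^2 / (2 * sy^2))) + b,
      data = df, start = start,
      lower = c(A = 0, x0 = min(xs) - 2, y0 = min(ys) - 2,
                sx = 0.05 * pixel_size, sy = 0.05 * pixel_size, b = -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) {
      abort(paste0("Spatial Gaussian fit failed: ", conditionMessage(e),
                   " (map range ", signif(diff(range(df$z)), 3), ")"))
    })
  cf <- coef(fit)
  tau <- NA_real_
  if (!is.null(timecourse)) {
    tc <- tibble(time_s = timecourse$time_s, dff = timecourse$dff)
    ipk <- which.max(tc$dff)
    post <- tc[ipk:nrow(tc), ]
    if (nrow(post) < 10) abort("Timecourse needs at least 10 frames after its peak.")
    tt <- (post$time_s - post$time_s[1]) * 1000
    dfit <- tryCatch(
      minpack.lm::nlsLM(dff ~ A * exp(-tt / tau), data = post,
                        start = list(A = post$dff[1],
                                     tau = max(tt[2], diff(range(tt)) / 3)),
                        lower = c(A = 0, tau = 1e-3)),
      error = function(e) abort(paste("Decay fit failed:", conditionMessage(e))))
    tau <- unname(coef(dfit)[["tau"]])
  }
  structure(
    list(space_constant_um = sqrt(cf[["sx"]] * cf[["sy"]]),
         sx_um = unname(cf[["sx"]]), sy_um = unname(cf[["sy"]]),
         center_um = c(x = unname(cf[["x0"]]), y = unname(cf[["y0"]])),
         amplitude = unname(cf[["A"]]), offset = unname(cf[["b"]]),
         decay_tau_ms = tau),
    class = "varicosity_fit"
  )
}

#' @export
print.varicosity_fit <- function(x, ...) {
  cat(sprintf(
    "<varicosity_fit> space constant %.3f um (center %.2f, %.2f); decay tau %s ms\n",
    x$space_constant_um, x$center_um[1], x$center_um[2],
    ifelse(is.na(x$decay_tau_ms), "NA", sprintf("%.1f", x$decay_tau_ms))))
  invisible(x)
}

# minimum count over all closed half-circles, O(n log n)
ajne_m <- function(theta) {
  n <- length(theta)
  th <- sort(theta %% (2 * pi))
  ext <- c(th, th + 2 * pi)
  idx <- seq_len(n)
  j1 <- findInterval(th + pi - 1e-12, ext)
  c1 <- j1 - idx + 1L          # points in [th_i, th_i + pi)
  j2 <- findInterval(th + pi + 1e-12, ext)
  c2 <- j2 - idx               # points in (th_i, th_i + pi]
  min(pmin(c1, n - c1), pmin(c2, n - c2))
}

#' Hodges-Ajne test of angular uniformity
#'
#' Non-parametric test based on `m`, the minimum number of observations in
#' any closed half-circle: concentrated angle distributions give small
#' `m`, uniform ones give `m` near `n / 2`. For `m < n / 3` the exact
#' tail probability `p = 2^(1-n) (n - 2m) C(n, m)` applies; outside that
#' range the null distribution is evaluated by Monte-Carlo simulation of
#' uniform samples (RNG state restored afterwards). The maximal statistic
#' `m = floor(n / 2)` carries no evidence against uniformity (`p = 1`).
#'
#' @param angles_deg Angles in degrees (n >= 4).
#' @param n_sim Monte-Carlo draws for the out-of-range branch.
#' @param mc_seed Seed for the Monte-Carlo branch.
#' @return A list of class `hodges_ajne`: `m`, `n`, `p_value`, `method`.
#' @export
hodges_ajne <- function(angles_deg, n_sim = 10000, mc_seed = 1L) {
  n <- length(angles_deg)
  if (n < 4) abort("Need at least 4 angles.")
  theta <- angles_deg * pi / 180
  m <- ajne_m(theta)
  if (m >= floor(n / 2)) {
    p <- 1
    method <- "maximal statistic"
  } else if (m < n / 3) {
    p <- min(1, exp(log(n - 2 * m) + lchoose(n, m) + (1 - n) * log(2)))
    method <- "exact"
  } else {
    sims <- withr::with_seed(mc_seed, {
      vapply(seq_len(n_sim), function(i) ajne_m(runif(n, 0, 2 * pi)),
             numeric(1))
    })
    p <- (1 + sum(sims <= m)) / (n_sim + 1)
    method <- "monte-carlo"
  }
  structure(list(m = m, n = n, p_value = p, method = method),
            class = "hodges_ajne")
}

#' @export
print.hodges_ajne <- function(x, ...) {
  cat(sprintf("Hodges-Ajne test: m = %d, n = %d, p = %.4g (%s)\n",
              x$m, x$n, x$p_value, x$method))
  invisible(x)
}

#' Paired comparison of tuning between conditions
#'
#' Two-sided Wilcoxon signed-rank test on paired per-ROI values (e.g. DSI
#' before and during an esterase blocker). All-zero differences are
#' flagged degenerate rather than tested.
#'
#' @param x_control,x_drug Paired numeric vectors of equal length.
#' @return A one-row tibble: `n`, `median_control`, `median_drug`,
#'   `p_value`, `degenerate`.
#' @export
compare_conditions <- function(x_control, x_drug) {
  if (length(x_control) != length(x_drug)) abort("Vectors must be paired (equal length).")
  d <- x_control - x_drug
  if (all(d == 0)) {
    return(tibble(n = length(d), median_control = median(x_control),
                  median_drug = median(x_drug), p_value = NA_real_,
                  degenerate = TRUE))
  }
  p <- wilcox.test(x_control, x_drug, paired = TRUE, exact = FALSE)$p.value
  tibble(n = length(d), median_control = median(x_control),
         median_drug = median(x_drug), p_value = p, degenerate = FALSE)
}
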