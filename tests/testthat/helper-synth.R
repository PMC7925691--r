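# shared helpers for building small fixtures in code

# independent difference-of-exponentials waveform (oracle for template shape)
doe_waveform <- function(t_ms, rise = 0.5, decay = 2.5) {
  w <- exp(-t_ms / decay) - exp(-t_ms / rise)
  w / max(w)
}

# build a noiseless trace with events of known onset times/amplitudes
make_event_trace <- function(onsets_s, amps, fs = 1e4, duration = NULL,
                             rise = 0.5, decay = 2.5, noise_sd = 0,
                             seed = 1) {
  if (is.null(duration)) duration <- max(onsets_s) + 0.1
  n <- round(duration * fs)
  t_tmpl <- seq(0, 10 * decay, by = 1000 / fs)
  tmpl <- doe_waveform(t_tmpl, rise, decay)
  y <- numeric(n)
  for (k in seq_along(onsets_s)) {
    i0 <- round(onsets_s[k] * fs) + 1L
    i1 <- min(n, i0 + length(tmpl) - 1L)
    y[i0:i1] <- y[i0:i1] + amps[k] * tmpl[seq_len(i1 - i0 + 1L)]
  }
  if (noise_sd > 0) {
    y <- y + withr::with_seed(seed, rnorm(n, 0, noise_sd))
  }
  current_trace(y, fs)
}

# straight-line skeleton along x from 0 to `len` um at (y0, z0)
make_line_skeleton <- function(len, y0 = 0, z0 = 0, step = 0.5,
                               cell_id = "line") {
  xs <- seq(0, len, by = step)
  as_skeleton(tibble::tibble(
    node_id = seq_along(xs), type = 3L, x = xs, y = y0, z = z0,
    radius = 0.5, parent = c(-1L, seq_along(xs)[-length(xs)]),
    arbor_label = "ON", cell_id = cell_id))
}

# best Jaccard overlap of any ROI against a truth mask
best_jaccard <- function(roi_map, truth_mask) {
  ids <- roi_map$seeds$roi_id
  if (!length(ids)) return(0)
  max(vapply(ids, function(r) {
    mm <- roi_map$labels == r
    sum(truth_mask & mm) / sum(truth_mask | mm)
  }, numeric(1)))
}

# angular difference in [0, 180]
ang_diff <- function(a, b) {
  d <- abs((a - b) %% 360)
  pmin(d, 360 - d)
}

# full imaging pipeline used by recovery tests: preprocess -> dff ->
# residuals -> segmentation -> tuning
run_imaging_pipeline <- function(gen, preprocess = TRUE, min_response = -Inf,
                                 threshold = 2.5) {
  stacks <- if (preprocess) lapply(gen$movies, preprocess_stack) else gen$movies
  dffs <- lapply(stacks, dff)
  res <- pixel_residuals(dffs)
  dims <- dim(dffs[[1]]$data)[2:3]
  resp <- apply(vapply(dffs, function(s) apply(s$data, c(2, 3), max),
                       matrix(0, dims[1], dims[2])), c(1, 2), mean)
  rois <- segment_rois(res, resp, threshold = threshold,
                       min_response = min_response)
  list(dffs = dffs, residuals = res, rois = rois,
       pixel_size = dffs[[1]]$pixel_size, dims = dims)
}
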