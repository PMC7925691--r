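#' Specification for a pair of synthetic quantal event trains
#'
#' Describes two voltage-clamp current traces whose quantal EPSC trains share
#' a controllable fraction of events, emulating paired recordings from
#' neighboring direction-selective ganglion cells that receive input from
#' common cholinergic release sites. Spontaneous quantal events arrive as a
#' Poisson process (~3 Hz is typical for these cells); a `shared_fraction`
#' of the events in train A also occur in train B within
#' `coincidence_jitter` milliseconds, modelling single vesicles whose
#' transmitter reaches both cells.
#'
#' Quantal amplitudes are log-normal; shared events carry the *same*
#' amplitude in both cells (one vesicle, two postsynaptic sites). The
#' quantal waveform is a difference of exponentials with default time
#' constants 0.5 ms (rise) and 2.5 ms (decay). Recording noise is Gaussian,
#' low-pass filtered at 1 kHz before addition to mimic amplifier bandwidth;
#' `noise_sd` is the standard deviation after filtering.
#'
#' @param duration Trace duration (s).
#' @param rate_a,rate_b Quantal event rates (events/s). `rate_b` must be at
#'   least `shared_fraction * rate_a` so the independent remainder of train B
#'   has a non-negative rate.
#' @param shared_fraction Fraction of train-A events that also appear in
#'   train B, in `[0, 1]`.
#' @param coincidence_jitter Maximum timing offset of a shared event between
#'   the two trains (ms).
#' @param amp_mean,amp_sd Mean and SD of the log-normal quantal amplitude
#'   distribution (pA). Defaults 15 and 6 pA keep essentially all events
#'   above a 5-pA detection floor while showing realistic spread.
#' @param rise_tau,decay_tau Waveform time constants (ms); `decay_tau` must
#'   exceed `rise_tau`.
#' @param noise_sd Post-filter noise SD (pA).
#' @param sample_rate Sampling rate (Hz); 10000 matches 10-kHz digitization.
#' @param seed Integer seed; identical specs give bit-identical traces.
#'
#' @return A validated list of class `paired_train_spec`.
#' @export
paired_train_spec <- function(duration = 20, rate_a = 3, rate_b = 3,
                              shared_fraction = 0, coincidence_jitter = 0.1,
                              amp_mean = 15, amp_sd = 6,
                              rise_tau = 0.5, decay_tau = 2.5,
                              noise_sd = 1, sample_rate = 1e4, seed = 1L) {
  if (shared_fraction < 0 || shared_fraction > 1) {
    abort("`shared_fraction` must be in [0, 1].")
  }
  if (rate_a < 0 || rate_b < 0) abort("Event rates must be >= 0.")
  if (!(decay_tau > rise_tau && rise_tau > 0)) {
    abort("Need decay_tau > rise_tau > 0.")
  }
  if (sample_rate <= 0) abort("`sample_rate` must be > 0.")
  if (duration <= 0) abort("`duration` must be > 0.")
  if (coincidence_jitter < 0) abort("`coincidence_jitter` must be >= 0.")
  if (amp_mean <= 0 || amp_sd < 0) abort("Amplitude parameters must be positive.")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (rate_b < shared_fraction * rate_a) {
    abort("`rate_b` must be >= shared_fraction * rate_a.")
  }
  structure(
    list(duration = duration, rate_a = rate_a, rate_b = rate_b,
         shared_fraction = shared_fraction,
         coincidence_jitter = coincidence_jitter,
         amp_mean = amp_mean, amp_sd = amp_sd,
         rise_tau = rise_tau, decay_tau = decay_tau,
         noise_sd = noise_sd, sample_rate = sample_rate,
         seed = as.integer(seed)),
    class = "paired_train_spec"
  )
}

# unit-peak difference-of-exponentials quantal waveform sampled at the trace rate
quantal_template <- function(rise_tau, decay_tau, sample_rate,
                             length_ms = 10 * decay_tau) {
  t_ms <- seq(0, length_ms, by = 1000 / sample_rate)
  w <- exp(-t_ms / decay_tau) - exp(-t_ms / rise_tau)
  w / max(w)
}

# Gaussian noise band-limited below `bandwidth` Hz, rescaled to `sd_target`
filtered_noise <- function(n, sd_target, sample_rate, bandwidth = 1000) {
  x <- rnorm(n)
  if (bandwidth < sample_rate / 2) {
    x <- butter_zerophase(x, sample_rate, bandwidth)
  }
  if (sd_target == 0) return(rep(0, n))
  x * (sd_target / stats::sd(x))
}

add_quantal_events <- function(y, onset_idx, amps, template) {
  nt <- length(template)
  ny <- length(y)
  for (k in seq_along(onset_idx)) {
    i0 <- onset_idx[k]
    if (i0 > ny) next
    i1 <- min(ny, i0 + nt - 1L)
    y[i0:i1] <- y[i0:i1] + amps[k] * template[seq_len(i1 - i0 + 1L)]
  }
  y
}

#' Generate a pair of current traces with a known shared-event fraction
#'
#' Simulates the paired-recording configuration used to measure synchronized
#' quantal inputs: two traces whose Poisson event trains overlap by a
#' controlled fraction, with full ground truth returned for every event.
#'
#' @param spec A [paired_train_spec()].
#' @return A list with elements `trace_a`, `trace_b` (both
#'   [current_trace()]) and `truth`, a tibble with one row per event:
#'   `cell` ("a"/"b"), `event_id` (shared events carry the same id in both
#'   cells), `onset_s`, `amp_pA`, `shared`.
#' @export
#' @examples
#' out <- gen_paired_traces(paired_train_spec(duration = 5, shared_fraction = 0.5))
#' table(out$truth$cell, out$truth$shared)
gen_paired_traces <- function(spec) {
  stopifnot(inherits(spec, "paired_train_spec"))
  withr::with_seed(spec$seed, {
    fs <- spec$sample_rate
    n <- round(spec$duration * fs)
    margin <- 0.05
    lo <- margin
    hi <- max(margin, spec$duration - margin)

    n_a <- rpois(1, spec$rate_a * spec$duration)
    t_a <- sort(runif(n_a, lo, hi))
    shared <- if (n_a > 0) rbinom(n_a, 1, spec$shared_fraction) == 1 else logical(0)

    rate_b_ind <- spec$rate_b - spec$shared_fraction * spec$rate_a
    n_b_ind <- rpois(1, rate_b_ind * spec$duration)
    t_b_ind <- sort(runif(n_b_ind, lo, hi))

    # log-normal amplitudes; shared events reuse the train-A amplitude
    lnorm_pars <- function(m, s) {
      sdlog <- sqrt(log(1 + (s / m)^2))
      c(meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
    }
    lp <- lnorm_pars(spec$amp_mean, spec$amp_sd)
    amp_a <- rlnorm(n_a, lp[1], lp[2])
    amp_b_ind <- rlnorm(n_b_ind, lp[1], lp[2])

    jit_s <- spec$coincidence_jitter / 1000
    t_b_shared <- t_a[shared] +
      if (jit_s > 0) runif(sum(shared), -jit_s, jit_s) else 0
    amp_b_shared <- amp_a[shared]

    ord_b <- order(c(t_b_shared, t_b_ind))
    t_b <- c(t_b_shared, t_b_ind)[ord_b]
    amp_b <- c(amp_b_shared, amp_b_ind)[ord_b]
    shared_b <- c(rep(TRUE, length(t_b_shared)), rep(FALSE, n_b_ind))[ord_b]
    id_a <- seq_len(n_a)
    id_b <- c(id_a[shared], if (n_b_ind > 0) n_a + seq_len(n_b_ind) else integer(0))[ord_b]

    tmpl <- quantal_template(spec$rise_tau, spec$decay_tau, fs)
    make_trace <- function(t_ev, amps, cell) {
      y <- add_quantal_events(numeric(n), pmax(1L, round(t_ev * fs) + 1L),
                              amps, tmpl)
      y <- y + filtered_noise(n, spec$noise_sd, fs)
      current_trace(y, fs, cell_id = cell)
    }
    trace_a <- make_trace(t_a, amp_a, "a")
    trace_b <- make_trace(t_b, amp_b, "b")

    truth <- bind_rows(
      tibble(cell = "a", event_id = id_a, onset_s = t_a,
             amp_pA = amp_a, shared = shared),
      tibble(cell = "b", event_id = id_b, onset_s = t_b,
             amp_pA = amp_b, shared = shared_b)
    )
    list(trace_a = trace_a, trace_b = trace_b, truth = truth)
  })
}

# ---------------------------------------------------------------------------
# Dendritic arbor pairs

#' Specification for a pair of co-fasciculated planar dendritic arbors
#'
#' Emulates the honeycomb-like plexus in which neighboring retinal ganglion
#' cell dendrites run in shared fascicles. Each cell's arbor is a planar
#' random binary tree (branches grown in ~2-um steps with Gaussian heading
#' jitter); the second cell shares the first cell's branch topology, and a
#' `cofasciculation` fraction of its branches is laid down within 1 um of
#' the corresponding branch of the first cell (sub-micron lateral offset and
#' matched depth), while the remaining branches are regrown with independent
#' geometry. Arbors are generated for both the ON and OFF strata (two
#' parallel planes), each confined to `+/- z_jitter` around its stratum.
#'
#' @param field_radius Dendritic-field radius (um).
#' @param branch_count Number of branches per arbor per stratum.
#' @param cofasciculation Fraction in `[0, 1]` of cell-B branches laid
#'   within 1 um of cell A's corresponding branch.
#' @param z_jitter Depth jitter around each stratum plane (um).
#' @param center_offset Length-2 numeric: XY offset of cell B's soma (um).
#'   The default 0 gives overlapping dendritic fields, as for neighboring
#'   cells of the same mosaic; a large offset gives disjoint fields.
#' @param strata Character vector of strata to generate (`"ON"`, `"OFF"`).
#' @param seed Integer seed; identical specs give identical skeletons.
#' @return A validated list of class `arbor_pair_spec`.
#' @export
arbor_pair_spec <- function(field_radius = 100, branch_count = 30,
                            cofasciculation = 0, z_jitter = 1,
                            center_offset = c(0, 0),
                            strata = c("ON", "OFF"), seed = 1L) {
  if (cofasciculation < 0 || cofasciculation > 1) {
    abort("`cofasciculation` must be in [0, 1].")
  }
  if (branch_count < 1) abort("`branch_count` must be >= 1.")
  if (field_radius <= 0) abort("`field_radius` must be > 0.")
  if (z_jitter < 0) abort("`z_jitter` must be >= 0.")
  if (length(center_offset) != 2 || !is.numeric(center_offset)) {
    abort("`center_offset` must be a numeric vector of length 2.")
  }
  if (!length(strata) || !all(strata %in% c("ON", "OFF"))) {
    abort("`strata` must be a subset of c(\"ON\", \"OFF\").")
  }
  structure(
    list(field_radius = field_radius, branch_count = as.integer(branch_count),
         cofasciculation = cofasciculation, z_jitter = z_jitter,
         center_offset = center_offset, strata = strata,
         seed = as.integer(seed)),
    class = "arbor_pair_spec"
  )
}

# grow one branch polyline from `start` with heading `ang`, clipped to the field
grow_branch_polyline <- function(start, ang, len, center, field_radius,
                                 step = 2) {
  n_steps <- max(2L, ceiling(len / step))
  pts <- matrix(NA_real_, n_steps + 1L, 2L)
  pts[1L, ] <- start
  for (i in seq_len(n_steps)) {
    ang <- ang + rnorm(1, 0, 0.08)
    cand <- pts[i, ] + step * c(cos(ang), sin(ang))
    if (sqrt(sum((cand - center)^2)) > field_radius) {
      pts <- pts[seq_len(i), , drop = FALSE]
      break
    }
    pts[i + 1L, ] <- cand
  }
  pts <- pts[!is.na(pts[, 1L]), , drop = FALSE]
  list(pts = pts, dir_end = ang)
}

# grow a planar binary tree; returns list of branches (pts, parent, dir_end)
grow_arbor_branches <- function(center, field_radius, branch_count) {
  branches <- list()
  queue <- integer(0)
  n_prim <- max(1L, min(3L, branch_count))
  for (i in seq_len(n_prim)) {
    ang <- runif(1, 0, 2 * pi)
    br <- grow_branch_polyline(center, ang, runif(1, 15, 30),
                               center, field_radius)
    br$parent <- 0L
    branches[[length(branches) + 1L]] <- br
    queue <- c(queue, length(branches))
  }
  while (length(branches) < branch_count && length(queue)) {
    pid <- queue[1L]
    queue <- queue[-1L]
    pb <- branches[[pid]]
    tip <- pb$pts[nrow(pb$pts), ]
    if (sqrt(sum((tip - center)^2)) > 0.95 * field_radius) next
    for (s in c(-1, 1)) {
      if (length(branches) >= branch_count) break
      ang <- pb$dir_end + s * (0.55 + abs(rnorm(1, 0, 0.2)))
      br <- grow_branch_polyline(tip, ang, runif(1, 15, 30),
                                 center, field_radius)
      br$parent <- pid
      branches[[length(branches) + 1L]] <- br
      queue <- c(queue, length(branches))
    }
  }
  branches
}

# assemble a branch list into skeleton rows; branches carry a `z` vector
branches_to_nodes <- function(branches, soma, soma_z, type_code, arbor_label,
                              cell_id, id_offset) {
  rows <- list()
  nid <- id_offset
  soma_id <- nid
  rows[[1]] <- tibble(node_id = soma_id, type = 1L,
                      x = soma[1], y = soma[2], z = soma_z,
                      radius = 2, parent = -1L,
                      arbor_label = arbor_label, cell_id = cell_id)
  tip_id <- integer(length(branches))
  for (b in seq_along(branches)) {
    br <- branches[[b]]
    pts <- br$pts
    m <- nrow(pts)
    if (m < 2L) { tip_id[b] <- if (br$parent == 0L) soma_id else tip_id[br$parent]; next }
    first_parent <- if (br$parent == 0L) soma_id else tip_id[br$parent]
    ids <- nid + seq_len(m - 1L)
    nid <- nid + m - 1L
    rows[[length(rows) + 1]] <- tibble(
      node_id = ids, type = type_code,
      x = pts[-1L, 1L], y = pts[-1L, 2L], z = br$z[-1L],
      radius = 0.5,
      parent = c(first_parent, ids[-length(ids)]),
      arbor_label = arbor_label, cell_id = cell_id
    )
    tip_id[b] <- ids[length(ids)]
  }
  bind_rows(rows)
}

#' Generate a pair of dendritic skeletons with controlled co-fasciculation
#'
#' @param spec An [arbor_pair_spec()].
#' @return A list with skeleton tibbles `skeleton_a` and `skeleton_b`
#'   (class `skeleton`; columns `node_id`, `type`, `x`, `y`, `z`, `radius`,
#'   `parent`, `arbor_label`, `cell_id`). SWC type codes: 1 = soma,
#'   3 = ON dendrite, 4 = OFF dendrite.
#' @export
#' @examples
#' pair <- gen_arbor_pair(arbor_pair_spec(field_radius = 40, branch_count = 8))
#' head(pair$skeleton_a)
gen_arbor_pair <- function(spec) {
  stopifnot(inherits(spec, "arbor_pair_spec"))
  withr::with_seed(spec$seed, {
    z_strata <- c(ON = 0, OFF = 12)
    center_a <- c(0, 0)
    center_b <- spec$center_offset
    out_a <- list()
    out_b <- list()
    id_a <- 1L
    id_b <- 1L
    for (stratum in spec$strata) {
      type_code <- if (stratum == "ON") 3L else 4L
      z0 <- z_strata[[stratum]]
      br_a <- grow_arbor_branches(center_a, spec$field_radius,
                                  spec$branch_count)
      # depth for cell A: per-node jitter around the stratum plane
      for (b in seq_along(br_a)) {
        br_a[[b]]$z <- z0 + runif(nrow(br_a[[b]]$pts), -spec$z_jitter,
                                  spec$z_jitter)
      }
      n_br <- length(br_a)
      n_cof <- round(spec$cofasciculation * n_br)
      cof_set <- if (n_cof > 0) sample(seq_len(n_br), n_cof) else integer(0)

      br_b <- vector("list", n_br)
      for (b in seq_len(n_br)) {
        if (b %in% cof_set) {
          # lay this branch within 1 um of cell A's branch
          phi <- runif(1, 0, 2 * pi)
          r_off <- runif(1, 0.1, 0.6)
          jit <- matrix(rnorm(2 * nrow(br_a[[b]]$pts), 0, 0.05), ncol = 2)
          pts <- sweep(br_a[[b]]$pts, 2, r_off * c(cos(phi), sin(phi)), "+") + jit
          br_b[[b]] <- list(pts = pts, dir_end = br_a[[b]]$dir_end,
                            parent = br_a[[b]]$parent,
                            z = br_a[[b]]$z + rnorm(length(br_a[[b]]$z), 0, 0.1))
        } else {
          # regrow with independent geometry from the B-side attachment point
          parent <- br_a[[b]]$parent
          start <- if (parent == 0L) center_b else {
            pb <- br_b[[parent]]
            pb$pts[nrow(pb$pts), ]
          }
          len <- 2 * (nrow(br_a[[b]]$pts) - 1L)
          ang <- runif(1, 0, 2 * pi)
          nb <- grow_branch_polyline(start, ang, max(len, 4), center_b,
                                     spec$field_radius)
          nb$parent <- parent
          nb$z <- z0 + runif(nrow(nb$pts), -spec$z_jitter, spec$z_jitter)
          br_b[[b]] <- nb
        }
      }
      nodes_a <- branches_to_nodes(br_a, center_a, z0, type_code, stratum,
                                   "cell_a", id_a)
      nodes_b <- branches_to_nodes(br_b, center_b, z0, type_code, stratum,
                                   "cell_b", id_b)
      id_a <- max(nodes_a$node_id) + 1L
      id_b <- max(nodes_b$node_id) + 1L
      out_a[[stratum]] <- nodes_a
      out_b[[stratum]] <- nodes_b
    }
    list(skeleton_a = as_skeleton(bind_rows(out_a)),
         skeleton_b = as_skeleton(bind_rows(out_b)))
  })
}

# ---------------------------------------------------------------------------
# Direction-tuned sensor movies

#' Specification for a synthetic neurotransmitter-sensor movie set
#'
#' Emulates two-photon movies of a fluorescent transmitter sensor reporting
#' release from direction-tuned sites on a dendrite: each site has a
#' Gaussian spatial footprint (`footprint_sigma`), a von-Mises direction
#' tuning curve of concentration `tuning_kappa` (kappa 0.37 corresponds to a
#' direction-selectivity index of about 0.35), and sensor kinetics with a
#' slow decay (140 ms by default). Trial-to-trial response gain fluctuates
#' with coefficient of variation `gain_cv` *shared across all pixels of a
#' site's footprint* (independent between sites), which is what makes
#' noise-correlation-based segmentation possible; photon shot noise is
#' independent across pixels and frames.
#'
#' @param grid Integer c(H, W) pixel grid.
#' @param pixel_size Pixel size (um); 0.45 matches the imaging window used
#'   for dendritic fields of view.
#' @param frame_rate Acquisition rate (Hz), 8-12 Hz typical.
#' @param site_positions Optional n x 2 matrix of site centers (um). If
#'   `NULL`, `n_sites` centers are drawn with a minimum separation of
#'   4 * `footprint_sigma`.
#' @param n_sites Number of release sites when `site_positions` is `NULL`.
#' @param footprint_sigma Gaussian footprint SD (um).
#' @param tuning_kappa von-Mises concentration (0 = untuned).
#' @param preferred_angles Optional per-site preferred directions (deg);
#'   random if `NULL`.
#' @param sensor_rise,sensor_decay Sensor rise/decay time constants (ms).
#' @param directions Stimulus motion directions (deg).
#' @param speed Stimulus speed (um/s).
#' @param spot_diameter Moving-spot diameter (um); together with `speed`
#'   it sets how long the spot covers a site (the release-drive duration,
#'   0.3 s for the default 300 um at 1000 um/s).
#' @param trials Trials per direction.
#' @param shot_noise_sd Per-pixel, per-frame noise SD in dF/F units.
#' @param peak_dff Peak dF/F of a site in its preferred direction.
#' @param gain_cv Trial-to-trial shared gain CV per site.
#' @param baseline_f Baseline fluorescence (arbitrary units).
#' @param stim_onset,stim_duration,post_stim Timing (s).
#' @param seed Integer seed.
#' @return A validated list of class `movie_spec`.
#' @export
movie_spec <- function(grid = c(32, 32), pixel_size = 0.45, frame_rate = 10,
                       site_positions = NULL, n_sites = 4,
                       footprint_sigma = 1, tuning_kappa = 0.37,
                       preferred_angles = NULL,
                       sensor_rise = 10, sensor_decay = 140,
                       directions = seq(0, 315, by = 45), speed = 1000,
                       spot_diameter = 300,
                       trials = 4, shot_noise_sd = 0.1, peak_dff = 0.8,
                       gain_cv = 0.2, baseline_f = 100,
                       stim_onset = 1, stim_duration = 2, post_stim = 1,
                       seed = 1L) {
  if (footprint_sigma <= 0) abort("`footprint_sigma` must be > 0.")
  if (trials < 1) abort("`trials` must be >= 1.")
  if (!length(directions)) abort("`directions` must be non-empty.")
  if (frame_rate <= 0 || pixel_size <= 0) {
    abort("`frame_rate` and `pixel_size` must be > 0.")
  }
  if (any(grid < 1) || length(grid) != 2) abort("`grid` must be c(H, W) >= 1.")
  if (!is.null(site_positions)) {
    site_positions <- as.matrix(site_positions)
    fov <- grid[c(2, 1)] * pixel_size  # (x extent, y extent)
    if (any(site_positions < 0) || any(site_positions[, 1] > fov[1]) ||
        any(site_positions[, 2] > fov[2])) {
      abort("`site_positions` must lie inside the imaged field.")
    }
  }
  structure(
    list(grid = as.integer(grid), pixel_size = pixel_size,
         frame_rate = frame_rate, site_positions = site_positions,
         n_sites = as.integer(n_sites), footprint_sigma = footprint_sigma,
         tuning_kappa = tuning_kappa, preferred_angles = preferred_angles,
         sensor_rise = sensor_rise, sensor_decay = sensor_decay,
         directions = directions, speed = speed,
         spot_diameter = spot_diameter, trials = as.integer(trials),
         shot_noise_sd = shot_noise_sd, peak_dff = peak_dff,
         gain_cv = gain_cv, baseline_f = baseline_f,
         stim_onset = stim_onset, stim_duration = stim_duration,
         post_stim = post_stim, seed = as.integer(seed)),
    class = "movie_spec"
  )
}

#' Ground-truth footprint labels on an arbitrary pixel grid
#'
#' Assigns each pixel of an `H x W` grid to the nearest release site when
#' it lies within the footprint's support radius (2 sigma, the extent of
#' the sensor-expressing membrane patch), 0 otherwise. Useful for scoring a
#' segmentation computed on a resampled grid (e.g. after
#' [preprocess_stack()], whose pixel size differs from the native one).
#'
#' @param sites Site tibble as returned by [gen_movie()] (`x_um`, `y_um`,
#'   `sigma_um`).
#' @param dims Integer c(H, W) of the target grid.
#' @param pixel_size Pixel size of the target grid (um).
#' @return Integer H x W matrix of site labels.
#' @export
site_footprint_labels <- function(sites, dims, pixel_size) {
  H <- dims[1]; W <- dims[2]
  xs <- (seq_len(W) - 0.5) * pixel_size
  ys <- (seq_len(H) - 0.5) * pixel_size
  Xg <- matrix(xs, H, W, byrow = TRUE)
  Yg <- matrix(ys, H, W)
  d2 <- vapply(seq_len(nrow(sites)), function(s) {
    (Xg - sites$x_um[s])^2 + (Yg - sites$y_um[s])^2
  }, matrix(0, H, W))
  nearest <- apply(d2, c(1, 2), which.min)
  mind <- sqrt(apply(d2, c(1, 2), min))
  ifelse(mind <= 2 * sites$sigma_um[1], nearest, 0L)
}

#' Construct a fluorescence frame stack
#'
#' @param data Numeric array, time x height x width.
#' @param frame_rate Frames per second.
#' @param pixel_size Pixel size (um).
#' @param direction Stimulus direction (deg) or `NA`.
#' @param trial_id Trial index or `NA`.
#' @param stim_onset Stimulus onset time (s) or `NA`.
#' @return A list of class `frame_stack`.
#' @export
frame_stack <- function(data, frame_rate, pixel_size, direction = NA,
                        trial_id = NA, stim_onset = NA) {
  if (length(dim(data)) != 3L) abort("`data` must be a T x H x W array.")
  if (frame_rate <= 0) abort("`frame_rate` must be > 0.")
  structure(
    list(data = data, frame_rate = frame_rate, pixel_size = pixel_size,
         direction = direction, trial_id = trial_id, stim_onset = stim_onset),
    class = "frame_stack"
  )
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<frame_stack> %d frames of %dx%d px @ %g Hz (%.2f um/px), dir %s, trial %s\n",
    d[1], d[2], d[3], x$frame_rate, x$pixel_size,
    format(x$direction), format(x$trial_id)))
  invisible(x)
}

#' Generate movies of direction-tuned release sites with shared trial noise
#'
#' @param spec A [movie_spec()].
#' @return A list with:
#' \describe{
#'   \item{movies}{List of [frame_stack()] objects, one per trial x direction.}
#'   \item{sites}{Tibble of ground-truth sites: position (um), preferred
#'     angle, footprint sigma, peak dF/F.}
#'   \item{truth_labels}{Integer H x W matrix assigning each pixel to the
#'     nearest site if within the footprint's support radius (2 sigma)
#'     of its center, 0 otherwise -- the ground-truth footprint masks
#'     used for segmentation scoring.}
#'   \item{gains}{Array (site x direction x trial) of shared gain draws.}
#' }
#' @export
gen_movie <- function(spec) {
  stopifnot(inherits(spec, "movie_spec"))
  withr::with_seed(spec$seed, {
    H <- spec$grid[1]; W <- spec$grid[2]
    px <- spec$pixel_size
    fov_x <- W * px; fov_y <- H * px

    sites <- spec$site_positions
    if (is.null(sites)) {
      margin <- 2 * spec$footprint_sigma
      min_sep <- 4 * spec$footprint_sigma
      pts <- matrix(NA_real_, 0, 2)
      tries <- 0
      while (nrow(pts) < spec$n_sites && tries < 5000) {
        cand <- c(runif(1, margin, fov_x - margin),
                  runif(1, margin, fov_y - margin))
        if (!nrow(pts) || min(sqrt(rowSums(sweep(pts, 2, cand)^2))) >= min_sep) {
          pts <- rbind(pts, cand)
        }
        tries <- tries + 1
      }
      if (nrow(pts) < spec$n_sites) {
        abort("Could not place sites with the requested separation; enlarge the grid.")
      }
      sites <- pts
    }
    n_sites <- nrow(sites)
    prefs <- spec$preferred_angles
    if (is.null(prefs)) prefs <- runif(n_sites, 0, 360)
    prefs <- prefs %% 360

    # pixel-center coordinates (x along columns, y along rows)
    xs <- (seq_len(W) - 0.5) * px
    ys <- (seq_len(H) - 0.5) * px
    Xg <- matrix(xs, H, W, byrow = TRUE)
    Yg <- matrix(ys, H, W)
    # Gaussian profile truncated at 2 sigma: the sensor reports release only
    # over the finite membrane patch that expresses it, so each site's
    # footprint has compact support (its ground-truth mask)
    support_r <- 2 * spec$footprint_sigma
    footprints <- lapply(seq_len(n_sites), function(s) {
      d2s <- (Xg - sites[s, 1])^2 + (Yg - sites[s, 2])^2
      exp(-d2s / (2 * spec$footprint_sigma^2)) * (sqrt(d2s) <= support_r)
    })

    d2 <- vapply(seq_len(n_sites), function(s) {
      (Xg - sites[s, 1])^2 + (Yg - sites[s, 2])^2
    }, matrix(0, H, W))
    nearest <- apply(d2, c(1, 2), which.min)
    mind <- sqrt(apply(d2, c(1, 2), min))
    truth_labels <- ifelse(mind <= support_r, nearest, 0L)

    total_s <- spec$stim_onset + spec$stim_duration + spec$post_stim
    T_ <- round(total_s * spec$frame_rate)
    t_s <- (seq_len(T_) - 0.5) / spec$frame_rate

    # von-Mises tuning amplitudes, normalized so the preferred direction
    # reaches peak_dff: A(theta) = peak * exp(kappa * (cos(theta - pref) - 1))
    amp <- outer(seq_len(n_sites), seq_along(spec$directions),
                 Vectorize(function(s, d) {
                   dth <- (spec$directions[d] - prefs[s]) * pi / 180
                   spec$peak_dff * exp(spec$tuning_kappa * (cos(dth) - 1))
                 }))

    # shared per-site trial gains (the noise correlations downstream live here)
    gains <- array(pmax(0.1, 1 + spec$gain_cv *
                          rnorm(n_sites * length(spec$directions) * spec$trials)),
                   dim = c(n_sites, length(spec$directions), spec$trials))
    if (spec$gain_cv == 0) gains[] <- 1

    # sensor response to a boxcar release drive (the spot covers a site for
    # spot_diameter / speed seconds), convolved with rise/decay kinetics on a
    # fine grid and sampled at the frame times; unit peak
    dwell_ms <- spec$spot_diameter / spec$speed * 1000
    kernel_for <- function(t_act) {
      dt <- 2 # ms
      tt <- seq(0, (max(t_s) - t_act) * 1000 + dt, by = dt)
      if (length(tt) < 2) return(numeric(T_))
      irf <- (1 - exp(-tt / spec$sensor_rise)) * exp(-tt / spec$sensor_decay)
      drive <- as.numeric(tt <= dwell_ms)
      conv <- stats::convolve(drive, rev(irf), type = "open")[seq_along(tt)]
      k <- approx(t_act + tt / 1000, conv, xout = t_s, yleft = 0,
                  rule = 2)$y
      k[t_s <= t_act] <- 0
      pk <- max(k)
      if (pk > 0) k / pk else k
    }

    movies <- list()
    for (d in seq_along(spec$directions)) {
      u <- c(cos(spec$directions[d] * pi / 180),
             sin(spec$directions[d] * pi / 180))
      corners <- rbind(c(0, 0), c(fov_x, 0), c(0, fov_y), c(fov_x, fov_y))
      proj0 <- min(corners %*% u)
      t_act <- spec$stim_onset + (as.vector(sites %*% u) - proj0) / spec$speed
      kernels <- vapply(t_act, kernel_for, numeric(T_)) # T x n_sites
      for (tr in seq_len(spec$trials)) {
        dff <- array(0, dim = c(T_, H, W))
        for (s in seq_len(n_sites)) {
          amp_s <- amp[s, d] * gains[s, d, tr]
          # outer product time-kernel x footprint
          dff <- dff + outer(kernels[, s] * amp_s, footprints[[s]])
        }
        f <- spec$baseline_f * (1 + dff) +
          spec$baseline_f * spec$shot_noise_sd *
            array(rnorm(T_ * H * W), dim = c(T_, H, W))
        movies[[length(movies) + 1]] <- frame_stack(
          f, spec$frame_rate, px, direction = spec$directions[d],
          trial_id = tr, stim_onset = spec$stim_onset)
      }
    }
    list(
      movies = movies,
      sites = tibble(site_id = seq_len(n_sites),
                     x_um = sites[, 1], y_um = sites[, 2],
                     pref_deg = prefs, sigma_um = spec$footprint_sigma,
                     peak_dff = spec$peak_dff, kappa = spec$tuning_kappa),
      truth_labels = truth_labels,
      gains = gains
    )
  })
}
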