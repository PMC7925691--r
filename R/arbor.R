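#' Skeleton objects and SWC input/output
#'
#' A skeleton is a tibble of centerline nodes with parent links, one row
#' per node: `node_id`, `type` (SWC code), `x`, `y`, `z` (um), `radius`,
#' `parent` (-1 for roots), `arbor_label` (`"ON"`/`"OFF"`) and `cell_id`.
#' Dendrite thickness is not represented: skeletons are centerlines, and
#' all distances are computed between centerline points.
#'
#' SWC type-code convention used here: 1 = soma, 3 = ON-stratum dendrite,
#' 4 = OFF-stratum dendrite.
#'
#' @param x A data frame with at least `node_id`, `x`, `y`, `z`, `parent`.
#' @return A `skeleton` tibble.
#' @export
as_skeleton <- function(x) {
  need <- c("node_id", "x", "y", "z", "parent")
  if (!all(need %in% names(x))) {
    abort(paste("Skeleton needs columns:", paste(need, collapse = ", ")))
  }
  if (anyNA(x[need]) || any(!is.finite(as.matrix(x[c("x", "y", "z")])))) {
    abort("Skeleton coordinates must be finite.")
  }
  out <- as_tibble(x)
  if (!"type" %in% names(out)) out$type <- 3L
  if (!"radius" %in% names(out)) out$radius <- 0.5
  if (!"arbor_label" %in% names(out)) {
    out$arbor_label <- ifelse(out$type == 4L, "OFF", "ON")
  }
  if (!"cell_id" %in% names(out)) out$cell_id <- NA_character_
  class(out) <- c("skeleton", class(out))
  out
}

#' @rdname as_skeleton
#' @param path SWC file path.
#' @param cell_id Identifier stored on the loaded skeleton.
#' @export
read_swc <- function(path, cell_id = basename(path)) {
  df <- utils::read.table(path, comment.char = "#",
                          col.names = c("node_id", "type", "x", "y", "z",
                                        "radius", "parent"))
  df$cell_id <- cell_id
  as_skeleton(df)
}

#' @rdname as_skeleton
#' @param sk A `skeleton`.
#' @export
write_swc <- function(sk, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# SWC export; type 1=soma, 3=ON dendrite, 4=OFF dendrite", con)
  utils::write.table(
    as.data.frame(sk[, c("node_id", "type", "x", "y", "z", "radius", "parent")]),
    con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

# decompose a skeleton into unbranched polyline paths (lists of node indices)
skeleton_paths <- function(sk) {
  n <- nrow(sk)
  id2row <- setNames(seq_len(n), sk$node_id)
  parent_row <- ifelse(sk$parent < 0, NA_integer_,
                       id2row[as.character(sk$parent)])
  n_children <- tabulate(parent_row[!is.na(parent_row)], nbins = n)
  # a node starts a path if its parent is a root, a soma, or a branch point
  starts <- which(vapply(seq_len(n), function(i) {
    p <- parent_row[i]
    if (is.na(p)) return(FALSE)                 # roots handled below
    n_children[p] > 1 || is.na(parent_row[p]) || sk$type[p] == 1L
  }, logical(1)))
  children <- split(seq_len(n)[!is.na(parent_row)],
                    parent_row[!is.na(parent_row)])
  paths <- list()
  for (s in starts) {
    path <- c(parent_row[s], s)
    cur <- s
    repeat {
      kids <- children[[as.character(cur)]]
      if (is.null(kids) || length(kids) != 1L) break
      cur <- kids
      path <- c(path, cur)
    }
    paths[[length(paths) + 1]] <- path
  }
  paths
}

#' Resample a skeleton into fixed-length segments
#'
#' Every unbranched path of the skeleton is resampled by arc length into
#' contiguous pieces of length `seg_len` (1 um by default, matching the
#' segmentation used for nearest-neighbor profiles); a terminal remainder
#' is kept as its own segment when it is at least `seg_len / 2` long.
#' Segment midpoints are interpolated along the centerline.
#'
#' @param sk A `skeleton`.
#' @param seg_len Segment length (um), > 0.
#' @return A tibble with `segment_id`, midpoint `x`, `y`, `z` (um),
#'   `length_um`, `arbor_label`, `cell_id`.
#' @export
resample_segments <- function(sk, seg_len = 1) {
  if (seg_len <= 0) abort("`seg_len` must be > 0.")
  if (!nrow(sk)) abort("Empty skeleton.")
  paths <- skeleton_paths(sk)
  if (!length(paths)) abort("Skeleton has no edges.")
  xyz <- as.matrix(sk[, c("x", "y", "z")])
  res <- purrr::map_dfr(paths, function(p) {
    P <- xyz[p, , drop = FALSE]
    dl <- sqrt(rowSums(diff(P)^2))
    L <- sum(dl)
    if (L <= 0) return(NULL)
    s_cum <- c(0, cumsum(dl))
    n_full <- floor(L / seg_len)
    rem <- L - n_full * seg_len
    ends <- seq_len(n_full) * seg_len
    mids <- ends - seg_len / 2
    lens <- rep(seg_len, n_full)
    if (rem >= seg_len / 2) {
      mids <- c(mids, n_full * seg_len + rem / 2)
      lens <- c(lens, rem)
    }
    if (!length(mids)) return(NULL)
    interp <- vapply(1:3, function(k) approx(s_cum, P[, k], xout = mids)$y,
                     numeric(length(mids)))
    interp <- matrix(interp, ncol = 3)
    tibble(x = interp[, 1], y = interp[, 2], z = interp[, 3],
           length_um = lens,
           arbor_label = sk$arbor_label[p[2]],
           cell_id = sk$cell_id[p[2]])
  })
  res$segment_id <- seq_len(nrow(res))
  res[, c("segment_id", "x", "y", "z", "length_um", "arbor_label", "cell_id")]
}

# exhaustive nearest-neighbor distances, chunked to bound memory
nn_exhaustive <- function(A, B, chunk = 512L) {
  nb2 <- rowSums(B^2)
  out <- numeric(nrow(A))
  for (i0 in seq(1L, nrow(A), by = chunk)) {
    i1 <- min(nrow(A), i0 + chunk - 1L)
    Ai <- A[i0:i1, , drop = FALSE]
    d2 <- outer(rowSums(Ai^2), nb2, "+") - 2 * tcrossprod(Ai, B)
    out[i0:i1] <- sqrt(pmax(0, apply(d2, 1, min)))
  }
  out
}

# grid-bucket nearest neighbor with expanding-shell search; exact.
# Points far from every bucket (upper bound > max_rings cells) fall back to
# a vectorized exhaustive scan, so sparse/disjoint geometries stay fast.
nn_grid <- function(A, B, cell = NULL, max_rings = 6L) {
  if (is.null(cell)) {
    vol_span <- apply(B, 2, function(v) diff(range(v)))
    cell <- max(1e-6, (prod(pmax(vol_span, 1e-6)) / nrow(B))^(1 / 3))
  }
  buckets <- new.env(hash = TRUE, parent = emptyenv())
  bidx <- floor(B / cell)
  bkey <- paste(bidx[, 1], bidx[, 2], bidx[, 3], sep = ",")
  for (grp in split(seq_len(nrow(B)), bkey)) {
    assign(bkey[grp[1]], grp, envir = buckets)
  }
  # cheap per-point upper bound from a handful of reference B points
  refs <- B[unique(round(seq(1, nrow(B), length.out = min(16, nrow(B))))),
            , drop = FALSE]
  aidx <- floor(A / cell)
  tB <- t(B)
  out <- numeric(nrow(A))
  for (i in seq_len(nrow(A))) {
    a <- A[i, ]
    ub <- sqrt(min(colSums((t(refs) - a)^2)))
    if (ub > max_rings * cell) {
      out[i] <- sqrt(min(colSums((tB - a)^2)))
      next
    }
    ci <- aidx[i, ]
    best <- ub
    ring <- 0L
    repeat {
      rng <- -ring:ring
      # enumerate the cube shell at Chebyshev radius `ring`
      offs <- as.matrix(expand.grid(dx = rng, dy = rng, dz = rng))
      offs <- offs[apply(abs(offs), 1, max) == ring, , drop = FALSE]
      keys <- paste(ci[1] + offs[, 1], ci[2] + offs[, 2], ci[3] + offs[, 3],
                    sep = ",")
      cand <- unlist(lapply(keys, function(k) {
        if (exists(k, envir = buckets, inherits = FALSE)) {
          get(k, envir = buckets, inherits = FALSE)
        }
      }))
      if (length(cand)) {
        d <- sqrt(colSums((tB[, cand, drop = FALSE] - a)^2))
        best <- min(best, min(d))
      }
      # any point in a farther shell is at least ring * cell away
      if (best <= ring * cell || ring > max_rings + 2L) break
      ring <- ring + 1L
    }
    out[i] <- best
  }
  out
}

#' Nearest-neighbor distance profile between two segment sets
#'
#' For each segment of `segments_a`, the Euclidean distance (3D,
#' midpoint-to-midpoint) to the nearest segment of `segments_b`, together
#' with the cumulative distribution binned at `bin` um: `cdf(d)` is the
#' fraction of cell-A segments whose nearest cell-B segment lies within
#' `d` um. Note the profile is directional (A toward B); compute both
#' directions for a pair.
#'
#' @param segments_a,segments_b Segment tibbles from [resample_segments()].
#' @param bin CDF bin width (um).
#' @param method `"grid"` (bucketed exact search, default), or
#'   `"exhaustive"` (all-pairs reference implementation).
#' @return An object of class `nnd_profile`: list with `segments` (the
#'   cell-A segments plus `nnd_um`), `cdf` (tibble `distance_um`,
#'   `fraction`), `arbor_label`, and `direction` ("a_to_b").
#' @export
nnd <- function(segments_a, segments_b, bin = 1,
                method = c("grid", "exhaustive")) {
  method <- match.arg(method)
  if (!nrow(segments_a) || !nrow(segments_b)) {
    abort("Both segment sets must be non-empty.")
  }
  A <- as.matrix(segments_a[, c("x", "y", "z")])
  B <- as.matrix(segments_b[, c("x", "y", "z")])
  d <- if (method == "grid") nn_grid(A, B) else nn_exhaustive(A, B)
  segs <- segments_a
  segs$nnd_um <- d
  grid_d <- seq(0, ceiling(max(d) / bin) * bin, by = bin)
  cdf <- tibble(distance_um = grid_d,
                fraction = vapply(grid_d, function(g) mean(d <= g), numeric(1)))
  structure(
    list(segments = segs, cdf = cdf,
         arbor_label = unique(segments_a$arbor_label),
         direction = "a_to_b"),
    class = "nnd_profile"
  )
}

#' @export
print.nnd_profile <- function(x, ...) {
  cat(sprintf(
    "<nnd_profile> %d segments (%s); median NND %.2f um; %.0f%% within 1 um\n",
    nrow(x$segments), paste(x$arbor_label, collapse = "/"),
    median(x$segments$nnd_um), 100 * mean(x$segments$nnd_um <= 1)))
  invisible(x)
}

# evaluate an nnd_profile's CDF at distance d (binned convention)
profile_cdf_at <- function(profile, d) {
  d <- max(0, d)
  mean(profile$segments$nnd_um <= d)
}

#' Fraction of overlapping dendrites at a distance
#'
#' The ON- and OFF-stratum CDFs are averaged and evaluated at distance
#' `d`; the value is read as the fraction of one cell's dendritic cable
#' that runs within `d` um of the other cell's.
#'
#' @param profile_on,profile_off `nnd_profile` objects for the two strata.
#' @param d Distance (um); values below the first bin return the bin-0
#'   (contact) fraction.
#' @return Overlap fraction in `[0, 1]`.
#' @export
overlap_fraction <- function(profile_on, profile_off, d) {
  vapply(pmax(d, 0), function(dd) {
    mean(c(profile_cdf_at(profile_on, dd), profile_cdf_at(profile_off, dd)))
  }, numeric(1))
}

#' Full nearest-neighbor analysis for a skeleton pair
#'
#' Resamples both skeletons at `seg_len`, computes directional NND
#' profiles per stratum, and returns per-direction overlap fractions on an
#' integer distance grid.
#'
#' @param sk_a,sk_b `skeleton` objects.
#' @param seg_len Segment length (um).
#' @param distances Distance grid for overlap fractions (um).
#' @param method Passed to [nnd()].
#' @return A list with `profiles` (nested list
#'   `[direction][arbor_label]` of `nnd_profile`) and `overlap`, a tibble
#'   (`direction`, `distance_um`, `fraction`).
#' @export
arbor_nnd <- function(sk_a, sk_b, seg_len = 1, distances = 0:3,
                      method = "grid") {
  seg_a <- resample_segments(sk_a, seg_len)
  seg_b <- resample_segments(sk_b, seg_len)
  labels <- intersect(unique(seg_a$arbor_label), unique(seg_b$arbor_label))
  if (!length(labels)) abort("Skeletons share no arbor stratum.")
  profiles <- list()
  overlap <- list()
  for (dir_ in c("a_to_b", "b_to_a")) {
    pr <- lapply(labels, function(lb) {
      qa <- seg_a[seg_a$arbor_label == lb, ]
      qb <- seg_b[seg_b$arbor_label == lb, ]
      if (dir_ == "a_to_b") nnd(qa, qb, method = method) else
        nnd(qb, qa, method = method)
    })
    names(pr) <- labels
    profiles[[dir_]] <- pr
    fr <- vapply(distances, function(dd) {
      mean(vapply(pr, profile_cdf_at, numeric(1), d = dd))
    }, numeric(1))
    overlap[[dir_]] <- tibble(direction = dir_, distance_um = distances,
                              fraction = fr)
  }
  list(profiles = profiles, overlap = bind_rows(overlap))
}

#' Compare dendritic overlap fractions with physiological correlation strength
#'
#' For a population of recorded/traced pairs, compares the fraction of
#' overlapping dendrites at each distance with the correlation strength of
#' the same pairs: per-distance mean difference (fraction - strength) with
#' a two-sided paired t-test, flagging the distance whose fractions best
#' match the physiology (smallest absolute mean difference).
#'
#' @param fractions Tibble with `pair_id`, `distance_um`, `fraction`.
#' @param strengths Tibble with `pair_id`, `strength`.
#' @return A tibble per distance: `distance_um`, `mean_difference`,
#'   `p_value`, `n_pairs`, `best_match` (logical).
#' @export
structure_function_compare <- function(fractions, strengths) {
  if (length(unique(strengths$pair_id)) < 3) {
    abort("Need at least 3 pairs.")
  }
  joined <- left_join(fractions, strengths, by = "pair_id")
  if (anyNA(joined$strength)) abort("Every pair needs a strength value.")
  out <- joined |>
    group_by(.data$distance_um) |>
    summarise(
      mean_difference = mean(.data$fraction - .data$strength),
      p_value = paired_p(.data$fraction, .data$strength),
      n_pairs = dplyr::n(),
      .groups = "drop"
    )
  out$best_match <- abs(out$mean_difference) == min(abs(out$mean_difference))
  out
}

# paired two-sided t-test p, with the degenerate constant-difference cases
# resolved by limit: all-zero differences -> p = 1, constant nonzero -> p -> 0
paired_p <- function(a, b) {
  d <- a - b
  if (length(d) != length(b)) abort("Length mismatch between fractions and strengths.")
  if (sd(d) < 1e-12) {
    return(if (abs(mean(d)) < 1e-12) 1 else 0)
  }
  t.test(a, b, paired = TRUE)$p.value
}
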