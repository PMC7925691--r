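#' Extracellular geometry for transmitter diffusion
#'
#' Two idealized geometries for the space a released vesicle's transmitter
#' diffuses through: a thin planar disc of height `cleft_height` between
#' pre- and postsynaptic membranes (2D spread), or a porous 3D
#' extracellular volume in which the effective diffusion coefficient is
#' reduced by a tortuosity factor (`D_eff = D / tortuosity_factor`).
#' Extracellular esterase is modelled as first-order loss at
#' `esterase_rate`. In the planar geometry the concentration gradient
#' away from the release site is shallower, so distal receptors see
#' relatively more transmitter than in the porous 3D case.
#'
#' @param mode `"planar-2D"` or `"porous-3D"`.
#' @param cleft_height Cleft height (um), used in 2D mode; 0.02 um (20 nm)
#'   is a typical synaptic cleft.
#' @param diffusion_coeff Free diffusion coefficient (um^2/ms).
#' @param esterase_rate First-order degradation rate (1/ms).
#' @param tortuosity_factor Dimensionless factor dividing D in 3D mode
#'   (lambda^2 in the usual notation; ~2.6 for brain extracellular space).
#' @return A list of class `cleft_geometry`.
#' @export
cleft_geometry <- function(mode = c("planar-2D", "porous-3D"),
                           cleft_height = 0.02, diffusion_coeff = 0.4,
                           esterase_rate = 0, tortuosity_factor = 2.6) {
  mode <- match.arg(mode)
  if (diffusion_coeff <= 0) abort("`diffusion_coeff` must be > 0.")
  if (mode == "planar-2D" && cleft_height <= 0) abort("`cleft_height` must be > 0.")
  if (esterase_rate < 0) abort("`esterase_rate` must be >= 0.")
  if (tortuosity_factor < 1) abort("`tortuosity_factor` must be >= 1.")
  structure(list(mode = mode, cleft_height = cleft_height,
                 diffusion_coeff = diffusion_coeff,
                 esterase_rate = esterase_rate,
                 tortuosity_factor = tortuosity_factor),
            class = "cleft_geometry")
}

#' A single-vesicle release event
#'
#' @param n_molecules Transmitter molecules in the vesicle (> 0); 1e4 is a
#'   round figure for a small clear vesicle with concentrated content.
#' @param time Release time (ms).
#' @return A list of class `release_event`.
#' @export
release_event <- function(n_molecules = 1e4, time = 0) {
  if (n_molecules <= 0) abort("`n_molecules` must be > 0.")
  structure(list(n_molecules = n_molecules, time = time),
            class = "release_event")
}

# molecules per um^3 corresponding to 1 uM
MOLEC_PER_UM3_PER_UM <- 602.214076

#' Transmitter concentration from an instantaneous point source
#'
#' Closed-form Green's-function solution for a vesicle released at the
#' origin at `t = 0`, with first-order esterase loss:
#' \itemize{
#' \item planar 2D: `C(r,t) = N / (4 pi D t h) * exp(-r^2 / (4 D t)) * exp(-k t)`
#'   (the 2D sheet concentration divided by the cleft height `h` gives a
#'   volume concentration);
#' \item porous 3D: `C(r,t) = N / (4 pi D_eff t)^{3/2} * exp(-r^2 / (4 D_eff t)) * exp(-k t)`
#'   with `D_eff = D / tortuosity_factor`.
#' }
#' Concentrations are converted from molecules/um^3 to uM
#' (1 uM = 602.214 molecules/um^3).
#'
#' @param geometry A [cleft_geometry()].
#' @param release A [release_event()].
#' @param r Radial distance(s) from the release site (um).
#' @param t Time(s) after release (ms), > 0.
#' @return A tibble with `r_um`, `t_ms`, `conc_uM` over the grid
#'   `expand.grid(r, t)`.
#' @export
cleft_concentration <- function(geometry, release, r, t) {
  if (any(t <= 0)) abort("`t` must be > 0 (instantaneous source).")
  if (any(r < 0)) abort("`r` must be >= 0.")
  grid <- expand.grid(r_um = r, t_ms = t)
  k <- geometry$esterase_rate
  N <- release$n_molecules
  conc <- if (geometry$mode == "planar-2D") {
    D <- geometry$diffusion_coeff
    N / (4 * pi * D * grid$t_ms * geometry$cleft_height) *
      exp(-grid$r_um^2 / (4 * D * grid$t_ms)) * exp(-k * grid$t_ms)
  } else {
    De <- geometry$diffusion_coeff / geometry$tortuosity_factor
    N / (4 * pi * De * grid$t_ms)^1.5 *
      exp(-grid$r_um^2 / (4 * De * grid$t_ms)) * exp(-k * grid$t_ms)
  }
  tibble(r_um = grid$r_um, t_ms = grid$t_ms,
         conc_uM = conc / MOLEC_PER_UM3_PER_UM)
}

#' Multi-state nicotinic receptor scheme
#'
#' A canonical two-binding-site gating scheme:
#' `C <-> CA <-> CA2 <-> O`, with desensitization `CA2 -> D` and
#' `O -> D` (rate `k_des`) and recovery `D -> CA2` (rate `k_res`).
#' Binding is `2 k_on * A` (C to CA) and `k_on * A` (CA to CA2) with
#' unbinding `k_off` and `2 k_off`; gating is `beta` (opening) and
#' `alpha` (closing). Two presets bracket the physiological range:
#' `"high"` affinity with slow desensitization (alpha7-like, sub-uM Kd)
#' and `"low"` affinity with fast desensitization (muscle-like, tens of
#' uM Kd). Every rate can be overridden.
#'
#' @param affinity_class `"high"` or `"low"`.
#' @param k_on Binding rate (1/(uM*ms)).
#' @param k_off Unbinding rate (1/ms).
#' @param beta,alpha Channel opening/closing rates (1/ms).
#' @param k_des,k_res Desensitization/recovery rates (1/ms).
#' @return A list of class `receptor_scheme`.
#' @export
receptor_scheme <- function(affinity_class = c("high", "low"),
                            k_on = NULL, k_off = NULL, beta = NULL,
                            alpha = NULL, k_des = NULL, k_res = NULL) {
  affinity_class <- match.arg(affinity_class)
  preset <- if (affinity_class == "high") {
    list(k_on = 0.1, k_off = 0.05, beta = 5, alpha = 1,
         k_des = 0.02, k_res = 0.002)
  } else {
    list(k_on = 0.1, k_off = 5, beta = 5, alpha = 1,
         k_des = 0.5, k_res = 0.002)
  }
  vals <- list(k_on = k_on, k_off = k_off, beta = beta, alpha = alpha,
               k_des = k_des, k_res = k_res)
  for (nm in names(vals)) if (!is.null(vals[[nm]])) preset[[nm]] <- vals[[nm]]
  if (any(unlist(preset) < 0)) abort("All rates must be >= 0.")
  structure(c(preset, list(affinity_class = affinity_class)),
            class = "receptor_scheme")
}

# generator matrix Q (columns sum to zero) at agonist concentration a (uM);
# state order C, CA, CA2, O, D
receptor_generator <- function(scheme, a) {
  with(scheme, {
    matrix(c(
      -2 * k_on * a, k_off, 0, 0, 0,
      2 * k_on * a, -(k_off + k_on * a), 2 * k_off, 0, 0,
      0, k_on * a, -(2 * k_off + beta + k_des), alpha, k_res,
      0, 0, beta, -(alpha + k_des), 0,
      0, 0, k_des, k_des, -k_res
    ), nrow = 5, byrow = TRUE)
  })
}

#' Steady-state occupancies at constant agonist concentration
#'
#' Closed-form stationary distribution of the receptor scheme's rate
#' matrix (null-space solution), used both for equilibrium predictions and
#' as an independent check on the time-domain integration.
#'
#' @param scheme A [receptor_scheme()].
#' @param conc Agonist concentration (uM).
#' @return Named numeric vector of occupancies (C, CA, CA2, O, D) summing
#'   to 1.
#' @export
receptor_steady_state <- function(scheme, conc) {
  Q <- receptor_generator(scheme, conc)
  # solve Q p = 0 with sum(p) = 1
  A <- rbind(Q, rep(1, 5))
  b <- c(rep(0, 5), 1)
  p <- qr.solve(A, b)
  setNames(pmax(p, 0) / sum(pmax(p, 0)), c("C", "CA", "CA2", "O", "D"))
}

#' Receptor open-probability response to a concentration transient
#'
#' Integrates the five-state receptor scheme driven by a transmitter
#' concentration timeseries (linearly interpolated between samples) with a
#' stiff-aware adaptive solver (`deSolve::lsoda`, absolute tolerance
#' 1e-10 on occupancies). Receptors start unbound and closed.
#'
#' @param conc Tibble with `t_ms` and `conc_uM` (non-negative).
#' @param scheme A [receptor_scheme()].
#' @param distance_um Optional distance annotation (um).
#' @return An object of class `site_response`: `open_prob` tibble
#'   (`t_ms`, `p_open`, plus all state occupancies), `peak`,
#'   `latency_to_peak_ms`, `distance_um`.
#' @export
receptor_response <- function(conc, scheme, distance_um = NA_real_) {
  if (any(conc$conc_uM < 0)) abort("Concentrations must be non-negative.")
  if (nrow(conc) < 2) abort("Concentration series needs at least 2 samples.")
  cfun <- approx_conc_fun(conc)
  rhs <- function(t, y, parms) {
    list(as.vector(receptor_generator(scheme, cfun(t)) %*% y))
  }
  y0 <- c(C = 1, CA = 0, CA2 = 0, O = 0, D = 0)
  times <- c(0, conc$t_ms)
  sol <- tryCatch(
    deSolve::lsoda(y0, times, rhs, parms = NULL,
                   rtol = 1e-10, atol = 1e-10),
    error = function(e) abort(paste("ODE integration failed:",
                                    conditionMessage(e))))
  if (attr(sol, "istate")[1] < 0) {
    abort(paste("ODE integration did not complete; solver diagnostics:",
                paste(attr(sol, "istate"), collapse = " ")))
  }
  out <- as_tibble(as.data.frame(sol))
  names(out)[1] <- "t_ms"
  out$p_open <- out$O
  ipk <- which.max(out$O)
  structure(
    list(open_prob = out, peak = out$O[ipk],
         latency_to_peak_ms = out$t_ms[ipk],
         distance_um = distance_um, scheme = scheme),
    class = "site_response"
  )
}

# zero-extended linear interpolation of the concentration series
approx_conc_fun <- function(conc) {
  f <- stats::approxfun(conc$t_ms, conc$conc_uM, rule = 2, yleft = 0)
  function(t) pmax(0, f(t))
}

#' @export
print.site_response <- function(x, ...) {
  cat(sprintf(
    "<site_response> peak open probability %.4f at %.2f ms (distance %s um)\n",
    x$peak, x$latency_to_peak_ms, format(x$distance_um)))
  invisible(x)
}

#' Compare receptor responses at proximal and distal sites
#'
#' Simulates the tripartite arrangement in which one release site drives
#' receptors directly beneath it (the classical synapse, 0 um) and
#' receptors on a neighboring dendrite about 1 um away: computes the
#' concentration transient at each distance, the receptor response to it,
#' and the distal/proximal peak-open-probability ratio. Ratios near 1
#' mean the two sites respond with similar efficacy despite the distance.
#'
#' @param geometry A [cleft_geometry()].
#' @param release A [release_event()].
#' @param scheme A [receptor_scheme()].
#' @param distances Distances to evaluate (um); default `c(0, 1)`.
#' @param t_max,dt Simulation horizon and sampling step (ms).
#' @return A list with `sites` (tibble: `distance_um`, `peak`,
#'   `latency_to_peak_ms`), `peak_ratio` (last distance / first), and the
#'   per-site `responses`.
#' @export
compare_sites <- function(geometry, release, scheme, distances = c(0, 1),
                          t_max = 50, dt = 0.05) {
  tgrid <- seq(dt, t_max, by = dt)
  responses <- lapply(distances, function(r) {
    cc <- cleft_concentration(geometry, release, r, tgrid)
    receptor_response(cc[, c("t_ms", "conc_uM")], scheme, distance_um = r)
  })
  sites <- tibble(
    distance_um = distances,
    peak = vapply(responses, `[[`, numeric(1), "peak"),
    latency_to_peak_ms = vapply(responses, `[[`, numeric(1),
                                "latency_to_peak_ms"))
  ratio <- sites$peak[nrow(sites)] / sites$peak[1]
  list(sites = sites, peak_ratio = ratio, responses = responses)
}
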