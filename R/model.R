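# Total interaction free energy of a DNA-GUV pair and its minimization over
# the trial contact angle. U(theta; T) = U_membrane + U_DNA - U0, with
#   U_membrane = 2 * (Ka/2) (A - Abar)^2 / Abar   (stretching only)
#   U_DNA      = U_hyb(x_b, x_l, N) - 2 N ln(A / Abar)   (confinement term)
#   U0         = U_hyb of an isolated unstretched vesicle pair, loops only.
# All energies in kBT at the current temperature.

#' Membrane stretching energy of the pair
#'
#' Quadratic stretching penalty for both vesicles,
#' `U_mem = 2 (Ka/2) (A - Abar(T))^2 / Abar(T)` in kBT. Bending elasticity
#' and fluctuation repulsion are neglected (strong-adhesion regime). The
#' penalty is applied symmetrically also for `A < Abar`; near equilibrium
#' the DNA attraction keeps `A >= Abar`, so the floppy side of the
#' approximation is inert.
#'
#' @param geom A `pair_geometry` from [geometry_at_angle()].
#' @param params A [model_params()] object.
#' @param T_C Temperature, degC.
#' @return Energy in kBT (for the pair).
#' @export
membrane_energy <- function(geom, params, T_C) {
  stopifnot(inherits(geom, "pair_geometry"))
  Abar_nm2 <- unstretched_area(params, T_C) * .NM2_PER_UM2
  Ka_kbt <- stretch_modulus_kbt_nm2(params$Ka, T_C)
  A_nm2 <- geom$A * .NM2_PER_UM2
  Ka_kbt * (A_nm2 - Abar_nm2)^2 / Abar_nm2
}

#' DNA free energy of the pair at a given geometry
#'
#' Mean-field hybridization free energy of the 2N mobile tethers at the
#' current geometry, plus the area-confinement term
#' `-2 N ln(A / Abar(T))` that accounts for the change in tether confinement
#' when the membranes stretch. The confinement term is applied to all 2N
#' tethers and referenced to the unstretched area, so the energy vanishes in
#' the no-bond, no-stretch limit; any other reference shifts the energy by an
#' angle-independent constant and cannot move the equilibrium.
#'
#' @inheritParams membrane_energy
#' @return Energy in kBT (for the pair).
#' @export
dna_free_energy <- function(geom, params, T_C) {
  stopifnot(inherits(geom, "pair_geometry"))
  N <- tethers_per_vesicle(params$rho_dna, params$R0)
  if (N < 2) return(0)
  be <- bond_free_energies(params, geom, T_C)
  fr <- solve_bond_fractions(be$dG_bridge, be$dG_loop, N)
  Abar <- unstretched_area(params, T_C)
  hybridization_free_energy(fr) - 2 * N * log(geom$A / Abar)
}

#' Reference energy of two isolated unstretched vesicles
#'
#' `U0` is the hybridization free energy of a pair of isolated, unstretched
#' GUVs in which only loops can form (no patch, `q_b = 0`), evaluated at
#' `A = Abar(T)`. It is independent of the trial contact angle and anchors
#' `U(theta; T)` so that the interaction energy vanishes for a melted,
#' unstretched pair.
#'
#' @inheritParams membrane_energy
#' @return Energy in kBT (non-positive).
#' @export
reference_energy <- function(params, T_C) {
  N <- tethers_per_vesicle(params$rho_dna, params$R0)
  if (N < 2) return(0)
  Abar <- unstretched_area(params, T_C)
  dG_l0 <- duplex_free_energy0(params, T_C) +
    rotational_entropy_cost(params$L, params$rho0) +
    translational_entropy_cost(Abar, Abar, params$L)
  q_l0 <- (N / 2) * exp(-dG_l0)
  x0 <- .bound_fractions(0, q_l0)$x
  2 * N * (log1p(-x0) + x0 / 2)
}

#' Total pair interaction free energy at a trial contact angle
#'
#' `U(theta; T) = U_membrane + U_DNA - U0`, vectorized over `theta`.
#'
#' @param theta Trial contact angle(s), rad, in `[0, 89 deg]`.
#' @param params A [model_params()] object.
#' @param T_C Temperature, degC.
#' @return Energy in kBT.
#' @export
total_energy <- function(theta, params, T_C) {
  if (any(theta < 0 | theta > .THETA_MAX + 1e-12)) {
    stop("theta must be in [0, 89 deg]")
  }
  g <- .geometry_grid(theta, params$R0, params$L)
  .energy_profile(g, params, T_C)$U_total
}

# Vectorized energy over a geometry grid; returns all components.
.energy_profile <- function(g, params, T_C) {
  Abar <- unstretched_area(params, T_C)
  Abar_nm2 <- Abar * .NM2_PER_UM2
  Ka_kbt <- stretch_modulus_kbt_nm2(params$Ka, T_C)
  A_nm2 <- g$A * .NM2_PER_UM2
  U_mem <- Ka_kbt * (A_nm2 - Abar_nm2)^2 / Abar_nm2

  N <- tethers_per_vesicle(params$rho_dna, params$R0)
  if (N >= 2) {
    dG0 <- duplex_free_energy0(params, T_C)
    rot <- rotational_entropy_cost(params$L, params$rho0)
    # q_i = (N/2) exp(-dG0 - rot - trans_i), trans_i = ln(A^2/(4 pi L^2 avail))
    log_pref <- log(N / 2) - dG0 - rot + log(4 * pi * params$L^2)
    q_l <- exp(log_pref - log(A_nm2))             # avail = A
    q_b <- exp(log_pref + log(g$Ap_eff * .NM2_PER_UM2) - 2 * log(A_nm2))
    xs <- .bound_fractions(q_b, q_l)
    U_hyb <- 2 * N * (log1p(-xs$x) + xs$x / 2)
    U_conf <- -2 * N * log(g$A / Abar)
    U0 <- reference_energy(params, T_C)
    U_dna <- U_hyb + U_conf
  } else {
    xs <- list(x = 0, x_b = rep(0, length(g$A)), x_l = rep(0, length(g$A)))
    U_dna <- rep(0, length(g$A))
    U0 <- 0
  }
  list(U_membrane = U_mem, U_dna = U_dna, U0 = U0,
       U_total = U_mem + U_dna - U0, x_b = xs$x_b, x_l = xs$x_l,
       tension = params$Ka * (g$A - Abar) / Abar)
}

# Precompute the theta-grid geometry (independent of temperature and of all
# propagated parameters; depends only on R0 and L).
.theta_cache <- function(R0, L, step_deg = 0.05,
                         theta_min_deg = 0.1, theta_max_deg = 89) {
  th <- seq(theta_min_deg, theta_max_deg, by = step_deg) * pi / 180
  list(grid = .geometry_grid(th, R0, L), step_rad = step_deg * pi / 180,
       R0 = R0, L = L)
}

#' Equilibrium state of the pair at one temperature
#'
#' Minimizes [total_energy()] over the trial contact angle with a dense grid
#' scan (default step 0.05 deg on `[0.1 deg, 89 deg]`) followed by local
#' refinement, and evaluates every observable at the optimum. Deterministic.
#' The global grid-then-refine search (rather than a single local descent)
#' guards against bound/unbound double minima near the DNA melting region.
#'
#' @param params A [model_params()] object.
#' @param T_C Temperature, degC.
#' @param step_deg Grid step for the scan, degrees.
#' @param refine `"optimize"` (golden-section refinement of the bracketing
#'   interval to 1e-4 rad, the default) or `"parabolic"` (vertex of the
#'   parabola through the best grid point and its neighbours; no extra energy
#'   evaluations, used in heavy Monte-Carlo loops).
#' @param cache Optional precomputed grid from the internal theta cache;
#'   reused across temperatures and parameter draws.
#' @return A one-row [tibble::tibble()] with columns `T_C`, `theta_deg`,
#'   `theta0_deg` (zero-stretch reference angle), `R_um`, `A_um2`, `Ap_um2`,
#'   `Apeff_um2`, `D_um`, `V_um3`, `x_b`, `x_l`, `tension_mN_m`,
#'   `U_membrane_kBT`, `U_dna_kBT`, `U_total_kBT` and `flat` (TRUE when the
#'   energy landscape is flat — no DNA and no excess area — in which case
#'   `theta = 0` is returned).
#' @examples
#' \donttest{
#' equilibrium_state(model_params(), 40)
#' }
#' @export
equilibrium_state <- function(params, T_C, step_deg = 0.05,
                              refine = c("optimize", "parabolic"),
                              cache = NULL) {
  refine <- match.arg(refine)
  validate_model_params(params)
  if (is.null(cache)) cache <- .theta_cache(params$R0, params$L, step_deg)
  g <- cache$grid
  prof <- .energy_profile(g, params, T_C)
  U <- prof$U_total
  i <- which.min(U)

  flat <- diff(range(U)) < 1e-9 * max(1, abs(U[i]))
  if (flat) {
    theta_star <- 0
  } else if (refine == "parabolic" && i > 1 && i < length(U)) {
    num <- U[i - 1] - U[i + 1]
    den <- 2 * (U[i - 1] - 2 * U[i] + U[i + 1])
    theta_star <- g$theta[i] + ifelse(den > 0, num / den * cache$step_rad, 0)
  } else {
    lo <- if (i > 1) g$theta[i - 1] else 0
    hi <- if (i < length(U)) g$theta[i + 1] else g$theta[i]
    opt <- stats::optimize(function(th) {
      gp <- .geometry_grid(th, params$R0, params$L)
      .energy_profile(gp, params, T_C)$U_total
    }, lower = lo, upper = hi, tol = 1e-4)
    # never accept a refinement worse than the best grid point
    theta_star <- if (opt$objective <= U[i]) opt$minimum else g$theta[i]
  }

  gs <- .geometry_grid(theta_star, params$R0, params$L)
  ps <- .energy_profile(gs, params, T_C)
  theta0 <- zero_stretch_angle(params, T_C)
  tibble::tibble(
    T_C = T_C,
    theta_deg = theta_star * 180 / pi,
    theta0_deg = theta0 * 180 / pi,
    R_um = gs$R, A_um2 = gs$A, Ap_um2 = gs$Ap, Apeff_um2 = gs$Ap_eff,
    D_um = gs$D, V_um3 = gs$V,
    x_b = ps$x_b, x_l = ps$x_l,
    tension_mN_m = ps$tension,
    U_membrane_kBT = ps$U_membrane, U_dna_kBT = ps$U_dna,
    U_total_kBT = ps$U_total,
    flat = flat)
}

#' Predicted equilibrium observables over a temperature grid
#'
#' Runs [equilibrium_state()] at every temperature of the grid.
#'
#' @param params A [model_params()] object.
#' @param T_grid Non-empty numeric vector of temperatures, degC.
#' @param ... Passed to [equilibrium_state()].
#' @return A [tibble::tibble()] with one row per temperature (the prediction
#'   table; see [write_predictions()] for the on-disk schema).
#' @examples
#' \donttest{
#' predict_curve(model_params(), c(0, 20, 40))
#' }
#' @export
predict_curve <- function(params, T_grid, ...) {
  if (length(T_grid) == 0) stop("T_grid must be non-empty")
  validate_model_params(params)
  cache <- .theta_cache(params$R0, params$L)
  do.call(rbind, lapply(T_grid, function(T_C) {
    equilibrium_state(params, T_C, cache = cache, ...)
  }))
}
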