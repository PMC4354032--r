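# Hybridization thermodynamics of mobile tethered DNA linkers: per-bond free
# energies for bridges (inter-vesicle) and loops (intra-vesicle), and the
# mean-field (saddle-point) solution for the equilibrium bond fractions.

#' Number of DNA tethers per vesicle
#'
#' Tethers are grafted at the reference area, so the count is fixed at
#' `N = rho_dna * 4 pi R0^2` and does not track the instantaneous area.
#' Half the tethers carry each of the two complementary sticky-end species.
#'
#' @param rho_dna Tether surface density, 1/um^2.
#' @param R0 Reference radius, um.
#' @return Tether count per vesicle.
#' @examples
#' tethers_per_vesicle(390, 10)  # ~4.9e5
#' @export
tethers_per_vesicle <- function(rho_dna, R0) {
  if (any(rho_dna < 0) || any(R0 <= 0)) stop("rho_dna must be >= 0 and R0 > 0")
  rho_dna * 4 * pi * R0^2
}

#' Rotational entropy cost of forming a tethered bond
#'
#' Orientational (pivoting) entropy lost when two freely pivoting rigid rods
#' of length `L` with point sticky ends hybridize, averaged over the lateral
#' displacement of the tethering points: `ln(4 pi rho0 L^3)` in kBT. After
#' displacement averaging the cost is identical for loops and bridges.
#'
#' Derivation bookkeeping: for tether points at distance `d_t`, the bound-pair
#' configurational density is `K / (2 pi rho0 d_t L^2)` (two spheres of radius
#' `L` in bipolar coordinates), with orbit factor `K = 1/2` for loops (half
#' the orbit excluded by the membrane plane) and `K = 1` for bridges. For
#' loops `d_t = y` with lateral displacement `y <= 2L`; for bridges, with
#' inter-membrane distance `L`, `d_t = sqrt(L^2 + y^2)` and `y <= sqrt(3) L`.
#' Both displacement integrals (weight `2 pi y dy`) equal `1/(rho0 L)`
#' exactly, and dividing by the reference disc `4 pi L^2` of the
#' translational term gives the same `1/(4 pi rho0 L^3)` Boltzmann weight for
#' either bond type.
#'
#' @param L Tether length, nm.
#' @param rho0 Reference concentration, 1/nm^3.
#' @return Cost `-T dS_rot` in kBT (positive).
#' @examples
#' rotational_entropy_cost(14.5, 0.6)  # ~10.0 kBT
#' @export
rotational_entropy_cost <- function(L, rho0) {
  if (any(L <= 0) || any(rho0 <= 0)) stop("L and rho0 must be > 0")
  log(4 * pi * rho0 * L^3)
}

#' Translational entropy cost of forming a tethered bond
#'
#' Mobile tethering points lose translational freedom on binding: two unbound
#' tethers explore `A^2` (positions on a vesicle of area `A`), while a bound
#' pair explores the area available to that bond type. The cost is
#' `ln(A^2 / (4 pi L^2 * area_available))` in kBT; the `4 pi L^2` reference
#' disc makes the rotational and translational pieces combine exactly into
#' the dimensionless bond weight `area_available / (rho0 L A^2)`.
#' `area_available = A` for loops and the effective patch area `Ap_eff` for
#' bridges, which is why bridge formation is entropically disfavoured when
#' the patch is small.
#'
#' @param area_available Area available to the bound pair, um^2.
#' @param A Total vesicle area, um^2.
#' @param L Tether length, nm.
#' @return Cost `-T dS_trans` in kBT.
#' @examples
#' translational_entropy_cost(4 * pi * 100, 4 * pi * 100, 14.5)  # ~13.1 kBT
#' @export
translational_entropy_cost <- function(area_available, A, L) {
  if (any(area_available <= 0) || any(A <= 0)) stop("areas must be > 0")
  if (any(L <= 0)) stop("L must be > 0")
  A_nm2 <- A * .NM2_PER_UM2
  avail_nm2 <- area_available * .NM2_PER_UM2
  log(A_nm2^2 / (4 * pi * L^2 * avail_nm2))
}

#' Per-bond free energies for bridges and loops
#'
#' Total hybridization free energy of a single tethered bond,
#' `dG = dG0(T) + (-T dS_rot) + (-T dS_trans)`, in kBT at the given
#' temperature. The geometry enters only through the translational term (the
#' total area `A` for loops, the effective patch area `Ap_eff` for bridges),
#' so `dG_loop - dG_bridge = ln(Ap_eff / A)` exactly.
#'
#' @param params A [model_params()] object.
#' @param geom A `pair_geometry` from [geometry_at_angle()].
#' @param T_C Temperature, degC.
#' @return A `bond_energies` list: `dG0`, `dS_rot_cost`,
#'   `dS_trans_bridge_cost`, `dS_trans_loop_cost`, `dG_bridge`, `dG_loop`
#'   (all kBT).
#' @export
bond_free_energies <- function(params, geom, T_C) {
  stopifnot(inherits(geom, "pair_geometry"))
  dG0 <- duplex_free_energy0(params, T_C)
  rot <- rotational_entropy_cost(params$L, params$rho0)
  tr_l <- translational_entropy_cost(geom$A, geom$A, params$L)
  tr_b <- translational_entropy_cost(geom$Ap_eff, geom$A, params$L)
  structure(list(dG0 = dG0,
                 dS_rot_cost = rot,
                 dS_trans_bridge_cost = tr_b,
                 dS_trans_loop_cost = tr_l,
                 dG_bridge = dG0 + rot + tr_b,
                 dG_loop = dG0 + rot + tr_l),
            class = "bond_energies")
}

#' Equilibrium bridge and loop fractions (mean-field gap equations)
#'
#' Solves the self-consistent mass-action (gap) equations for a symmetric
#' pair of vesicles carrying `N` tethers each (N/2 per sticky-end species):
#' `x_i = (1 - x_b - x_l)^2 * q_i` with bond strengths
#' `q_i = (N/2) exp(-dG_i)`. The multiplicity `N/2` carries the combinatorial
#' "any tether can bind N partners" attraction (magnitude `ln N` in kBT,
#' about 13 for typical coatings); no separate additive `-ln N` term is
#' applied. The closed-form solution for the total bound fraction
#' `x = x_b + x_l` with `q = q_b + q_l` is
#' `x = (1 + 2q - sqrt(1 + 4q)) / (2q)`, evaluated in the numerically stable
#' form `x = 1 - 2 / (1 + sqrt(1 + 4q))`, which also reproduces the small-q
#' series `x ~ q - 2 q^2` without cancellation.
#'
#' @param dG_b Bridge bond free energy, kBT.
#' @param dG_l Loop bond free energy, kBT.
#' @param N Tethers per vesicle; must be >= 2.
#' @return A `bond_fractions` list: `x_b`, `x_l`, `q_b`, `q_l`, `N`.
#' @examples
#' # q_b = q_l = 1 gives x_b = x_l = 1/4 exactly
#' f <- solve_bond_fractions(log(2 / 2), log(2 / 2), 2)
#' @export
solve_bond_fractions <- function(dG_b, dG_l, N) {
  if (any(N < 2)) stop("N must be >= 2: a tether needs at least one partner")
  q_b <- (N / 2) * exp(-dG_b)
  q_l <- (N / 2) * exp(-dG_l)
  xs <- .bound_fractions(q_b, q_l)
  structure(list(x_b = xs$x_b, x_l = xs$x_l, q_b = q_b, q_l = q_l, N = N),
            class = "bond_fractions")
}

# vectorized core: stable closed form of the gap equations
.bound_fractions <- function(q_b, q_l) {
  q <- q_b + q_l
  x <- 1 - 2 / (1 + sqrt(1 + 4 * q))
  share <- ifelse(q > 0, q_b / q, 0)
  list(x = x, x_b = x * share, x_l = x * (1 - share))
}

#' Mean-field hybridization free energy of the pair
#'
#' Equilibrium free energy of the 2N-linker system relative to the fully
#' unbound state: `U_hyb = 2 N [ln(1 - x) + x/2]` kBT with total bound
#' fraction `x = x_b + x_l`. Always non-positive; in the weak-binding limit
#' it tends to `-N x` (one kBT of attraction per formed bond).
#'
#' @param fractions A `bond_fractions` object from [solve_bond_fractions()],
#'   or a list with fields `x_b`, `x_l`, `N`.
#' @return Energy in kBT.
#' @export
hybridization_free_energy <- function(fractions) {
  x <- fractions$x_b + fractions$x_l
  if (any(x < 0 | x >= 1)) stop("bound fraction must be in [0, 1)")
  2 * fractions$N * (log1p(-x) + x / 2)
}

#' Exact bridge/loop statistics by partition-function enumeration
#'
#' Independent finite-N reference for [solve_bond_fractions()] and
#' [hybridization_free_energy()]: sums the exact partition function over all
#' pairings of `m` tethers per sticky-end species per vesicle, with per-bond
#' Boltzmann weights `exp(-dG)`. Configurations are counted by the number of
#' loops on each vesicle (`n_l1`, `n_l2`) and bridges in each direction;
#' because the two bridge directions draw on disjoint tether pools, the sum
#' factorizes and costs `O(m^3)`. For large `m` the sum may be restricted to
#' a window of half-width `window` standard-deviation-scaled counts around
#' the mean-field solution; terms outside are negligible.
#'
#' @param m Tethers per species per vesicle (total per vesicle `N = 2 m`).
#' @param dG_b,dG_l Bond free energies, kBT.
#' @param window Optional half-width (in units of `sqrt(N)`) of the
#'   enumeration window; `NULL` (default) enumerates the full range, which is
#'   advisable for `m` up to a few hundred.
#' @return List with exact `x_b`, `x_l` (expected fraction of a vesicle's
#'   tethers in bridges/loops) and `U_hyb = -ln Z` in kBT.
#' @export
exact_bond_fractions <- function(m, dG_b, dG_l, window = NULL) {
  if (m < 1 || m != round(m)) stop("m must be a positive integer")
  log_chi_b <- -dG_b
  log_chi_l <- -dG_l
  rng_l <- 0:m
  if (!is.null(window)) {
    mf <- solve_bond_fractions(dG_b, dG_l, 2 * m)
    half <- ceiling(window * sqrt(2 * m))
    ctr_l <- round(mf$x_l * m)
    rng_l <- max(0, ctr_l - half):min(m, ctr_l + half)
  }
  # loop multiplicity on one vesicle: C(m, nl)^2 * nl!
  log_loop <- 2 * lchoose(m, rng_l) + lfactorial(rng_l) + rng_l * log_chi_l

  # S(a, b) = sum_j C(a, j) C(b, j) j! chi_b^j over bridges of one direction,
  # with a = m - n_l1 remaining donors and b = m - n_l2 remaining acceptors.
  bridge_sums <- function(a, b) {
    j <- 0:min(a, b)
    if (!is.null(window)) {
      mf <- solve_bond_fractions(dG_b, dG_l, 2 * m)
      half <- ceiling(window * sqrt(2 * m))
      ctr <- round(mf$x_b * m)
      j <- j[j >= ctr - half & j <= ctr + half]
      if (length(j) == 0) j <- 0
    }
    lw <- lchoose(a, j) + lchoose(b, j) + lfactorial(j) + j * log_chi_b
    M <- max(lw)
    w <- exp(lw - M)
    s <- sum(w)
    list(logS = M + log(s), mean_j = sum(j * w) / s)
  }

  n1 <- length(rng_l)
  logW <- matrix(-Inf, n1, n1)
  mj <- matrix(0, n1, n1)
  for (i1 in seq_len(n1)) {
    for (i2 in seq_len(i1)) {
      bs <- bridge_sums(m - rng_l[i1], m - rng_l[i2])
      lw <- log_loop[i1] + log_loop[i2] + 2 * bs$logS
      logW[i1, i2] <- lw
      logW[i2, i1] <- lw
      mj[i1, i2] <- bs$mean_j
      mj[i2, i1] <- bs$mean_j
    }
  }
  M <- max(logW)
  W <- exp(logW - M)
  Z <- sum(W)
  # tethers on vesicle 1: 2 n_l1 in loops, n_b1 + n_b2 = 2 <j> in bridges
  Exl <- sum(W * (2 * rng_l[row(W)])) / Z / (2 * m)
  Exb <- sum(W * (2 * mj)) / Z / (2 * m)
  list(x_b = Exb, x_l = Exl, U_hyb = -(M + log(Z)))
}
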