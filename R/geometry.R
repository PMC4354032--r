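# Closed-form geometry of two identical truncated spheres joined at a flat
# adhesion patch. The trial contact angle theta parametrizes every observable
# under the constant-volume (water-impermeable) closure: the radius R of the
# spherical segment is chosen so the enclosed volume equals the reference
# sphere volume 4/3 pi R0^3 at every angle.

.THETA_MAX <- 89 * pi / 180  # cap: avoid the degenerate hemisphere limit

#' Pair geometry at a trial contact angle
#'
#' Geometry of one vesicle in a symmetric adhering pair, at trial contact
#' angle `theta`, under constant enclosed volume. With `c = cos(theta)`:
#' `V = (pi/3) R^3 (1+c)^2 (2-c)`, free spherical area `2 pi R^2 (1+c)`,
#' patch `Ap = pi R^2 (1-c^2)`, total area `A = 2 pi R^2 (1+c) + Ap`,
#' centre-to-centre distance `D = 2 R c`, and
#' `R = R0 * (4 / ((1+c)^2 (2-c)))^(1/3)` so that `V = 4/3 pi R0^3`.
#' `D` excludes the ~15 nm inter-membrane gap, which is below optical
#' resolution.
#'
#' @param theta Trial contact angle, rad, in `[0, pi/2)` (capped at 89 deg).
#' @param R0 Reference radius, um.
#' @param L Tether length, nm (enters only the effective bridge-formation
#'   area `Ap_eff`, see [effective_patch_area()]).
#' @return A `pair_geometry` object: list with fields `theta` (rad), `R` (um),
#'   `A`, `Ap`, `Ap_eff` (um^2), `D` (um), `V` (um^3), `nu` (dimensionless
#'   reduced volume).
#' @examples
#' g <- geometry_at_angle(60 * pi / 180, R0 = 10, L = 14.5)
#' g$Ap  # ~264 um^2
#' @export
geometry_at_angle <- function(theta, R0, L = 14.5) {
  if (!is.numeric(theta) || length(theta) != 1 || !is.finite(theta)) {
    stop("theta must be a finite numeric scalar")
  }
  if (theta < 0 || theta >= pi / 2) stop("theta must be in [0, pi/2)")
  if (R0 <= 0) stop("R0 must be > 0")
  g <- .geometry_grid(theta, R0, L)
  structure(lapply(g, `[`, 1L), class = "pair_geometry")
}

#' @export
print.pair_geometry <- function(x, ...) {
  cat(sprintf(
    "pair geometry: theta = %.3f deg, R = %.4g um, A = %.5g um^2,\n  Ap = %.4g um^2 (eff %.4g), D = %.4g um, V = %.5g um^3, nu = %.5f\n",
    x$theta * 180 / pi, x$R, x$A, x$Ap, x$Ap_eff, x$D, x$V, x$nu))
  invisible(x)
}

# Vectorized core used by the minimizer; theta in rad, R0 um, L nm.
.geometry_grid <- function(theta, R0, L) {
  cth <- cos(theta)
  R <- R0 * (4 / ((1 + cth)^2 * (2 - cth)))^(1 / 3)
  Ap <- pi * R^2 * (1 - cth^2)
  A <- 2 * pi * R^2 * (1 + cth) + Ap
  V <- (pi / 3) * R^3 * (1 + cth)^2 * (2 - cth)
  L_um <- L * 1e-3
  # rim ring: 2 pi (R sin th) * L/(2 tan th) = pi R L cos th, continuous at 0
  Ap_eff <- Ap + pi * R * L_um * cth
  list(theta = theta, R = R, A = A, Ap = Ap, Ap_eff = Ap_eff,
       D = 2 * R * cth, V = V, nu = reduced_volume_of_angle(theta))
}

#' Reduced volume of the pair geometry at a trial contact angle
#'
#' Scale-free sphericity measure `nu = 6 sqrt(pi) V / A^(3/2)`, which for the
#' truncated-sphere pair reduces to the closed form
#' `2 sqrt(1+c) (2-c) / (3-c)^(3/2)` with `c = cos(theta)`. Equals 1 for an
#' untruncated sphere and decreases strictly with the angle.
#'
#' @param theta Trial contact angle, rad, in `[0, pi/2)` (vectorized).
#' @return Reduced volume, dimensionless.
#' @export
reduced_volume_of_angle <- function(theta) {
  if (!is.numeric(theta) || any(!is.finite(theta))) stop("theta must be numeric")
  if (any(theta < 0 | theta >= pi / 2)) stop("theta must be in [0, pi/2)")
  cth <- cos(theta)
  2 * sqrt(1 + cth) * (2 - cth) / (3 - cth)^1.5
}

#' Unstretched membrane area at a temperature
#'
#' Linear thermal area expansion about the neutral temperature:
#' `A_bar(T) = 4 pi R0^2 (1 + alpha (T - T0))`.
#'
#' @param params A [model_params()] object.
#' @param T_C Temperature, degC (vectorized).
#' @return Area in um^2.
#' @export
unstretched_area <- function(params, T_C) {
  f <- 1 + params$alpha * (T_C - params$T0)
  if (any(f <= 0)) stop("unstretched area would be non-positive at this temperature")
  4 * pi * params$R0^2 * f
}

#' Reduced volume of an isolated vesicle at a temperature
#'
#' Under constant volume and thermal area expansion,
#' `nu(T) = (1 + alpha (T - T0))^(-3/2)`: below 1 for `T > T0` (excess area,
#' floppy vesicle), above 1 for `T < T0` (turgid sphere).
#'
#' @inheritParams unstretched_area
#' @return Reduced volume, dimensionless.
#' @export
reduced_volume_of_temperature <- function(params, T_C) {
  f <- 1 + params$alpha * (T_C - params$T0)
  if (any(f <= 0)) stop("non-physical thermal contraction: 1 + alpha (T - T0) <= 0")
  f^(-1.5)
}

#' Zero-stretching contact angle
#'
#' The contact angle a pair of adhering vesicles adopts when the adhesion
#' consumes exactly the thermally generated excess area, without stretching
#' the bilayer: the root of
#' `reduced_volume_of_angle(theta) = reduced_volume_of_temperature(T)`.
#' Returns 0 for `T <= T0` (turgid spheres, no excess area).
#'
#' @inheritParams unstretched_area
#' @param tol Bisection tolerance on the angle, rad.
#' @return Angle in rad.
#' @export
zero_stretch_angle <- function(params, T_C, tol = 1e-6) {
  nu_T <- reduced_volume_of_temperature(params, T_C)
  vapply(nu_T, .angle_of_reduced_volume, numeric(1), tol = tol)
}

.angle_of_reduced_volume <- function(nu, tol = 1e-6) {
  if (nu >= 1) return(0)
  lo <- 0
  hi <- pi / 2 - 1e-9
  if (nu < reduced_volume_of_angle(hi)) {
    stop("excess area beyond the geometric range of the truncated-sphere pair")
  }
  stats::uniroot(function(th) reduced_volume_of_angle(th) - nu,
                 lower = lo, upper = hi, tol = tol)$root
}

#' Effective patch area for bridge formation
#'
#' Bridges of tether length `L` can form not only within the flat contact
#' disc but also in a narrow rim around it, where the membranes diverge with
#' gap `L + 2 s tan(theta)` at distance `s` outside the patch edge; bridges
#' remain possible while the gap is at most `2L`, i.e. within rim width
#' `s* = L / (2 tan(theta))`. The resulting ring area `2 pi R sin(theta) s*`
#' equals `pi R L cos(theta)`, continuous in the angle with limit `pi R L`
#' as `theta -> 0`, which keeps the bridge-formation area finite when the
#' flat patch closes.
#'
#' @param geom A `pair_geometry` object from [geometry_at_angle()].
#' @param L Tether length, nm.
#' @return Effective area `Ap_eff = Ap + pi R L cos(theta)`, um^2.
#' @export
effective_patch_area <- function(geom, L) {
  stopifnot(inherits(geom, "pair_geometry"))
  geom$Ap + pi * geom$R * (L * 1e-3) * cos(geom$theta)
}
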