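# Image-analysis estimators: turn per-frame measurements (fitted circle
# radii, patch chord length, mean fluorescence intensities) into geometric
# observables and the bridge fraction. The pipeline starts from fitted
# quantities; actual image processing is out of scope.

#' Patch area from the patch chord length
#'
#' Flat-disc approximation: `Ap = pi (Lp/2)^2`, neglecting the slight
#' curvature of the adhesion patch.
#'
#' @param Lp Chord length subtended by the patch arc, um (>= 0).
#' @return Patch area, um^2.
#' @export
patch_area_from_chord <- function(Lp) {
  if (any(Lp < 0)) stop("Lp must be >= 0")
  pi * (Lp / 2)^2
}

#' Contact angle from chord and fitted radius
#'
#' `theta = asin(Lp / (2 R))`, again neglecting patch curvature.
#'
#' @param Lp Chord length, um; must satisfy `0 <= Lp <= 2 R`.
#' @param R Fitted circle radius, um.
#' @return Angle, rad.
#' @export
contact_angle_from_chord <- function(Lp, R) {
  if (any(Lp < 0)) stop("Lp must be >= 0")
  if (any(Lp > 2 * R)) stop("Lp cannot exceed the circle diameter 2R")
  asin(Lp / (2 * R))
}

#' Total vesicle area from fitted radius, angle and patch area
#'
#' `A = 2 pi R^2 (1 + cos(theta)) + Ap`: spherical segment plus adhesion
#' disc.
#'
#' @param R Fitted radius, um.
#' @param theta Contact angle, rad.
#' @param Ap Patch area, um^2.
#' @return Total area, um^2.
#' @export
total_area_from_fit <- function(R, theta, Ap) {
  if (any(R <= 0) || any(Ap < 0)) stop("R must be > 0 and Ap >= 0")
  2 * pi * R^2 * (1 + cos(theta)) + Ap
}

#' Bridge fraction from fluorescence intensities
#'
#' Estimates the fraction of a vesicle's tethers forming bridges from the
#' mean background-subtracted intensities of the free membrane (`Iv`) and the
#' adhesion patch (`Ip`). The patch carries two membranes' worth of
#' loop/unbound signal plus the bridges, and both vesicles contribute to the
#' detected patch fluorescence (hence the factor 1/2):
#' per-vesicle non-bridge signal `S_v = (Iv - Ibg) A`, per-vesicle bridge
#' signal `S_b = (1/2) (Ip - 2 Iv + Ibg) Ap`, and
#' `x_b = S_b / (S_b + S_v)`, clipped to `[0, 1]`. The estimator is a ratio
#' of intensities, so any common rescaling of the background-subtracted
#' signals — in particular the monotonic temperature decay of the
#' intercalating dye's brightness — cancels. The ~10% brightness increase of
#' a bound tether pair (95 vs 86 paired bases) is deliberately neglected, as
#' in the imaging analysis it mirrors; [generate_pair_series()] can switch it
#' on to quantify the resulting bias.
#'
#' With `method = "one-membrane"` the patch is instead diminished by a single
#' membrane's signal, `S_b = (1/2) (Ip - Iv) Ap`; this variant overestimates
#' the bridge signal by half the non-bridge patch contribution and is kept
#' only for comparison.
#'
#' @param rec A list or one-row data frame with fields `Iv`, `Ip`, `Ibg`
#'   (arbitrary units); `Ip >= Ibg` and `Iv >= Ibg` required.
#' @param A Total vesicle area, um^2.
#' @param Ap Patch area, um^2.
#' @param method `"two-membrane"` (default, unbiased on the forward model) or
#'   `"one-membrane"`.
#' @return Estimated bridge fraction in `[0, 1]`; `NA` (with a warning) when
#'   the total signal is non-positive.
#' @export
bridge_fraction_from_intensities <- function(rec, A, Ap,
                                             method = c("two-membrane",
                                                        "one-membrane")) {
  method <- match.arg(method)
  if (any(A <= 0)) stop("A must be > 0")
  if (any(rec$Ip < rec$Ibg) || any(rec$Iv < rec$Ibg)) {
    stop("intensities must satisfy Ip >= Ibg and Iv >= Ibg")
  }
  S_v <- (rec$Iv - rec$Ibg) * A
  excess <- if (method == "two-membrane") {
    rec$Ip - 2 * rec$Iv + rec$Ibg
  } else {
    rec$Ip - rec$Iv
  }
  S_b <- 0.5 * excess * Ap
  tot <- S_b + S_v
  out <- ifelse(tot > 0, pmin(1, pmax(0, S_b / tot)), NA_real_)
  if (any(is.na(out))) warning("non-positive total signal: bridge fraction undefined")
  out
}

#' DNA surface coverage from calibrated confocal intensity
#'
#' Converts the mean equatorial membrane intensity of a confocal
#' cross-section into a tether surface density. The bookkeeping assumes the
#' membrane band inside a slice of thickness `delta` (area `2 pi R delta`)
#' projects onto an annulus of radial width `delta^2 / (8 R)`, so the mean
#' intensity scales as `Iv - Id = C d rho 8 R / delta` with per-strand
#' brightness `C d` (calibration constant `C`, pixel size `d`). Inverting,
#' the surface intensity is `J = (Iv - Id) / (8 d R)` and
#' `rho_dna = J delta / C`; the slice thickness cancels between `J`'s
#' `1/delta` intensity scaling and the explicit factor, which
#' [generate_calibration_series()]-based tests verify.
#'
#' @param Iv Mean membrane intensity, a.u.
#' @param Id Sensor dark signal, a.u.; `Iv > Id` required for a nonzero
#'   coverage (`Iv == Id` gives 0).
#' @param R Vesicle radius, um.
#' @param delta Confocal slice thickness (z-resolution), um.
#' @param C Calibration constant, um (see [fit_coverage_calibration()]).
#' @param d Pixel size, um.
#' @return Coverage `rho_dna`, 1/um^2.
#' @export
coverage_from_calibration <- function(Iv, Id, R, delta, C = 2.7, d = 0.076) {
  if (any(R <= 0) || any(delta <= 0) || any(C <= 0) || any(d <= 0)) {
    stop("R, delta, C and d must be > 0")
  }
  if (any(Iv < Id)) stop("Iv must be >= the dark signal Id")
  J <- (Iv - Id) / (8 * d * R)
  J * delta / C
}

#' Fit the intensity calibration constant from a bulk dilution series
#'
#' The reference intensity of free DNA at number density `n`, diminished by
#' the dark signal, scales linearly with `n`: `I - Id = C d delta n`. A
#' least-squares line through the series recovers `C`.
#'
#' @param calib Data frame with columns `n` (1/um^3) and `intensity` (a.u.),
#'   e.g. from [generate_calibration_series()].
#' @param Id Dark signal, a.u.
#' @param d Pixel size, um.
#' @param delta Slice thickness, um.
#' @return Fitted `C`, um.
#' @export
fit_coverage_calibration <- function(calib, Id, d = 0.076, delta = 0.5) {
  if (nrow(calib) < 2) stop("calibration series needs at least 2 points")
  slope <- stats::coef(stats::lm(I(intensity - Id) ~ n + 0, data = calib))[["n"]]
  slope / (d * delta)
}

#' Estimate observables from an observation table
#'
#' Applies the chord/intensity estimators row-wise to an observation table
#' (see [generate_pair_series()] for the schema) and returns the estimates
#' table with per-vesicle contact angles and areas and the bridge fraction.
#'
#' @param obs Data frame with columns `T_C`, `R1_um`, `R2_um`, `Lp_um`,
#'   `Iv`, `Ip`, `Ibg`.
#' @param method Passed to [bridge_fraction_from_intensities()].
#' @return A [tibble::tibble()] with columns `T_C`, `theta1_deg`,
#'   `theta2_deg`, `Ap_um2`, `A1_um2`, `A2_um2`, `x_b`.
#' @export
estimate_observables <- function(obs, method = "two-membrane") {
  need <- c("T_C", "R1_um", "R2_um", "Lp_um", "Iv", "Ip", "Ibg")
  miss <- setdiff(need, names(obs))
  if (length(miss) > 0) {
    stop("observation table is missing columns: ", paste(miss, collapse = ", "))
  }
  Lp <- pmin(obs$Lp_um, 2 * pmin(obs$R1_um, obs$R2_um))
  th1 <- contact_angle_from_chord(Lp, obs$R1_um)
  th2 <- contact_angle_from_chord(Lp, obs$R2_um)
  Ap <- patch_area_from_chord(Lp)
  A1 <- total_area_from_fit(obs$R1_um, th1, Ap)
  A2 <- total_area_from_fit(obs$R2_um, th2, Ap)
  x_b <- bridge_fraction_from_intensities(obs, (A1 + A2) / 2, Ap,
                                          method = method)
  tibble::tibble(T_C = obs$T_C,
                 theta1_deg = th1 * 180 / pi, theta2_deg = th2 * 180 / pi,
                 Ap_um2 = Ap, A1_um2 = A1, A2_um2 = A2, x_b = x_b)
}
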