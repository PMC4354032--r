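# Synthetic per-temperature observation tables with the statistical
# structure the analysis assumes: geometry from the forward model plus
# Gaussian measurement noise, and intensity triplets (free membrane, patch,
# background) consistent with the predicted bridge fraction, the DNA
# coverage, and a monotonically temperature-decreasing dye brightness.

.IBG_DEFAULT <- 10    # background intensity baseline, a.u.
.B0_DEFAULT <- 0.25   # brightness per tether per um^-2 of density, a.u. um^2

#' Fractional brightness increment of a bound tether pair
#'
#' A hybridized tether pair carries 95 paired bases against 86 for two
#' unbound tethers, so an intercalating stain reports bound pairs about 10%
#' brighter: `(95 - 86) / 86`.
#'
#' @return Dimensionless increment (~0.105).
#' @export
duplex_brightness_increment <- function() {
  (95 - 86) / 86
}

#' Measurement-noise specification for synthetic observations
#'
#' @param sigma_R Radius noise, um.
#' @param sigma_Lp Patch chord noise, um.
#' @param intensity_cv Relative (multiplicative Gaussian) intensity noise.
#' @param brightness_slope Fractional dye-brightness decay per degC about
#'   20 degC; the stain dims monotonically on heating. Brightness must stay
#'   positive over the simulated grid.
#' @param include_duplex_brightness If TRUE, bound tethers are weighted by
#'   `1 + duplex_brightness_increment()` in the intensity model (the
#'   estimator deliberately neglects this, so switching it on quantifies the
#'   estimator's bias).
#' @param seed Integer seed for reproducible noise.
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(sigma_R = 0.1, sigma_Lp = 0.1, intensity_cv = 0.02,
                       brightness_slope = 0.005,
                       include_duplex_brightness = FALSE, seed = 1L) {
  if (sigma_R < 0 || sigma_Lp < 0 || intensity_cv < 0) {
    stop("noise scales must be >= 0")
  }
  structure(list(sigma_R = sigma_R, sigma_Lp = sigma_Lp,
                 intensity_cv = intensity_cv,
                 brightness_slope = brightness_slope,
                 include_duplex_brightness = include_duplex_brightness,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

#' Noise-free fluorescence intensities for one state point
#'
#' Surface-density bookkeeping: bridges are confined to the adhesion patch
#' while loops and unbound tethers distribute uniformly over the whole
#' membrane. The single-membrane non-bridge density is
#' `sigma_v = N (1 - x_b) / A` and the patch carries two membranes plus the
#' bridges: `2 sigma_v + 2 N x_b / Ap`. Intensities are
#' `Ibg + b(T) * density` with dye brightness
#' `b(T) = b0 (1 - brightness_slope (T - 20))`. With
#' `include_duplex_brightness`, bound tethers are weighted `95/86`.
#'
#' @param x_b Bridge fraction, in `[0, 1)`.
#' @param N Tethers per vesicle.
#' @param A Total vesicle area, um^2.
#' @param Ap Patch area, um^2 (must be > 0 when `x_b > 0`).
#' @param T_C Temperature, degC.
#' @param noise A [noise_spec()] (only `brightness_slope` and
#'   `include_duplex_brightness` are used here; no noise is added).
#' @param x_l Loop fraction (needed only when bound tethers are re-weighted).
#' @param Ibg Background intensity, a.u.
#' @param b0 Dye brightness scale at 20 degC, a.u. um^2.
#' @return Named list `Iv`, `Ip`, `Ibg` in a.u.
#' @export
intensity_model <- function(x_b, N, A, Ap, T_C, noise = noise_spec(),
                            x_l = 0, Ibg = .IBG_DEFAULT, b0 = .B0_DEFAULT) {
  if (any(x_b < 0 | x_b >= 1)) stop("x_b must be in [0, 1)")
  if (any(A <= 0)) stop("A must be > 0")
  if (any(Ap <= 0 & x_b > 0)) stop("bridges need a patch: Ap = 0 with x_b > 0")
  b <- b0 * (1 - noise$brightness_slope * (T_C - 20))
  if (any(b <= 0)) stop("dye brightness must stay positive over the grid")
  w <- if (noise$include_duplex_brightness) 1 + duplex_brightness_increment() else 1
  sigma_v <- N * ((1 - x_b - x_l) + w * x_l) / A
  sigma_p <- 2 * sigma_v + 2 * N * w * x_b / ifelse(Ap > 0, Ap, NA_real_)
  sigma_p <- ifelse(x_b > 0, sigma_p, 2 * sigma_v)
  list(Iv = Ibg + b * sigma_v, Ip = Ibg + b * sigma_p, Ibg = Ibg)
}

#' Generate a synthetic per-temperature observation series for one pair
#'
#' Runs the forward model on the temperature grid, derives the measurable
#' quantities (`Lp = 2 R sin(theta)`, intensity triplets from
#' [intensity_model()]), and adds Gaussian measurement noise per the
#' [noise_spec()]. The two vesicles are generated identical (symmetric
#' model); the reported `R1`/`R2` differ only by measurement noise. Returns
#' both the noisy observations and the noiseless ground truth; fully
#' reproducible for a fixed seed.
#'
#' @param params A [model_params()] object.
#' @param T_grid Temperatures, degC (default 0..40 at 1 degC, the cooling
#'   ramp resolution of the imaging protocol it emulates).
#' @param noise A [noise_spec()].
#' @return List with `observations` (tibble: `T_C`, `R1_um`, `R2_um`,
#'   `Lp_um`, `Iv`, `Ip`, `Ibg`) and `truth` (the prediction table from
#'   [predict_curve()]).
#' @export
generate_pair_series <- function(params, T_grid = 0:40, noise = noise_spec()) {
  stopifnot(inherits(noise, "noise_spec"))
  truth <- predict_curve(params, T_grid)
  N <- tethers_per_vesicle(params$rho_dna, params$R0)
  Ap_signal <- ifelse(truth$Ap_um2 > 0, truth$Ap_um2, truth$Apeff_um2)
  ints <- intensity_model(truth$x_b, N, truth$A_um2, Ap_signal,
                          truth$T_C, noise, x_l = truth$x_l)
  Lp <- 2 * truth$R_um * sin(truth$theta_deg * pi / 180)

  nT <- nrow(truth)
  obs <- withr::with_seed(noise$seed, {
    jit <- function(x, sd) if (sd > 0) x + stats::rnorm(nT, 0, sd) else x
    ncv <- function(x) {
      if (noise$intensity_cv > 0) x * (1 + stats::rnorm(nT, 0, noise$intensity_cv)) else x
    }
    tibble::tibble(
      T_C = truth$T_C,
      R1_um = jit(truth$R_um, noise$sigma_R),
      R2_um = jit(truth$R_um, noise$sigma_R),
      Lp_um = pmax(0, jit(Lp, noise$sigma_Lp)),
      Iv = ncv(ints$Iv), Ip = ncv(ints$Ip), Ibg = ncv(rep(ints$Ibg, nT)))
  })
  list(observations = obs, truth = truth)
}

#' Generate a synthetic bulk calibration series
#'
#' Linear dilution series of free DNA for the coverage calibration: the
#' intensity, diminished by the dark signal, scales linearly with the number
#' density `n` with slope `C d delta` (see [fit_coverage_calibration()]).
#'
#' @param C Calibration constant, um.
#' @param d Pixel size, um.
#' @param n_points Number of dilution points.
#' @param noise Absolute Gaussian intensity noise, a.u.
#' @param seed Integer seed.
#' @param n_max Largest number density of the series, 1/um^3.
#' @param Id Dark signal, a.u.
#' @param delta Slice thickness, um.
#' @return A [tibble::tibble()] with columns `n` (1/um^3) and `intensity`
#'   (a.u.).
#' @export
generate_calibration_series <- function(C = 2.7, d = 0.076, n_points = 10,
                                        noise = 0, seed = 1L, n_max = 1000,
                                        Id = 5, delta = 0.5) {
  if (C <= 0 || d <= 0 || n_points < 2 || n_max <= 0) {
    stop("C, d, n_max must be > 0 and n_points >= 2")
  }
  n <- seq(0, n_max, length.out = n_points)
  intensity <- Id + C * d * delta * n
  if (noise > 0) {
    intensity <- withr::with_seed(seed, intensity + stats::rnorm(n_points, 0, noise))
  }
  tibble::tibble(n = n, intensity = intensity)
}
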