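# Fitting the neutral temperature T0 (the model's single free parameter)
# and Monte-Carlo propagation of parameter uncertainty to percentile
# envelopes on every predicted observable.

# Fast internal prediction path used by the fit and the Monte-Carlo loops:
# grid scan with parabolic refinement, no tibble construction, no
# zero-stretch reference angle.
.predict_observables <- function(params, T_C, cache) {
  prof <- .energy_profile(cache$grid, params, T_C)
  U <- prof$U_total
  i <- which.min(U)
  theta <- cache$grid$theta[i]
  if (i > 1 && i < length(U)) {
    den <- U[i - 1] - 2 * U[i] + U[i + 1]
    if (den > 0) theta <- theta + (U[i - 1] - U[i + 1]) / (2 * den) * cache$step_rad
  }
  g <- .geometry_grid(theta, params$R0, params$L)
  p <- .energy_profile(g, params, T_C)
  c(theta_deg = theta * 180 / pi, Ap_um2 = g$Ap, D_um = g$D, R_um = g$R,
    A_um2 = g$A, V_um3 = g$V, x_b = p$x_b, x_l = p$x_l)
}

.predict_theta_deg <- function(params, T_vec, cache) {
  vapply(T_vec, function(T_C) .predict_observables(params, T_C, cache)[["theta_deg"]],
         numeric(1))
}

#' Fit the neutral temperature of a vesicle pair
#'
#' The neutral temperature `T0` — at which an isolated vesicle is spherical
#' and tensionless — is the model's only free parameter and is fitted
#' independently for every pair. The default objective is least squares on
#' the contact angle, the primary observable:
#' `sum_T (theta_pred(T; T0) - theta_obs(T))^2`, scanned on a 0.25 degC grid
#' over `[min(T_obs) - 15, min(T_obs) + 10]` degC and then refined locally to
#' 0.05 degC. Deterministic. Observations at duplicate temperatures are
#' averaged.
#'
#' A weighted multi-observable objective is available via `observables`:
#' residuals of each named column are scaled by the root-mean-square of its
#' observed values so the terms are commensurate; this option is off by
#' default.
#'
#' @param obs Data frame of per-temperature observations: either estimator
#'   output with columns `T_C` and `theta_deg` (e.g. from
#'   [estimate_observables()], averaging `theta1_deg`/`theta2_deg` first), or
#'   a raw observation table (columns `T_C`, `R1_um`, `R2_um`, `Lp_um`, `Iv`,
#'   `Ip`, `Ibg`), which is passed through [estimate_observables()]
#'   internally. At least 5 temperatures spanning at least 10 degC.
#' @param params A [model_params()] object; its `T0` entry is ignored.
#' @param observables Character vector of observation columns entering the
#'   objective (default `"theta_deg"` only).
#' @param grid_step Coarse scan step, degC.
#' @param refine_step Refinement step, degC.
#' @return A list of class `t0_fit`: `T0` (degC), `objective` (at the
#'   optimum), `n_obs`, `grid` (scan bounds), `trace` (tibble of scanned
#'   `T0` vs objective).
#' @export
fit_neutral_temperature <- function(obs, params, observables = "theta_deg",
                                    grid_step = 0.25, refine_step = 0.05) {
  validate_model_params(params)
  if (!("theta_deg" %in% names(obs)) && all(c("R1_um", "Lp_um") %in% names(obs))) {
    est <- estimate_observables(obs)
    est$theta_deg <- (est$theta1_deg + est$theta2_deg) / 2
    keep <- intersect(c("T_C", "theta_deg", "Ap_um2", "x_b"), names(est))
    obs <- est[keep]
  }
  if (!all(c("T_C", observables) %in% names(obs))) {
    stop("obs must contain columns T_C and ", paste(observables, collapse = ", "))
  }
  obs <- stats::aggregate(obs[observables], by = list(T_C = obs$T_C), FUN = mean)
  if (nrow(obs) < 5) stop("need at least 5 distinct observation temperatures")
  if (diff(range(obs$T_C)) < 10) stop("observations must span at least 10 degC")
  if ("theta_deg" %in% observables && all(abs(obs$theta_deg) < 1)) {
    stop("degenerate observations: all contact angles are ~0")
  }

  scale <- vapply(observables, function(v) {
    s <- sqrt(mean(obs[[v]]^2))
    if (s > 0) s else 1
  }, numeric(1))
  cache <- .theta_cache(params$R0, params$L)
  multi <- length(observables) > 1
  obj <- function(T0) {
    p <- params
    p$T0 <- T0
    pred <- vapply(obs$T_C, function(T_C) .predict_observables(p, T_C, cache),
                   numeric(8))
    sum(vapply(seq_along(observables), function(k) {
      res <- pred[observables[k], ] - obs[[observables[k]]]
      if (multi) res <- res / scale[k]
      sum(res^2)
    }, numeric(1)))
  }

  lo <- min(obs$T_C) - 15
  hi <- min(obs$T_C) + 10
  T0_grid <- seq(lo, hi, by = grid_step)
  vals <- vapply(T0_grid, obj, numeric(1))
  i <- which.min(vals)
  fine <- seq(max(lo, T0_grid[i] - grid_step), min(hi, T0_grid[i] + grid_step),
              by = refine_step)
  fvals <- vapply(fine, obj, numeric(1))
  j <- which.min(fvals)
  structure(list(T0 = fine[j], objective = fvals[j], n_obs = nrow(obs),
                 grid = c(lo, hi),
                 trace = tibble::tibble(T0 = T0_grid, objective = vals)),
            class = "t0_fit")
}

#' @export
print.t0_fit <- function(x, ...) {
  cat(sprintf("neutral-temperature fit: T0 = %.2f degC (objective %.4g, %d observations, scan [%.4g, %.4g] degC)\n",
              x$T0, x$objective, x$n_obs, x$grid[1], x$grid[2]))
  invisible(x)
}

#' Draw parameter sets for uncertainty propagation
#'
#' Independent normal draws for `alpha`, `Ka` and `rho_dna` about their
#' central values; draws that violate positivity are rejected and redrawn
#' (the relative uncertainty on `alpha` is large, so plain normals would
#' produce unphysical values). `dH0` and `dS0` are perfectly coupled: a
#' single shared standard-normal deviate scales both, which prevents
#' unphysical fluctuations of the duplex melting temperature `dH0/dS0`.
#' `L`, `rho0`, `T0` and `R0` are not propagated.
#'
#' @param params A [model_params()] object.
#' @param n Number of draws (>= 1).
#' @param seed Integer seed.
#' @param band Which uncertainties to propagate: `"alpha"` (alpha only),
#'   `"alpha_Ka"`, or `"full"` (alpha, Ka, dH0+dS0, rho_dna). The draw order
#'   is fixed per parameter, so the alpha column is identical across bands at
#'   equal seed.
#' @return A [tibble::tibble()] with `n` rows and columns `alpha`, `Ka`,
#'   `rho_dna`, `dH0`, `dS0`.
#' @export
sample_parameters <- function(params, n, seed = 1L,
                              band = c("full", "alpha", "alpha_Ka")) {
  band <- match.arg(band)
  if (n < 1) stop("n must be >= 1")
  validate_model_params(params)
  use <- switch(band,
                alpha = c(alpha = TRUE, Ka = FALSE, hs = FALSE, rho = FALSE),
                alpha_Ka = c(alpha = TRUE, Ka = TRUE, hs = FALSE, rho = FALSE),
                full = c(alpha = TRUE, Ka = TRUE, hs = TRUE, rho = TRUE))
  withr::with_seed(as.integer(seed), {
    draw_pos <- function(mu, sd, on) {
      x <- mu + (if (on) sd else 0) * stats::rnorm(n)
      while (any(x <= 0)) {
        bad <- which(x <= 0)
        x[bad] <- mu + sd * stats::rnorm(length(bad))
      }
      x
    }
    alpha <- draw_pos(params$alpha, params$alpha_sd, use[["alpha"]])
    Ka <- draw_pos(params$Ka, params$Ka_sd, use[["Ka"]])
    rho <- draw_pos(params$rho_dna, params$rho_dna_sd, use[["rho"]])
    z <- if (use[["hs"]]) stats::rnorm(n) else rep(0, n)
    tibble::tibble(alpha = alpha, Ka = Ka, rho_dna = rho,
                   dH0 = params$dH0 + z * params$dH0_sd,
                   dS0 = params$dS0 + z * params$dS0_sd)
  })
}

#' Monte-Carlo uncertainty envelopes for all predicted observables
#'
#' Propagates the parameter uncertainties through the full equilibrium
#' prediction: for each draw from [sample_parameters()] and each temperature
#' it minimizes the free energy and records `theta`, `Ap`, `D`, `R`, `A`,
#' `V`, `x_b`, `x_l`; the per-temperature summary is the median and the 16th
#' and 84th percentiles (68% of draws). Nested propagation sets mirror the
#' three uncertainty bands of the analysis: `alpha` only, `alpha + Ka`, and
#' the full set. Identical seeds give bitwise-identical envelopes; draws use
#' common random numbers across bands, so the bands nest.
#'
#' @param params A [model_params()] object.
#' @param T_grid Temperatures, degC.
#' @param n Draws per band, in `[1e3, 1e5]` (default 1e4).
#' @param seed Integer seed.
#' @param bands Subset of `c("alpha", "alpha_Ka", "full")`.
#' @return A [tibble::tibble()] with columns `band`, `T_C`, `observable`,
#'   `median`, `p16`, `p84`; attributes `n_samples`, `seed` and `failures`
#'   (count of draws where the solver failed; failed draws are dropped from
#'   the percentiles but reported, never silently lost).
#' @export
propagate_uncertainty <- function(params, T_grid, n = 1e4, seed = 1L,
                                  bands = c("alpha", "alpha_Ka", "full")) {
  if (n < 1e3 || n > 1e5) stop("n must be in [1e3, 1e5]")
  bands <- match.arg(bands, several.ok = TRUE)
  validate_model_params(params)
  cache <- .theta_cache(params$R0, params$L)
  obs_names <- c("theta_deg", "Ap_um2", "D_um", "R_um", "A_um2", "V_um3",
                 "x_b", "x_l")
  failures <- 0L
  out <- list()
  for (band in bands) {
    draws <- sample_parameters(params, n, seed = seed, band = band)
    for (T_C in T_grid) {
      vals <- matrix(NA_real_, n, length(obs_names),
                     dimnames = list(NULL, obs_names))
      for (k in seq_len(n)) {
        p <- params
        p$alpha <- draws$alpha[k]; p$Ka <- draws$Ka[k]
        p$rho_dna <- draws$rho_dna[k]
        p$dH0 <- draws$dH0[k]; p$dS0 <- draws$dS0[k]
        v <- tryCatch(.predict_observables(p, T_C, cache),
                      error = function(e) NULL)
        if (is.null(v)) failures <- failures + 1L else vals[k, ] <- v
      }
      qs <- apply(vals, 2, stats::quantile, probs = c(0.16, 0.5, 0.84),
                  na.rm = TRUE, names = FALSE)
      out[[length(out) + 1L]] <- tibble::tibble(
        band = band, T_C = T_C, observable = obs_names,
        median = unname(qs[2, ]), p16 = unname(qs[1, ]),
        p84 = unname(qs[3, ]))
    }
  }
  env <- do.call(rbind, out)
  attr(env, "n_samples") <- n
  attr(env, "seed") <- as.integer(seed)
  attr(env, "failures") <- failures
  env
}
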