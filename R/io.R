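# Readers/writers for the pipeline's tables and configuration, plus the
# run_* drivers that tie the stages into one reproducible pipeline. All
# tables are plain CSV with fixed headers; scalar results are JSON; the
# configuration is flat YAML. Angles are serialized in degrees (figure
# convention), radians internally.

.PRED_COLS <- c("T_C", "theta_deg", "theta0_deg", "R_um", "A_um2", "Ap_um2",
                "Apeff_um2", "D_um", "V_um3", "x_b", "x_l", "tension_mN_m",
                "U_total_kBT")
.OBS_COLS <- c("T_C", "R1_um", "R2_um", "Lp_um", "Iv", "Ip", "Ibg")
.ENV_COLS <- c("T_C", "observable", "median", "p16", "p84", "band")

#' Write / read the predictions table
#'
#' Fixed-schema CSV with columns `T_C, theta_deg, theta0_deg, R_um, A_um2,
#' Ap_um2, Apeff_um2, D_um, V_um3, x_b, x_l, tension_mN_m, U_total_kBT`.
#'
#' @param pred Prediction table from [predict_curve()].
#' @param path CSV path.
#' @return `path` invisibly; `read_predictions()` returns a tibble.
#' @export
write_predictions <- function(pred, path) {
  miss <- setdiff(.PRED_COLS, names(pred))
  if (length(miss) > 0) stop("prediction table missing columns: ",
                             paste(miss, collapse = ", "))
  utils::write.csv(as.data.frame(pred)[.PRED_COLS], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  df <- utils::read.csv(path)
  miss <- setdiff(.PRED_COLS, names(df))
  if (length(miss) > 0) stop("prediction CSV missing columns: ",
                             paste(miss, collapse = ", "))
  tibble::as_tibble(df)
}

#' Write / read the observations table
#'
#' Fixed-schema CSV with columns `T_C, R1_um, R2_um, Lp_um, Iv, Ip, Ibg`
#' (optionally `Id`).
#'
#' @param obs Observation table (e.g. from [generate_pair_series()]).
#' @param path CSV path.
#' @return `path` invisibly; `read_observations()` returns a tibble.
#' @export
write_observations <- function(obs, path) {
  miss <- setdiff(.OBS_COLS, names(obs))
  if (length(miss) > 0) stop("observation table missing columns: ",
                             paste(miss, collapse = ", "))
  keep <- c(.OBS_COLS, intersect("Id", names(obs)))
  utils::write.csv(as.data.frame(obs)[keep], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  df <- utils::read.csv(path)
  miss <- setdiff(.OBS_COLS, names(df))
  if (length(miss) > 0) {
    stop("observation CSV missing columns: ", paste(miss, collapse = ", "),
         " (rows present: ", nrow(df), ")")
  }
  if (nrow(df) == 0) stop("observation CSV is empty")
  bad <- which(!stats::complete.cases(df[.OBS_COLS]))
  if (length(bad) > 0) {
    stop("malformed observation rows (missing values) at row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  tibble::as_tibble(df)
}

#' Write / read an uncertainty-envelope table
#'
#' Fixed-schema CSV with columns `T_C, observable, median, p16, p84, band`.
#'
#' @param env Envelope table from [propagate_uncertainty()].
#' @param path CSV path.
#' @return `path` invisibly; `read_envelopes()` returns a tibble.
#' @export
write_envelopes <- function(env, path) {
  miss <- setdiff(.ENV_COLS, names(env))
  if (length(miss) > 0) stop("envelope table missing columns: ",
                             paste(miss, collapse = ", "))
  utils::write.csv(as.data.frame(env)[.ENV_COLS], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_envelopes
#' @export
read_envelopes <- function(path) {
  df <- utils::read.csv(path)
  miss <- setdiff(.ENV_COLS, names(df))
  if (length(miss) > 0) stop("envelope CSV missing columns: ",
                             paste(miss, collapse = ", "))
  tibble::as_tibble(df)
}

#' Read a pipeline run configuration
#'
#' YAML with blocks `params` (keys of [model_params()]), `grid`
#' (`start`, `stop`, `step` in degC), `noise` (keys of [noise_spec()]),
#' `inference` (`n_samples`, `seed`, `bands`) and `output` (directory). All
#' blocks except `params` are optional and take the documented defaults.
#'
#' @param path YAML path.
#' @return A validated `run_config` list with elements `params` (a
#'   [model_params()]), `grid` (numeric temperature vector), `noise` (a
#'   [noise_spec()]), `inference`, `output`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  build_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg A nested list with the same structure as the YAML file.
#' @export
build_run_config <- function(cfg) {
  params <- do.call(model_params, as.list(cfg$params))
  grid <- cfg$grid
  if (is.null(grid)) grid <- list(start = 0, stop = 40, step = 1)
  for (k in c("start", "stop", "step")) {
    if (is.null(grid[[k]])) stop("config grid block is missing key: ", k)
  }
  if (grid$step <= 0) stop("config grid step must be > 0")
  T_grid <- seq(grid$start, grid$stop, by = grid$step)
  noise <- do.call(noise_spec, as.list(cfg$noise))
  inf <- cfg$inference
  if (is.null(inf)) inf <- list()
  if (is.null(inf$n_samples)) inf$n_samples <- 1e4
  if (inf$n_samples < 1e3 || inf$n_samples > 1e5) {
    stop("config inference n_samples must be in [1e3, 1e5]")
  }
  if (is.null(inf$seed)) inf$seed <- 1L
  if (is.null(inf$bands)) inf$bands <- c("alpha", "alpha_Ka", "full")
  out_dir <- if (is.null(cfg$output)) "." else cfg$output
  structure(list(params = params, grid = T_grid, noise = noise,
                 inference = inf, output = out_dir),
            class = "run_config")
}

#' Pipeline drivers
#'
#' Thin orchestration over the package stages, each writing its fixed-schema
#' outputs into the configured directory and returning the result invisibly:
#' * `run_predict()`: predictions CSV (`predictions.csv`).
#' * `run_simulate()`: observations + ground truth CSVs and a sidecar JSON
#'   echoing the seed and noise spec (`observations.csv`, `truth.csv`,
#'   `simulation_meta.json`).
#' * `run_fit()`: neutral-temperature fit JSON (`fit.json`) from an
#'   observations CSV.
#' * `run_propagate()`: envelope CSV (`envelopes.csv`).
#' * `run_estimate()`: estimator output CSV (`estimates.csv`) from an
#'   observations CSV.
#'
#' @param config A `run_config` from [read_run_config()]/[build_run_config()],
#'   or a path to the YAML file.
#' @param out_dir Output directory (overrides the config's `output`).
#' @param seed Optional seed overriding the config's.
#' @param obs_path Path to an observations CSV (for `run_fit` and
#'   `run_estimate`).
#' @return The stage's main result, invisibly.
#' @name pipeline
NULL

.as_config <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  config
}

.outfile <- function(cfg, out_dir, name) {
  dir <- if (is.null(out_dir)) cfg$output else out_dir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  file.path(dir, name)
}

#' @rdname pipeline
#' @export
run_predict <- function(config, out_dir = NULL) {
  cfg <- .as_config(config)
  pred <- predict_curve(cfg$params, cfg$grid)
  write_predictions(pred, .outfile(cfg, out_dir, "predictions.csv"))
  invisible(pred)
}

#' @rdname pipeline
#' @export
run_simulate <- function(config, out_dir = NULL, seed = NULL) {
  cfg <- .as_config(config)
  noise <- cfg$noise
  if (!is.null(seed)) noise$seed <- as.integer(seed)
  sim <- generate_pair_series(cfg$params, cfg$grid, noise)
  write_observations(sim$observations, .outfile(cfg, out_dir, "observations.csv"))
  write_predictions(sim$truth, .outfile(cfg, out_dir, "truth.csv"))
  jsonlite::write_json(list(seed = noise$seed, noise = unclass(noise)),
                       .outfile(cfg, out_dir, "simulation_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(sim)
}

#' @rdname pipeline
#' @export
run_fit <- function(obs_path, config, out_dir = NULL) {
  cfg <- .as_config(config)
  obs <- read_observations(obs_path)
  fit <- fit_neutral_temperature(obs, cfg$params)
  jsonlite::write_json(list(T0_C = fit$T0, objective = fit$objective,
                            n_obs = fit$n_obs, grid = fit$grid,
                            seed = cfg$inference$seed),
                       .outfile(cfg, out_dir, "fit.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(fit)
}

#' @rdname pipeline
#' @export
run_propagate <- function(config, out_dir = NULL, seed = NULL) {
  cfg <- .as_config(config)
  s <- if (is.null(seed)) cfg$inference$seed else seed
  env <- propagate_uncertainty(cfg$params, cfg$grid,
                               n = cfg$inference$n_samples, seed = s,
                               bands = cfg$inference$bands)
  write_envelopes(env, .outfile(cfg, out_dir, "envelopes.csv"))
  invisible(env)
}

#' @rdname pipeline
#' @export
run_estimate <- function(obs_path, config, out_dir = NULL) {
  cfg <- .as_config(config)
  obs <- read_observations(obs_path)
  est <- estimate_observables(obs)
  utils::write.csv(as.data.frame(est),
                   .outfile(cfg, out_dir, "estimates.csv"), row.names = FALSE)
  invisible(est)
}
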