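#' dnaguv: thermomechanics of DNA-mediated adhesion in GUV pairs
#'
#' Forward model, inference and estimators for pairs of giant unilamellar
#' vesicles (GUVs) adhering through mobile DNA tethers. The central objects
#' are [model_params()] (physical parameters with uncertainties),
#' [geometry_at_angle()] (truncated-sphere pair geometry), the bridge/loop
#' mean-field solver [solve_bond_fractions()], the free-energy minimizer
#' [equilibrium_state()], the neutral-temperature fit
#' [fit_neutral_temperature()], Monte-Carlo error propagation
#' [propagate_uncertainty()], the fluorescence estimators
#' ([bridge_fraction_from_intensities()] and friends) and the synthetic
#' observation generator [generate_pair_series()].
#'
#' @keywords internal
"_PACKAGE"

# Physical constants used throughout. Energies cross module boundaries in
# units of kBT at the *current* temperature; temperatures in degrees Celsius
# at interfaces, kelvin internally; lengths in nm internally, areas reported
# in um^2 at interfaces.
.kB <- 1.380649e-23          # J / K
.Rgas <- 1.987e-3            # kcal / mol / K
.zeroC <- 273.15             # K at 0 degC
.NM2_PER_UM2 <- 1e6

#' Model parameters for a DNA-GUV pair
#'
#' Container for all physical input parameters of the model, with standard
#' deviations for those that carry experimental uncertainty. Defaults are the
#' central literature/measurement values for DOPC GUVs coated with
#' double-stranded DNA tethers bearing complementary sticky ends.
#'
#' @param alpha Area thermal expansion coefficient of the bilayer, 1/K.
#' @param alpha_sd Standard deviation of `alpha`, 1/K.
#' @param Ka Membrane stretching modulus, mN/m.
#' @param Ka_sd Standard deviation of `Ka`, mN/m.
#' @param rho_dna DNA tether surface density (both sticky-end species
#'   combined), 1/um^2.
#' @param rho_dna_sd Standard deviation of `rho_dna`, 1/um^2.
#' @param L Tether (duplex spacer) length, nm. The inter-membrane distance in
#'   the adhesion patch is fixed at `h = L`: for a fixed geometry the
#'   pair potential has a strong minimum at that separation, so `h` is not a
#'   free variable of the model.
#' @param dH0 Hybridization enthalpy of the sticky ends, kcal/mol (negative
#'   for a binding pair).
#' @param dH0_sd Standard deviation of `dH0`, kcal/mol.
#' @param dS0 Hybridization entropy of the sticky ends, cal/mol/K (negative).
#' @param dS0_sd Standard deviation of `dS0`, cal/mol/K.
#' @param rho0 Reference concentration defining the standard state of the
#'   duplex thermodynamics, 1/nm^3 (0.6 corresponds to 1 M).
#' @param T0 Neutral temperature, degC: the temperature at which an isolated
#'   vesicle is exactly spherical and tensionless (reduced volume 1). This is
#'   the model's single fitted parameter.
#' @param R0 Reference vesicle radius at the neutral temperature, um.
#'
#' @return An object of class `model_params`: a named list of the above
#'   fields, validated.
#' @examples
#' p <- model_params()
#' p$Ka
#' @export
model_params <- function(alpha = 1.3e-3, alpha_sd = 0.7e-3,
                         Ka = 240, Ka_sd = 90,
                         rho_dna = 390, rho_dna_sd = 90,
                         L = 14.5,
                         dH0 = -68.5, dH0_sd = 3,
                         dS0 = -193.5, dS0_sd = 8,
                         rho0 = 0.6,
                         T0 = -3,
                         R0 = 10) {
  p <- list(alpha = alpha, alpha_sd = alpha_sd,
            Ka = Ka, Ka_sd = Ka_sd,
            rho_dna = rho_dna, rho_dna_sd = rho_dna_sd,
            L = L,
            dH0 = dH0, dH0_sd = dH0_sd,
            dS0 = dS0, dS0_sd = dS0_sd,
            rho0 = rho0, T0 = T0, R0 = R0)
  validate_model_params(p)
  structure(p, class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("DNA-GUV model parameters\n")
  cat(sprintf("  alpha   : %.3g +/- %.3g 1/K\n", x$alpha, x$alpha_sd))
  cat(sprintf("  Ka      : %.4g +/- %.3g mN/m\n", x$Ka, x$Ka_sd))
  cat(sprintf("  rho_dna : %.4g +/- %.3g 1/um^2\n", x$rho_dna, x$rho_dna_sd))
  cat(sprintf("  L       : %.4g nm\n", x$L))
  cat(sprintf("  dH0     : %.4g +/- %.3g kcal/mol\n", x$dH0, x$dH0_sd))
  cat(sprintf("  dS0     : %.4g +/- %.3g cal/mol/K\n", x$dS0, x$dS0_sd))
  cat(sprintf("  rho0    : %.3g 1/nm^3\n", x$rho0))
  cat(sprintf("  T0      : %.4g degC, R0 : %.4g um\n", x$T0, x$R0))
  invisible(x)
}

validate_model_params <- function(p) {
  need <- c("alpha", "alpha_sd", "Ka", "Ka_sd", "rho_dna", "rho_dna_sd", "L",
            "dH0", "dH0_sd", "dS0", "dS0_sd", "rho0", "T0", "R0")
  miss <- setdiff(need, names(p))
  if (length(miss) > 0) {
    stop("model_params is missing fields: ", paste(miss, collapse = ", "))
  }
  num <- vapply(p[need], function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                logical(1))
  if (!all(num)) {
    stop("model_params fields must be finite numeric scalars: ",
         paste(need[!num], collapse = ", "))
  }
  pos <- c("alpha", "Ka", "rho0", "L", "R0")
  bad <- pos[vapply(pos, function(f) p[[f]] <= 0, logical(1))]
  if (length(bad) > 0) {
    stop("model_params fields must be strictly positive: ",
         paste(bad, collapse = ", "))
  }
  if (p$rho_dna < 0) stop("rho_dna must be >= 0")
  if (p$dH0 >= 0 || p$dS0 >= 0) {
    stop("dH0 and dS0 must be negative for a binding sticky end")
  }
  sds <- c("alpha_sd", "Ka_sd", "rho_dna_sd", "dH0_sd", "dS0_sd")
  bad <- sds[vapply(sds, function(f) p[[f]] < 0, logical(1))]
  if (length(bad) > 0) {
    stop("standard deviations must be >= 0: ", paste(bad, collapse = ", "))
  }
  invisible(p)
}

#' Thermal energy kB*T
#'
#' @param T_C Temperature in degrees Celsius (vectorized).
#' @return Thermal energy in joules.
#' @examples
#' thermal_energy(26.85)  # ~4.14e-21 J at 300 K
#' @export
thermal_energy <- function(T_C) {
  if (!is.numeric(T_C) || any(!is.finite(T_C))) {
    stop("T_C must be finite numeric")
  }
  if (any(T_C <= -.zeroC)) {
    stop("non-physical temperature: T must be above absolute zero (-273.15 degC)")
  }
  .kB * (T_C + .zeroC)
}

#' Standard-state duplex hybridization free energy
#'
#' Free energy of hybridization of the untethered sticky ends,
#' `dG0 = dH0 - T*dS0`, converted to units of kBT at the given temperature.
#' Negative below the duplex melting temperature `Tm = dH0/dS0`.
#'
#' @param params A [model_params()] object.
#' @param T_C Temperature, degC (vectorized).
#' @return Free energy in kBT units.
#' @examples
#' duplex_free_energy0(model_params(), 60)  # about -6.1 kBT
#' @export
duplex_free_energy0 <- function(params, T_C) {
  T_K <- T_C + .zeroC
  if (any(T_K <= 0)) stop("non-physical temperature")
  dS0_kcal <- params$dS0 / 1000
  (params$dH0 - T_K * dS0_kcal) / (.Rgas * T_K)
}

#' Stretching modulus in kBT per nm^2
#'
#' Converts a membrane stretching modulus from mN/m to kBT/nm^2 at the given
#' temperature (1 mN/m = 1e-21 J/nm^2).
#'
#' @param Ka Stretching modulus, mN/m; must be > 0.
#' @param T_C Temperature, degC.
#' @return Modulus in kBT/nm^2.
#' @examples
#' stretch_modulus_kbt_nm2(240, 26.85)  # ~58 kBT/nm^2
#' @export
stretch_modulus_kbt_nm2 <- function(Ka, T_C) {
  if (!is.numeric(Ka) || any(Ka <= 0)) stop("Ka must be > 0")
  Ka * 1e-21 / thermal_energy(T_C)
}

#' Contour length of a double-stranded DNA spacer
#'
#' @param n_bp Number of base pairs.
#' @param rise_per_bp Helical rise per base pair, nm (B-DNA: 0.338 nm).
#' @return Contour length in nm. The default 43-bp spacer gives 14.5 nm.
#' @export
spacer_contour_length <- function(n_bp = 43, rise_per_bp = 0.338) {
  if (any(n_bp < 0) || any(rise_per_bp <= 0)) stop("invalid spacer geometry")
  n_bp * rise_per_bp
}

#' Read model parameters from a flat key-value configuration file
#'
#' The file is YAML with flat scalar keys `alpha, alpha_sd, Ka, Ka_sd,
#' rho_dna, rho_dna_sd, L, dH0, dH0_sd, dS0, dS0_sd, rho0, T0, R0`. Missing
#' keys fall back to the defaults of [model_params()].
#'
#' @param path Path to the YAML file.
#' @return A [model_params()] object.
#' @seealso [write_model_params()]
#' @export
read_model_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(model_params))
  extra <- setdiff(names(vals), known)
  if (length(extra) > 0) {
    stop("unknown parameter key(s) in ", path, ": ", paste(extra, collapse = ", "))
  }
  do.call(model_params, vals[intersect(names(vals), known)])
}

#' Write model parameters to a flat key-value configuration file
#'
#' @param params A [model_params()] object.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_model_params <- function(params, path) {
  validate_model_params(params)
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}
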