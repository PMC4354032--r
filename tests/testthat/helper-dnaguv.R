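# Shared fixtures: central parameter set used across the suite (the model's
# default literature/measurement values with T0 = -3 degC, R0 = 10 um).
central_params <- function(...) model_params(...)

# A pair_geometry built directly from raw fields, for formula-level tests.
raw_geometry <- function(theta = 0, R = 10, A = 4 * pi * 100, Ap = 0,
                         Ap_eff = Ap, D = 2 * R, V = 4 / 3 * pi * 1000,
                         nu = 1) {
  structure(list(theta = theta, R = R, A = A, Ap = Ap, Ap_eff = Ap_eff,
                 D = D, V = V, nu = nu), class = "pair_geometry")
}
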