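# Shared fixtures: a synthetic reference parameter set (the model carries
# no published values) and small constructors used across test files.

ref_params <- function(...) {
  p <- default_config()$model$rates
  over <- list(...)
  p[names(over)] <- over
  as_rate_constants(p)
}

ref_geometry <- function() krogh_geometry(L = 2, R_l = 0.02, R_m = 0.01,
                                          R_e = 0.05)

ref_flow <- function(vmax = 2, km = 0.02, Q = 1, c_in = 0.2) {
  flow_conditions(Q = Q, c_in = c_in, uptake_vmax = vmax, uptake_km = km)
}

# independent term-by-term re-evaluation of the mass-action rates, kept
# deliberately separate from the package implementation
oracle_rhs <- function(y, p) {
  c(P = -p$k_sul * y[["S"]] * y[["P"]] - p$k_gluc * y[["P"]] -
      p$k_450 * y[["P"]] + p$k_rev * y[["N"]],
    S = p$beta_S - p$delta_S * y[["S"]] - p$k_sul * y[["S"]] * y[["P"]],
    N = p$k_450 * y[["P"]] - p$k_rev * y[["N"]] -
      p$k_GSH * y[["G"]] * y[["N"]] - p$k_PSH * y[["N"]],
    G = p$beta_G - p$delta_G * y[["G"]] - p$k_GSH * y[["G"]] * y[["N"]],
    T = p$k_PSH * y[["N"]] - p$delta_T * y[["T"]],
    E_sul = p$k_sul * y[["S"]] * y[["P"]],
    E_gluc = p$k_gluc * y[["P"]],
    C_GSH = p$k_GSH * y[["G"]] * y[["N"]])
}
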