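# Example zonatox run configuration (units: mM, hours, cm).
# Rate constants are the synthetic reference set; the model is published
# unparameterised.
model:
  rates:
    k_sul: 0.3      # mM^-1 h^-1, sulphation (consumes cofactor S)
    k_gluc: 0.5     # h^-1, glucuronidation (pseudo-first-order)
    k_450: 0.2      # h^-1, P450 bioactivation to NAPQI (zonated)
    k_rev: 0.05     # h^-1, NAPQI breakdown back to APAP
    k_GSH: 50       # mM^-1 h^-1, NAPQI-glutathione conjugation
    k_PSH: 0.4      # h^-1, NAPQI-protein adduction
    beta_S: 0.2     # mM h^-1, cofactor production
    delta_S: 0.4    # h^-1, cofactor decay
    beta_G: 2       # mM h^-1, GSH production (zonated)
    delta_G: 0.5    # h^-1, GSH decay
  P0: 20
  t_end: 24
zonation:
  geometry: {L: 2, R_l: 0.02, R_m: 0.01, R_e: 0.05}
  flow: {Q: 1, c_in: 0.2}
  uptake: {vmax: 2, km: 0.02}
  mapping: {k450_min: 0.1, k450_max: 0.5, betaG_min: 0.5, betaG_max: 2, P0: 20}
  n_zones: 24
  threshold: 1
doseresponse:
  doses: {from: 0.5, to: 50, n: 12, log: true}
  metric: terminal_T
  survival: {ec50: 2, hill_n: 2}
seed: 0
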