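# zonatox

Kinetic simulation of paracetamol (APAP) hepatotoxicity in a zonated
hepatic sinusoid, for systems toxicologists and bioreactor modellers who
need a mechanistic, testable substrate for drug-induced liver injury
questions: when does glutathione run out, where along the sinusoid does
damage concentrate, and how do damage metrics translate into
dose–response curves?

## The model

A single well-mixed hepatocyte carries five species — APAP *P*, a
depletable sulphation cofactor *S*, the reactive metabolite NAPQI *N*,
glutathione *G*, and the cumulative drug–protein adduct *T* — governed by
mass-action kinetics with ten rate constants:

```
dP/dt = −k_sul·S·P − k_gluc·P − k_450·P + k_rev·N
dS/dt = β_S − δ_S·S − k_sul·S·P
dN/dt = k_450·P − k_rev·N − k_GSH·G·N − k_PSH·N
dG/dt = β_G − δ_G·G − k_GSH·G·N
dT/dt = k_PSH·N
```

Three cumulative product pools (`E_sul`, `E_gluc`, `C_GSH`) close the mass
balance, so `P + N + T + E_sul + E_gluc + C_GSH = P0` holds exactly — a
built-in solver-accuracy and wiring check (`conservation_residual()`).
The toxic switch lives at the NAPQI node: while `k_GSH·G ≫ k_PSH` the
conjugation branch detoxifies nearly everything; once glutathione is
depleted the flux flips to protein adduction and *T* — the damage readout
— accumulates.

Around the cell model:

* **Zonation** (`axial_oxygen_profile`, `sinusoid_zones`,
  `simulate_sinusoid`, `classify_injury`): a reduced plug-flow oxygen
  balance along a Krogh-cylinder fibre, `Q dc/dz = −A_cell·Vmax·c/(Km+c)`,
  generates a portal→central oxygen gradient; the position-dependent
  parameters `k*_450` (rising centrally, as CYP2E1/3A do) and `β*_G`
  (falling centrally) are mapped from oxygen, each zone runs the cell
  model independently, and the terminal-adduct profile is classified as
  centrilobular / periportal / midzonal / panlobular / none.
* **Dose–response** (`dose_response_scan`, `fit_hill`): damage metrics
  (terminal adduct, NAPQI AUC, NAPQI peak) mapped to survival through a
  Hill transform, with bounded multi-start four-parameter-logistic
  fitting and EC50 recovery.
* **Estimation** (`fit_rate_constants`): Levenberg–Marquardt on
  log-parameters with per-species residual scaling and an
  identifiability screen.
* **I/O and CLI** (`load_config`, `write_results`, `exec/zonatox`): YAML
  configs with strict validation, schema-stable CSV + JSON-sidecar
  outputs, and `simulate | zonate | dose-response` subcommands.

Units: concentrations in mM, time in hours. The model is published
unparameterised; all default values are synthetic (see the methods
vignette in `vignettes/zonatox-methods.Rmd`).

## Worked example

```r
library(zonatox)

p <- rate_constants(k_sul = 0.3, k_gluc = 0.5, k_450 = 0.2, k_rev = 0.05,
                    k_GSH = 50, k_PSH = 0.4, beta_S = 0.2, delta_S = 0.4,
                    beta_G = 2, delta_G = 0.5)
p
#> APAP metabolism rate constants (mM, h):
#>   k_sul  k_gluc   k_450   k_rev   k_GSH   k_PSH  beta_S delta_S  beta_G delta_G
#>    0.30    0.50    0.20    0.05   50.00    0.40    0.20    0.40    2.00    0.50
#> drug-free baselines: S0 = 0.5 mM, G0 = 4 mM

traj <- simulate_cell(p, P0 = 20, t_end = 24)
traj
#> APAP cell trajectory: 201 time points over [0, 24] h, P0 = 20 mM
#> terminal: P = 5.973e-08, N = 5.985e-11, G = 4, T = 0.01953 mM
#> solver: lsoda (rtol 1e-10, atol 1e-12)
conservation_residual(traj)$max_relative
#> [1] 3.197442e-15
```

At this dose, a single average hepatocyte detoxifies almost everything:
the drug is cleared within the day, glutathione returns to its 4 mM
baseline, and only ~0.02 mM of adduct forms. Zonation changes the
picture — downstream zones see more bioactivation and less glutathione
production:

```r
zp <- sinusoid_zones(
  krogh_geometry(L = 2, R_l = 0.02, R_m = 0.01, R_e = 0.05),
  flow_conditions(Q = 1, c_in = 0.2, uptake_vmax = 2, uptake_km = 0.02),
  zonation_mapping(P0 = 20), n_zones = 24)
inj <- simulate_sinusoid(zp, p, t_end = 24, keep_trajectories = FALSE)
inj
#> Sinusoid injury map: 24 zones, terminal T in [0.009157, 5.209] mM at t = 24 h
cls <- classify_injury(inj, threshold = 1)
cat(cls$pattern, "|", sum(cls$injured), "of 24 zones injured\n")
#> centrilobular | 11 of 24 zones injured
```

Terminal adduct burden spans nearly three orders of magnitude from the
portal to the central end of the same sinusoid, and the injured zones sit
in the downstream half: the characteristic centrilobular pattern of APAP,
produced here purely by the oxygen-mapped parameter gradients.

The same run is available from the shell:

```sh
Rscript exec/zonatox zonate --config inst/extdata/example_config.yaml --out out/
```

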