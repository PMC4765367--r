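---
title: "Modelling zonated paracetamol hepatotoxicity with zonatox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling zonated paracetamol hepatotoxicity with zonatox}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zonatox)
```

## The problem

An overdose of paracetamol (APAP) injures the liver through a well-understood
sequence: most of the drug is detoxified by the phase II conjugation pathways
(sulphation and glucuronidation), but a fraction is oxidised by cytochrome
P450 enzymes — chiefly CYP2E1/3A — to the reactive quinone imine NAPQI.
NAPQI is normally mopped up by glutathione (GSH); once the GSH pool is
exhausted, NAPQI binds covalently to protein thiols, and the accumulated
protein adducts track the ensuing necrosis. Because the P450 isoenzymes are
enriched around the central vein while oxygen and GSH fall along the
sinusoid, APAP necrosis is characteristically centrilobular, whereas
toxicants with the opposite enzyme distribution (methapyrilene, allyl
alcohol) injure the periportal zone.

`zonatox` implements this mechanism as a small mass-action ODE model of one
well-mixed hepatocyte, embeds it in a zonated sinusoid by making the two
position-sensitive parameters functions of a modelled axial oxygen
gradient, and adds a dose--response layer that maps damage to survival
through a four-parameter logistic (Hill) transform.

## The cell model

The state carries the five dynamic species — APAP $P$, sulphation cofactor
$S$, NAPQI $N$, glutathione $G$ and the cumulative adduct pool $T$ — plus
three cumulative product pools ($E_{\mathrm{sul}}$, $E_{\mathrm{gluc}}$,
$C_{\mathrm{GSH}}$). The product pools are bookkeeping extensions: the
underlying pathway discards its excretory and conjugation products, but
keeping them as states turns the pathway topology into a testable identity
(see *Conservation* below). The mass-action rates are

$$
\begin{aligned}
\dot P &= -k_{\mathrm{sul}}\,S\,P - k_{\mathrm{gluc}}\,P - k_{450}\,P
          + k_{\mathrm{rev}}\,N,\\
\dot S &= \beta_S - \delta_S\,S - k_{\mathrm{sul}}\,S\,P,\\
\dot N &= k_{450}\,P - k_{\mathrm{rev}}\,N - k_{\mathrm{GSH}}\,G\,N
          - k_{\mathrm{PSH}}\,N,\\
\dot G &= \beta_G - \delta_G\,G - k_{\mathrm{GSH}}\,G\,N,\\
\dot T &= k_{\mathrm{PSH}}\,N,
\end{aligned}
$$

with $\dot E_{\mathrm{sul}} = k_{\mathrm{sul}} S P$,
$\dot E_{\mathrm{gluc}} = k_{\mathrm{gluc}} P$ and
$\dot C_{\mathrm{GSH}} = k_{\mathrm{GSH}} G N$ closing the balance. The
model has exactly ten rate constants. Modelling assumptions worth stating
explicitly:

* **Pseudo-first-order P450 and UGT steps.** P450 and the glucuronidation
  cofactors are abundant enough that their levels barely move, so
  $k_{450}$ and $k_{\mathrm{gluc}}$ are effective first-order constants.
  The sulphation cofactor pool, by contrast, is depletable and is tracked
  ($S$), with constitutive turnover $\beta_S/\delta_S$.
* **One reverse path.** NAPQI breakdown back to APAP is a single
  first-order term $k_{\mathrm{rev}} N$; whether the reversal is enzymatic
  or spontaneous is kinetically indistinguishable at first order.
* **Inexhaustible protein thiols.** Adduction is a simple decay term
  $k_{\mathrm{PSH}} N$; there is no protein-depletion mode. $T$ is an
  accumulated total, not a standing concentration — by default it has no
  decay. An optional turnover `delta_T` exists but is off (zero) by
  default and excluded from the ten-constant core when zero.
* **1:1 stoichiometry** is assumed for both bimolecular steps (one $S$ per
  sulphated APAP, one $G$ per conjugated NAPQI); this is the simplest
  mass-action reading of the pathway and the only one under which the
  conservation identity below holds with unit coefficients.
* **Initial condition.** A healthy dosed cell: $P(0)=P_0$,
  $S(0)=\beta_S/\delta_S$, $G(0)=\beta_G/\delta_G$ (the healthy-cell GSH
  level), $N(0)=T(0)=0$.

The key dynamical feature is the **branch switch** at the NAPQI node: while
$k_{\mathrm{GSH}} G \gg k_{\mathrm{PSH}}$ almost all NAPQI is detoxified;
as $G$ is consumed the balance flips and adduction dominates.
`branch_fraction()` exposes the instantaneous toxic fraction
$k_{\mathrm{PSH}}/(k_{\mathrm{PSH}} + k_{\mathrm{GSH}} G)$.

### Conservation

Summing the equations, $P + N + T + E_{\mathrm{sul}} + E_{\mathrm{gluc}} +
C_{\mathrm{GSH}} = P_0$ exactly for all $t$ (when `delta_T = 0`): every
drug molecule is in exactly one pool. `conservation_residual()` reports the
deviation from this identity; it is simultaneously a solver-accuracy meter
and a regression guard on the pathway wiring (zeroing any cumulative pool
is detected immediately).

### Numerical choices

Integration uses `deSolve::ode` with `lsoda`, which switches itself between
non-stiff and stiff (BDF) methods — the GSH conjugation flux can run four
orders of magnitude faster than pool turnover. Default tolerances are
`rtol = 1e-10`, `atol = 1e-12`. These are deliberately tight: global error
accumulates on the scale of the *largest* state, and parameter sets
combining a small dose with a large GSH baseline (hundreds of mM) would
otherwise leave conservation residuals above $10^{-6} P_0$; at the
defaults the residual stays near $10^{-8} P_0$ across two-decade random
parameter sweeps, at no measurable runtime cost for this 8-state system.
State values that undershoot zero within solver error (bounded by
$10^{-6}$ of the problem scale) are clamped to exactly zero; larger
undershoots raise an error rather than being silently repaired. Reported
trajectories therefore satisfy non-negativity exactly, and cumulative
pools are monotone up to accumulated solver error.

### Units

The model is published without parameter values, so units are a package
convention: concentrations in mM, time in hours, bimolecular constants in
mM$^{-1}$h$^{-1}$. The reference parameter set in `default_config()` is
synthetic and illustrative. It was chosen once, on biological plausibility
grounds: a healthy GSH level of 4 mM with production 2 mM/h; conjugation
($k_{\mathrm{GSH}} = 50$ mM$^{-1}$h$^{-1}$) fast against adduction
($k_{\mathrm{PSH}} = 0.4$ h$^{-1}$) so the detox branch dominates at low
dose; and phase II clearance ($k_{\mathrm{sul}} S + k_{\mathrm{gluc}}
\approx 0.65$ h$^{-1}$) a few-fold faster than bioactivation
($k_{450} = 0.2$ h$^{-1}$). With these values NAPQI production overtakes
GSH replenishment between roughly 10 and 20 mM initial dose, so the
GSH-depletion switch — the scientifically interesting regime — sits inside
the default dose scan.

## Parameter estimation

`fit_rate_constants()` estimates any subset of the constants from
time-course data by Levenberg--Marquardt (`minpack.lm::nls.lm`) on
**log-transformed** parameters, which enforces positivity and equalises
step sizes across constants spanning decades. Residuals are scaled per
species by the observed column maximum; without this the objective is
dominated by the parent drug (mM scale) and the adduct pool (three orders
smaller) carries almost no weight. Identifiability is screened before
optimisation by a finite-difference sensitivity probe at the start point:
with $P_0 = 0$ the data contain no information about any reaction
constant, and the fit reports non-identifiability instead of returning the
start values as "estimates".

## The zonated sinusoid

The transport unit is a Krogh cylinder: a fibre of length $L$ with lumen
radius $R_l$, membrane thickness $R_m$ and a cell-bearing annulus of depth
$R_e$. The full lumen/membrane/ECS transport problem (Navier--Stokes plus
Darcy flow, radial diffusion) is out of scope; the one feature the model
needs is a controlled, monotone axial oxygen gradient, and for that a
reduced 1-D plug-flow balance suffices:

$$ Q\,\frac{dc}{dz} = -A_{\mathrm{cell}}\,
   \frac{V_{\max}\,c}{K_m + c}, \qquad c(0) = c_{\mathrm{in}}, $$

with $A_{\mathrm{cell}} = \pi\!\left[(R_l+R_m+R_e)^2 - (R_l+R_m)^2\right]$
the annular cross-section of the cell layer. The two analytic limits
(linear decline for $K_m \to 0$, exponential for $K_m \gg c$) serve as
oracles in the test suite, and the scaling identity
$c(z; 2Q) = c(z/2; Q)$ holds exactly. In the zero-order limit the profile
can legitimately hit zero; it is clamped there and the profile flagged
anoxic rather than raising an error. Radial gradients within each zone are
ignored — the cell model is well-mixed, so radial resolution would add
structure the model cannot verify.

Positions are fractions of $L$, with $z = 0$ the portal/inlet end and
$z = 1$ the central/outlet end; the fibre is split into equal closed-open
zones (24 by default) and oxygen is evaluated at zone midpoints. Tertile
boundaries at $L/3$ and $2L/3$ define the periportal, midzonal and
centrilobular bands.

### Oxygen-to-parameter mapping

No quantitative oxygen-to-enzyme map is established for this system, so
the default is the simplest monotone choice: linear interpolation in
oxygen, with direction fixed by the biology — $k^*_{450}$ rises from
`k450_min` at inlet oxygen to `k450_max` at the profile minimum
(CYP2E1/3A are centrilobular), and $\beta^*_G$ falls from `betaG_max` to
`betaG_min` (GSH is depleted centrally). The initial dose field is uniform
by default; the drug is assumed well-perfused, and no claim is made about
axial drug depletion (a custom `P0` mapping function is accepted for users
who want one). Custom non-monotone mappings are accepted but flagged in
the output metadata rather than rejected.

Each zone then runs the cell model independently — zones are coupled only
through the oxygen-derived parameter fields, which is verified by a
permutation test. `classify_injury()` thresholds terminal $T$ and reads
the pattern off the injured tertiles: injury reaching the central tertile
but sparing the portal one is **centrilobular**, the mirror case
**periportal**, all three tertiles **panlobular**, only the middle tertile
**midzonal**, and no injured zone **none**. The midzonal label and the
treatment of mixed cases are package decisions: severe centrilobular
necrosis extends midzonally in the pathology literature, so reaching-but-
not-spanning cases inherit the label of the pole they include, and the
disjoint portal+central case (never produced by monotone mappings) falls
back to panlobular.

## Dose--response

`dose_response_scan()` runs the cell model over a dose grid, evaluates one
of three damage metrics — terminal adduct burden `terminal_T` (the
default; cumulative covalent damage), NAPQI exposure `auc_N` (trapezoidal
AUC), or `peak_N` (peak concentration) — and maps damage to survival with
a decreasing Hill transform fixed to asymptotes $[0, 1]$:
$s = 1 - d^n/(\mathrm{EC}_{50}^n + d^n)$. All three metrics are offered
because the field genuinely disagrees on whether cytotoxicity tracks
cumulative exposure or peak levels; the package takes no side, and the
test suite includes a constructed pair of equal-AUC, different-peak
profiles to keep the distinction observable. The damage-to-survival link
for APAP is not quantitatively established; the transform is a
configurable assumption, not a calibrated claim.

`fit_hill()` fits the four-parameter logistic by bounded
Levenberg--Marquardt with EC$_{50}$ parameterised on the log-dose axis,
asymptotes bounded in $[0,1]$, Hill coefficient in $(0, 20]$, and
EC$_{50}$ confined to a decade beyond the dose range. Three deterministic
starts (EC$_{50}$ at the 25th/50th/75th log-dose percentiles) guard
against local minima; ties are broken by residual, then by the lower Hill
coefficient. Constant responses and all-zero dose grids are reported
non-identifiable rather than fitted.

## Synthetic fixtures

The model is published unparameterised, so `generate_fixtures()` exists to
exercise the estimation machinery, not to mimic any experiment: rate
constants are drawn log-uniformly within configured ranges, clean
trajectories are verified against the conservation identity *before*
noise, and noise is multiplicative Gaussian (relative error is the natural
model for concentration readouts), floored at zero. Everything is
deterministic given the seed. What these fixtures do **not** emulate:
measurement sparsity and irregular sampling, inter-cell heterogeneity,
systematic assay bias, and any real APAP kinetics — recovery results on
them demonstrate that the estimator is correct and well-conditioned, not
that real rate constants are recoverable from real assays.

## Problem sizes used in validation

The test suite and the acceptance script run: conservation sweeps over 200
random parameter sets (two decades around the reference values, doses
0.5--50 mM, 24 h horizons); recovery studies with 20 noise replicates on
41-point trajectories (1% noise) and 12-point log-dose grids (2% noise);
and zonation runs with 12--24 zones. These sizes give stable medians for
the stochastic checks while keeping a full run in the minutes range on a
single core.

## Known limitations

* No intracellular spatial resolution, enzyme regulation (Nrf2 induction,
  CYP dynamics), mitochondrial injury or immune amplification — the model
  stops at adduct formation.
* The adduct pool is a damage *proxy*; no quantitative adduct-to-death
  relation is claimed.
* The oxygen balance ignores membrane resistance, ECS convection and
  radial gradients; it produces gradients of the right shape and
  controllability, not calibrated oxygen fields.
* All default parameter values are synthetic; none should be quoted as
  measurements.
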