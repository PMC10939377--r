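---
title: "Modelling kin-bacteria coexistence under pulsed antibiotic stress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling kin-bacteria coexistence under pulsed antibiotic stress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(kincoex)
```

## The system and the model

`kincoex` simulates a small bacterial community of kin strains — a slow-growing
*cooperator* that detoxifies an antibiotic (here sulfamethoxazole, SMX, at
200 µg/l) as a public good, and a fast-growing *cheater* that enjoys that
protection without paying for it — optionally joined by a third, non-kin
*regulator* species. The dynamical core is a Lotka–Volterra competition model
extended with an Allee factor and a time-windowed, density-dependent
antibiotic mortality term. For members $X_i$ (abundances normalized to the
carrying capacity $K = 10^9$ CFU/ml):

$$
\frac{dX_i}{dt} \;=\; r_i X_i\left[\frac{X_i}{a_i + X_i}\,(1 - X_i)
\;-\; \sum_{j \ne i} \alpha_{ij} X_j\right] \;-\; \mu_i(t, D)\, X_i
$$

* $r_i$ — maximum per-capita growth rate (h$^{-1}$). Defaults: cooperator
  0.5, cheater 0.75, regulator 0.75 (matched to the cheater).
* $a_i$ — Allee constant; $X/(a+X)$ is 1 for $a = 0, X > 0$ and defined as 0
  at $X = 0$, so an extinct member has derivative exactly zero. Defaults 0.
* $\alpha_{ij}$ — effect of member $j$ on member $i$; positive values are
  inhibitory under the minus-sign convention. Defaults between the kin pair:
  $\alpha_{AB} = 1.9$, $\alpha_{BA} = 1.75$ — both above 1, so the
  death-free pair is bistable and competition ends in exclusion. Regulator
  pairs are mirror-equal ($\alpha_{iC} = \alpha_{Ci}$), the
  complete-correlation assumption used in the sweeps.
* $\mu_i(t, D)$ — additional mortality, active only inside the antibiotic
  window (default hours [72, 96) of the run, i.e. the fourth daily cycle).
  The cooperator has $\mu_A = -0.6$ h$^{-1}$: a negative death rate, i.e. a
  hormetic growth boost while the drug is present. The regulator's rate
  follows its phenotype: sensitive $0.8$, detoxifying $-0.3$, intrinsically
  resistant $0$.

The cheater's mortality is a *linear function of the run's initial total
density* $D$ — the inoculum-density effect of cross-protection: more
cooperator biomass at inoculation clears the drug faster, so the cheater
dies less. The package parameterizes the line as

$$\mu_B(D) \;=\; \mu_{B,\max}\,\max\!\left(0,\; 1 - D/D_{\text{protect}}\right),$$

clamped below at zero (density-dependent mortality never becomes growth).
Only the *linearity* of $\mu_B(D)$ is part of the model's provenance; its
two coefficients are free parameters of this package. The shipped defaults
are $\mu_{B,\max} = 1.2$ h$^{-1}$ and $D_{\text{protect}} = 0.2$
(2×10$^8$ CFU/ml), chosen by calibration against the qualitative behaviour
the model is meant to exhibit:

* an *unprotected* cheater must decline during the pulse despite growing at
  0.75 h$^{-1}$ — hence $\mu_{B,\max}$ clearly above 0.75 (net kill
  ≈ 0.45 h$^{-1}$, a several-log drop per day, the scale observed for a
  sensitive strain under 200 µg/l SMX). With $\mu_{B,\max}$ at or below the
  growth rate the low-inoculum cooperator flip never occurs at any
  $D_{\text{protect}}$.
* mortality must remain partially active across the experimentally probed
  inoculum range (10$^5$–10$^8$ CFU/ml, $D$ = 10$^{-4}$–10$^{-1}$), because
  a widened 48-h pulse can only dethrone the cheater at high inoculum if
  $\mu_B$ is still positive there — hence $D_{\text{protect}}$ above that
  range.

Both are `config`-exposed (`kin_pair_model()`, `death_density_protected()`).

## The serial-dilution protocol

`run_protocol()` alternates 24-h batch growth cycles (`integrate_cycle()`)
with instantaneous dilution events (`apply_dilution()`), for 7 cycles
(168 h) by default. Two dilution conventions are supported: back to the
fixed initial total density (the simulation convention; composition is
preserved exactly) or by a fixed factor (default 10-fold, the experimental
transfer convention). The antibiotic window is expressed in absolute hours
and simply overrides the death-model windows of the member models, so a
single model object can be run with, without, or with a lengthened pulse.

```{r example-run}
traj <- run_protocol(kin_pair_model(), protocol_spec(),
                     solver_opts(out_dt = 0.5))
traj
plot(traj)
```

## Outcome classification and phase diagrams

`classify_coexistence()` applies the operational rule: a community
*coexists* iff no member is extinct and no member's abundance declined by
strictly more than 20% over the final cycle, measured from its
post-dilution start to its pre-dilution end. Exactly 20% still counts as
coexisting (the comparison carries a 10$^{-12}$ float guard). A decline
baseline against the member's share of the global inoculum is available
behind the `baseline` switch. Communities failing the rule are
`exclusion` (annotated with the dominant member; ties break to the lowest
index with a message) or `collapse` when nobody survives.

The per-cycle baseline, rather than the raw global inoculum, is used
because an absolute comparison of a saturated end-of-cycle population
against a diluted inoculum would label nearly everything as growth; the
within-cycle decline is what signals a pathway toward extinction.

`sweep_two_member()` maps (cheater growth rate × initial density) to the
final dominant member — the density axis sets both the integration initial
condition and $\mu_B(D)$ — and `sweep_three_member()` maps the regulator's
mutual interaction coefficients ($\alpha_{AC}$, $\alpha_{BC}$), or its
growth rate, to the coexistence category, per phenotype. Grid cells are
annotated with the interaction regime: competition (both coefficients
positive), mutualism (both negative), exploitation (mixed signs); cells
with an exactly-zero coefficient are labelled `neutral`. The reference
resolution for production diagrams is 500 points per axis; the package's
tests and the bundled acceptance analysis run 25-point axes through the
identical code path, and all workhorse runs here use 24-h cycles with
dense output every 0.1–3 h depending on whether the full trajectory or
only cycle snapshots are needed.

```{r sweep-demo}
pd <- sweep_two_member(kin_pair_model(), protocol_spec(),
                       cheater_rate_range = c(0.55, 0.75),
                       D_range = c(1e-4, 1e-1), n_points = c(5, 9))
table(pd$grid$dominant)
```

## Numerical choices

* **Integrator.** `deSolve::ode()` with `lsoda` (stiff-capable, automatic
  switching), `rtol = 1e-8`, `atol = 1e-12`. Each cycle is split into
  sub-segments at antibiotic-window boundaries, so the death term is
  piecewise constant within every solver call and the discontinuity never
  sits inside an adaptive step. Halving the tolerances moves final-cycle
  abundances by far less than 10$^{-6}$ (asserted in the tests).
* **Extinction floor.** $\varepsilon = 10^{-9}$ normalized (≈1 cell/ml)
  is the extinction *threshold* used by the classifier,
  `extinction_cycle()` and reporting. A hard clamp-to-zero during
  integration (root-triggered deSolve event) is available via
  `solver_opts(clamp = TRUE)` but is **off by default**: the phase
  diagrams depend on rare lineages rebounding after the pulse, which is
  the behaviour of the continuous ODE system this package reproduces. With
  the clamp on, a low-inoculum cooperator is already extinct when the
  day-4 pulse arrives and the density-dependent state switch disappears —
  users wanting demographically honest extinctions should enable the clamp
  knowingly.
* **Degenerate inputs.** All-zero states are absorbing; dilution of a
  collapsed community warns and returns zeros; a member at exactly the
  fixed point has residual 0 to machine precision.
* **Determinism.** Runs are deterministic given inputs; repeated runs are
  bit-identical. All synthetic-data randomness flows from explicit seeds
  through a local RNG scope that restores global state.

## Design choices where the ground truth was open

* **Growth-rate assignment.** The two kin growth rates (0.5 and 0.75
  h$^{-1}$) are attributed cooperator = 0.5, cheater = 0.75: only this
  assignment makes the cheater the faster competitor, which the
  exclusion-in-three-cycles behaviour and the phase-diagram axis
  ("reducing the cheater's rate from 0.75") require. The opposite
  attribution appears in one parameter listing of the source material and
  is rejected as a symbol swap.
* **Run length for classification.** Every simulation runs 168 h
  (7 cycles) by default, including coexistence classification. Classifying
  at 5 cycles — one cycle after the pulse — is dominated by the pulse
  transient (it even labels facilitation-only communities as coexisting);
  two further recovery cycles make the final-cycle rule informative.
* **Default inoculum.** $D = 10^{-2}$ (10$^7$ CFU/ml), the pivotal
  switching density of the two-member experiments.
* **Window placement.** "Antibiotic added on day 3 before dilution" is
  mapped to absolute hours [72, 96).

## The synthetic-data generator

`generate_od_curves()`, `generate_cocult_counts()` and
`generate_smx_decay()` emulate the three experimental data shapes the
estimators consume: plate-reader OD600 growth curves over a log-spaced
inoculum grid (logistic ground truth, fixed OD-per-density conversion of
10$^{-9}$ OD per CFU/ml, multiplicative lognormal noise, additive
rate effects in SMX wells), daily selective plate counts along a protocol
trajectory (Poisson counting noise at an auto-chosen power-of-ten dilution
targeting 30–300 colonies), and linear antibiotic decay with slope
proportional to cooperator density. What they deliberately do *not*
emulate: lag phases, non-logistic growth shapes (Gompertz/Baranyi),
plate-to-plate systematic error, pipetting error correlated across a
dilution series, or mechanistic pharmacodynamics. Parameter-recovery tests
passing on these generators therefore demonstrate estimator correctness
under the stated noise model, not robustness to real-world growth-curve
pathology.

`effective_growth_rate()` implements the threshold-crossing estimator: the
decadal-log rate $\log_{10}(\mathrm{OD}_{thr}/\mathrm{OD}_i)/T_{thr}$ with
$\mathrm{OD}_{thr} = 0.5$ and the crossing time linearly interpolated
between bracketing samples; wells that never cross within the horizon are
censored and excluded from group comparisons (with counts retained).
Group contrasts use the two-sided Wilcoxon rank-sum test, exact for both
groups ≤ 12 without ties.

## Known limitations

* The antibiotic is not a state variable: the pulse is represented purely
  through the mortality window, so protection dynamics within a cycle
  (drug decaying below the MIC part-way through) are averaged into
  $\mu_B(D)$.
* Three-member coexistence in this model is *pulse-maintained, not
  asymptotically stable*: the continuous three-species competition system
  with the default kin coefficients has no stable interior equilibrium
  (the kin 2×2 principal minor of $I + \alpha$ is negative), and runs
  extended well beyond the pulse relax toward exclusion. The
  coexistence regions reported by `sweep_three_member()` are confined to
  the competition quadrant, hug the $\alpha_{AC} \approx \alpha_{BC}$
  diagonal with a bias toward slightly *stronger pressure on the
  cooperator* — the pulse-boosted cooperator is the long-run-stronger kin
  member under the calibrated mortality — and thin out as the horizon
  grows. The bundled acceptance analysis reports the persistence fraction
  honestly rather than assuming an equilibrium.
* Spatial structure, demographic noise, horizontal gene transfer and
  explicit resource competition are out of scope; the regulator's resource
  advantage is represented only through its interaction coefficients.
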