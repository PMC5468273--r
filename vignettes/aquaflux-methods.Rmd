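---
title: "Models and methods behind aquaflux"
author: "Package Author"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind aquaflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquaflux)
```

aquaflux implements the quantitative chain used to characterize insect
aquaporin (AQP) channels: heterologous expression in *Xenopus laevis*
oocytes read out by swelling assays, relative transcript quantification by
qPCR, and in vivo excretion/fecundity phenotypes in blood-feeding bugs.
This vignette describes the models, the tunable parameters and their
defaults, the numerical choices, and what the built-in synthetic data can
and cannot tell you about real experiments.

## The osmotic swelling model

An oocyte equilibrated in ~200 mOsm medium and dropped into a 70 mOsm bath
swells as water follows the osmotic gradient. We model the cell as a single
well-mixed compartment of volume $V$ with fixed membrane area $S$:

$$\frac{dV}{dt} = P_f \, S \, V_w \, \big(\mathrm{osm}_{in}(t) -
  \mathrm{osm}_{out}\big), \qquad
  \mathrm{osm}_{in}(t) = \frac{\mathrm{osm}_{in,0}\, V_0}{V(t)},$$

where $P_f$ (cm/s) is the osmotic water permeability, $V_w = 18$
cm$^3$/mol the molar volume of water, and the second relation expresses
conservation of the impermeant internal osmolytes. Geometry defaults are
the standard oocyte values $V_0 = 9\times10^{-4}$ cm$^3$ and $S = 0.045$
cm$^2$ (`oocyte_geometry()`). Concentrations are accepted in mOsm/mM and
converted once, in a single internal helper, to mol/cm$^3$
($\times 10^{-6}$).

Assumptions worth keeping in mind:

* **Fixed surface area.** The slope formulas use a constant $S$, so the
  simulator does too. Real oocyte membrane unfolds microvilli as the cell
  swells; at large $V/V_0$ the model therefore understates area and the
  permeability read off a late window inherits a downward bias. Initial
  slope fits over short windows are insensitive to this.
* **All volume osmotically active.** There is no solid fraction, which
  keeps the equilibrium closed-form: swelling stops exactly at
  $V/V_0 = \mathrm{osm}_{in,0}/\mathrm{osm}_{out}$
  (`equilibrium_relative_volume()`; 200/70 = 2.857 for the reference
  assay). Real oocytes have a non-osmotic fraction of roughly 15–30%, so
  measured plateaus sit below this.
* **First-order relaxation.** The volume approaches equilibrium
  monotonically with no overshoot; tests assert this.

For the solute (glycerol/urea) assay the bath is isosmotic overall —
medium mixed 1:1 with isosmotic solute solution, i.e. 100 mOsm salts plus
100 mM test solute against 200 mOsm inside — and a second state variable
tracks the internal solute amount $s$:

$$\frac{ds}{dt} = P_s \, S \,\big(\mathrm{sol}_{out} -
  \mathrm{sol}_{in}(t)\big), \qquad \mathrm{sol}_{in} = s/V,$$

with the water equation driven by the *total* internal osmolarity
(conserved osmolytes diluted by $V$, plus $\mathrm{sol}_{in}$). Solute
entry raises internal osmolarity and water follows; with $P_s = 0$ nothing
happens, and with $P_f = 0$ solute enters but the volume — the assay's
only readout — stays flat. The latter mirrors the co-expression logic of
the biology: a glyceroporin's solute flux is invisible in a swelling assay
unless water permeability is present.

**Integration.** Both models are integrated with `deSolve::lsoda` at
`rtol = 1e-10`, so osmolyte conservation and agreement with fine-grid
reference runs hold to about $10^{-7}$ relative; tests compare a
`dt = 0.1` s trajectory against a `dt = 0.002` s one. An integrator
failure raises an error rather than returning a truncated trajectory.

## Estimating Pf and Ps from area time courses

The measured quantity is the cross-sectional area $A_t$ from a
camera-equipped microscope. `fit_swelling()` converts to relative volume
per oocyte via $V/V_0 = (A_t/A_0)^{3/2}$, always normalizing to that
oocyte's own first frame, fits $d(V/V_0)/dt$ by ordinary least squares
(free intercept) over an early window, and inverts

$$P_f = \frac{V_0 \, d(V/V_0)/dt}{S \, V_w \,
  |\mathrm{osm}_{in} - \mathrm{osm}_{out}|}, \qquad
  P_s = \frac{V_0 \, d(V/V_0)/dt}{S \, V_w \,
  |\mathrm{sol}_{in} - \mathrm{sol}_{out}|}.$$

Two conventions are deliberate and documented:

* **Gradient magnitude.** The raw gradient $(\mathrm{sol}_{in} -
  \mathrm{sol}_{out})$ is negative during influx, which would make every
  influx-driven coefficient negative; both estimators therefore use the
  magnitude so that swelling yields positive coefficients.
* **$V_w$ in the Ps formula.** Part of the oocyte literature defines
  $P_s$ without the molar volume of water. This package keeps $V_w$ in
  both formulas; Ps values are only comparable within one convention.

**Fit windows.** The default water window is 20 s of the 60 s record: over
20 s internal dilution shrinks the gradient by ~7%, biasing the fitted
slope only ~3% low, while averaging 21 frames of measurement noise.
Because that dilution bias grows with window length, noise-free estimates
decrease strictly across windows {5, 10, 20, 40, 60} s — a property the
tests assert rather than correct for, since the slope method is defined by
its window.

The solute window needs more care. Early on the volume response *lags*
solute entry: $d(V/V_0)/dt \approx (P_f S V_w/V_0)\,\mathrm{sol}_{in}(t)$
with $\mathrm{sol}_{in}$ growing from zero, so the fitted slope ramps
roughly linearly with the window and the operational $P_s$ is
window-dependent. Expanding for small $t$, the OLS slope over $[0, T]$
matches $P_s S V_w \mathrm{sol}_{out}/V_0$ at the calibration window
$T^* = 2 V_0 / (P_f S)$ — 2.0 s at the reference conditions — up to a
solute-saturation correction of order $-15\%$ there. The package defaults
the solute window to 2 s, and the round-trip test asserts recovery at 15%
tolerance. The practical reading: the slope-based Ps is an operational,
window- and Pf-dependent index of solute transport, not a pure membrane
constant; compare Ps values only across groups measured with one window
and comparable Pf.

**Quality control.** Fits with $R^2 < 0.8$ are flagged, never dropped:
the class of experiment reports minima of five oocytes per group and
silently discarding records would bias small-group statistics. Mercury
inhibition is summarized by `inhibition_percent()` (100·(1 −
treated/untreated), unclipped by default so stimulation is visible), and
`effective_pf()` models Hg$^{2+}$ block as a multiplicative Pf reduction
with partial restoration after 2-mercaptoethanol — a phenomenological
factor, not binding kinetics.

**Group statistics.** Per-oocyte coefficients (slopes fitted per oocyte,
never on pooled data — matching designs that report per-oocyte minima) go
into `compare_groups()`: a two-sided Welch t-test for two groups
(unequal-variance by default; the pooled/Welch choice is rarely stated in
assay write-ups and Welch is the safer default), otherwise one-way ANOVA
with Tukey HSD.

## Relative expression by the ddCt method

`relative_expression()` implements the standard
$RQ = 2^{-\Delta\Delta C_t}$ of Livak & Schmittgen (some write-ups print
the exponent sign convention loosely as "$-2^{\Delta\Delta C_t}$"; the
standard form is what is computed). Replicate $C_t$s are averaged before
differencing; replicate SD is propagated to the fold range
$2^{-(\Delta\Delta C_t \pm s)}$ with $s = \sqrt{s^2_{target} +
s^2_{ref}}$. The calibrator group has $RQ = 1$ identically, and $RQ$ is
invariant to adding a constant to all $C_t$s of one sample — the
reference-gene normalization property, asserted as a test.

Primer sets are *gated*, not corrected: `efficiency_from_dilution_series()`
fits $C_t$ against $\log_{10}$ dilution, converts the slope to
$E = 10^{-1/\mathrm{slope}} - 1$, and flags genes outside $0.9 \le E \le
1.1$. Gated-out genes should be excluded with a logged warning rather than
rescued by Pfaffl-type efficiency correction, which is out of scope here.
`knockdown_timecourse()` applies the machinery per day post injection with
the matched-day control as calibrator, carrying non-target genes as
off-target check slots.

## Phenotype endpoints

Excretion is weight loss relative to the gained meal: with pre-feed weight
$W_{t-1}$, fed weight $W_{t0}$ and $W_{gained} = W_{t0} - W_{t-1}$,

$$\%\ \mathrm{excreted}(t_n) = 100\,\frac{W_{t0} - W_{t_n}}{W_{gained}}.$$

The raw difference $W_{t_n} - W_{t0}$ is negative as weight is lost; the
positive magnitude is reported. Weight *increases* between time points
(balance jitter, grooming water) are retained and flagged, never forced
monotone. Engorgement is $100 (W_{t0} - W_{t-1})/W_{t-1}$.

Urea is back-calculated from a linear colorimetric standard curve
(`fit_urea_curve()`, OLS, positive slope enforced), then scaled from
reaction to bug: 20 µL of excreta solution assayed out of the 100 µL well
resuspension gives the factor 5 in `urea_per_bug()`. Absorbances below the
blank intercept floor at 0 with a warning; values outside the calibrated
range carry an extrapolation flag. The linear curve form and the standard
levels are configuration, not assumptions baked into the analysis.

`endpoint_comparison()` runs the two-sided Welch t-test on the 24-h
excretion percentage, per-bug urea, or total eggs, reporting the
difference of means with a 95% confidence interval alongside the p-value
(effect sizes are worth having even when the original write-ups report
only p). Egg analysis uses the per-bug total until oviposition ceased;
the daily series is retained in the generator output but not modeled
further (no survival/life-table analysis).

## The synthetic-data generators

Every analysis stage has a matching seeded generator, so the whole chain
is testable without laboratory data. The generators take explicit integer
seeds, never touch the global RNG state, and are bit-reproducible.

* `sim_swelling_cohort()`: per-oocyte permeabilities are lognormal
  (permeabilities are positive and right-skewed) with mean `pf_true` and
  CV `pf_cv` (default 10%); trajectories come from the forward model;
  areas are recovered under the sphere relation (the $t=0$ area is
  consistent with $V_0$) and multiplied by mean-one lognormal per-frame
  measurement noise with CV `area_noise_cv` (default 2%). Defaults are the
  reference assay: Pf $2\times10^{-2}$ cm/s (a high-efficiency water
  channel), 200 → 70 mOsm, 60 s at 1 s sampling (a plausible frame
  interval for a camera-equipped microscope; the interval is rarely
  reported), five oocytes.
  Noise propagation is worth internalizing: 2% area noise is 3% noise on
  $V/V_0$, which over a 20 s window at 1 s sampling puts an SD of
  $0.03/\sqrt{770} \approx 1.1\times10^{-3}$ s$^{-1}$ on the fitted slope
  — about half the true slope. Per-oocyte Pf estimates under these
  defaults scatter accordingly, and five-oocyte group means carry ~20%
  standard error; the parameter-recovery simulations in the tests and the
  acceptance script measure exactly this.
* `sim_ct_table()`: target $C_t$ = baseline − $\log_2$(fold) + Gaussian
  cycle noise; the reference gene is independent of group. Noise-free
  tables round-trip exactly through `relative_expression()`. Three
  replicates per group matches the knockdown-assessment design.
* `sim_bug_cohort()`: unfed weight lognormal around 4 mg (CV 10%, adult
  females); engorgement Gaussian 318 ± 72% of pre-fed weight; excretion an
  exponential approach $F(t) = p\,(1 - e^{-\lambda t})$ to a plateau
  fraction $p = 0.5$ of the meal with half-time 4 h, per-bug lognormal
  rate variation (CV 20%), weights on the canonical 1, 2, 3, 4, 6, 8, 12,
  24 h grid; excreta urea proportional to mass excreted (20 nmol/mg); egg
  totals negative binomial (over-dispersed counts, mean 6, size 8). The
  treatment group's rate is scaled by `effect_multiplier` (1 = exchangeable
  null) and its egg mean by `fecundity_multiplier`. The functional form of
  the excretion curve and every noise magnitude are the generator's own
  choices — published curves are empirical and report no noise levels — so
  they are parameters with stated defaults, not hidden constants.
* `sim_urea_plate()`: absorbance = slope·nmol + intercept + read noise;
  noise-free plates round-trip exactly.

**What passing tests do and do not show.** The generators reproduce the
statistical *structure* the analyses assume: lognormal biological
variation, multiplicative measurement error, exponential-like excretion,
over-dispersed counts. They do not emulate image segmentation artifacts,
membrane unfolding, oocyte batch effects, incomplete blood meals,
redundant channel activity in vivo, or non-linear plate chemistry.
Recovery and calibration results on synthetic cohorts are therefore
statements about the estimators under their own assumptions — necessary,
not sufficient, evidence about real assays.

## Problem sizes and determinism

The simulation studies shipped in the tests and the acceptance script use
200 five-oocyte cohorts for Pf recovery, 1000 null and 200 effect cohorts
of 10 bugs per group for the t-test calibration and power, and a
$2\times10^4$ s horizon for the equilibrium check — sizes at which the
Monte-Carlo error on the reported rates is a few percent and a full run
stays under a minute. All randomness flows through explicit integer
seeds; derived sub-seeds are kept below $2^{31}$.
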