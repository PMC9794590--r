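---
title: "Whole-body PBPK modelling of schaftoside: model, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-body PBPK modelling of schaftoside: model, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(schaftosim)
```

## The problem

Schaftoside is the marker flavone C-glycoside of total flavonoids of
*Desmodium styracifolium* (TFDS), an approved herbal treatment for
urolithiasis. It is hydrophilic (logP −2.427), a weak monoprotic acid
(pKa 6.35), moderately protein-bound (fu 0.2665), essentially not
metabolized by liver microsomes, and excreted unchanged in urine (~55% of
an intravenous dose in rat) and bile (~25%). Oral bioavailability from TFDS
is very low (<5%). Because renal excretion dominates elimination, exposure
in patients with chronic kidney disease (CKD) is the clinically interesting
unknown, and a physiologically based pharmacokinetic (PBPK) model is the
natural tool: it carries disease physiology (GFR, kidney volume and
perfusion, protein binding, gastrointestinal transit) explicitly.

`schaftosim` implements that analysis end to end: reference rat and human
physiologies, a whole-body perfusion-limited ODE model with oral
absorption, non-compartmental analysis (NCA), fold-error model
qualification, local sensitivity analysis, and virtual-population
simulation for elderly and CKD stage 3–5 populations.

## Model structure

The state is the amount (mg) of drug in 13 body compartments (venous and
arterial blood, lung, heart, brain, muscle, adipose, skin, bone, kidney,
liver, spleen, gut wall), six gut-lumen depots (stomach, small and large
intestine, each split into undissolved and dissolved drug) and four
cumulative sinks (urine, bile, a residual route, feces). Distribution is
perfusion-limited: each organ exchanges with arterial blood at its blood
flow, leaving at blood concentration $C_T/(K_{p,T}/BP)$, where $K_{p,T}$
is the tissue:plasma partition coefficient and $BP$ the blood:plasma
ratio. Gut wall and spleen drain into the liver through the portal vein.
An optional permeability-limited mode caps organ exchange with
$PS_T = P_{\text{organ}} \times$ (a packaged capillary area density)
$\times V_T$; the default, matching the analysis, is perfusion-limited.

Elimination:

* renal — a plasma clearance acting on the kidney plasma concentration,
  accumulating in the urine sink;
* biliary — a plasma clearance on the liver plasma concentration (bile
  sink); there is no enterohepatic recirculation;
* residual — a site-unspecified plasma clearance on venous plasma. This
  route exists because the rat mass-balance study recovers only ~80% of an
  intravenous dose in urine plus bile even though elimination is complete
  well before 48 h (half-life 0.64 h); a two-route model cannot
  simultaneously match the total clearance and both excretion fractions.
  The residual sink is part of the mass balance:
  body + gut lumen + urine + bile + residual + feces = dose administered,
  enforced to 1e−6 relative at every output time.

All clearance routes scale with the effective unbound fraction
(fu × the individual's fu multiplier) relative to the reference fu at
which the clearance parameters were estimated — a restrictive-clearance
assumption that lets CKD-induced changes in protein binding propagate to
elimination. Human renal clearance additionally scales with GFR relative
to the healthy reference (110.57 mL/min/1.73 m²); rat renal clearance is a
direct parameter.

Oral absorption: dose events deposit drug in the stomach, split into
dissolved and undissolved according to the Weibull dissolution profile
$f(t) = 1 - \exp(-\ln 2\,(t/t_{50})^{shape})$, with $t_{50}$ exactly the
50%-dissolved time. The printed shape parameters (1.08e−3 for the rat
suspension, 3.74e−4 for the human capsule) make dissolution nearly a step:
about half the dose dissolves essentially instantly and the remainder
dissolves on a timescale of decades; we use the printed values verbatim.
Numerically, the Weibull hazard is singular at $t = 0$ for shape < 1, so
the engine applies the closed-form dissolved fraction over the first
0.36 s of each dose analytically and the smooth hazard thereafter;
dissolution is modelled in the gastric compartment only (the residual
undissolved fraction transits and leaves in feces). Gastric emptying and
intestinal transit are first-order; dissolved drug in the small intestine
is absorbed into the liver (portal inflow) with clearance
$CL_a = P_{\text{int}} \times A_{\text{eff}}$, where $P_{\text{int}}$
is the printed transcellular intestinal permeability and $A_{\text{eff}}$
an effective absorption surface area (see calibration). Solubility does
not cap dissolution in the default (empirical Weibull) mode; the
predicted dose-linearity between 0.6 g and 1 g TFDS would be violated by
a solubility cap.

Partition coefficients come from a tissue-composition method: the drug
distributes into tissue water, tissue lipid (weighted by the
ionization-corrected octanol:water partition coefficient of a monoprotic
acid, Henderson–Hasselbalch at plasma pH 7.4 and tissue pH 7.0) and
weakly into tissue protein (weight 0.5), referenced to plasma water
(fraction 0.96); plasma protein binding enters through fu. A single
global calibration scalar rescales all Kp values. For schaftoside the
resulting Kp values are all well below 1 (adipose ≈ 0.05), consistent
with the observed small distribution volume (~0.4 L/kg in rat).

## Physiology

Organ volumes, blood flows and tissue composition are packaged constants
compiled from standard physiology references for a 0.25 kg rat and a
70 kg adult man, rescaled linearly to the requested body weight. Flow
fractions sum to one over the non-lung organs, so the flow-balance
invariant holds by construction. Ageing (human) is a set of documented
constants: cardiac output −1% per decade after age 30, GFR
−8 mL/min/1.73 m² per decade after 40, muscle −3% per decade after 30
with the lost volume shifted to adipose; female individuals get
muscle ×0.85 and adipose ×1.3. The reference clinical individual is the
28-year-old, 56.35 kg, 162.1 cm male used for the human model.

CKD stages are applied as multiplicative fractions of healthy values
(GFR target 60/30/15; kidney volume 0.81/0.61/0.51; renal perfusion
0.55/0.36/0.29; fu 1.07/1.16/1.55; gastric emptying 1.00/1.60/1.60;
small-intestinal transit 1.00/1.40/1.40; large-intestinal transit 1.00),
exactly as packaged in the `table2` fixture. Drug parameters are never
touched by disease scaling.

Gastrointestinal constants (gastric emptying 0.5 h human / 0.25 h rat;
small-intestinal residence 1.6 h human / 1.5 h rat; large-intestinal
transit 20 h / 14 h) are package constants in the range used by
whole-body PBPK platforms for fasted subjects. The human small-intestinal
residence matters: the observed human terminal half-life (1.62 h day 1)
is shorter than $\ln 2 \times$ any longer residence time would allow
(absorption-limited "flip-flop" kinetics), so a fasted-scintigraphy-range
value of 1.6 h is used.

## Calibration

The printed parameter table does not fully determine the model; the
documented calibration step (`calibrate_rat_model()`,
`calibrate_human_model()`) fits the remaining constants against observed
summary statistics, mirroring the "optimized" provenance of several
printed parameters:

* **Rat disposition.** Renal, biliary and residual plasma clearances and
  the global partition scalar are iterated (five fixed-point rounds, each
  one intravenous simulation) until total plasma clearance is
  0.44 L/h/kg, terminal half-life 0.64 h, and the cumulative urinary and
  biliary fractions are 54.59% and 24.78% of dose. The calibrated renal
  clearance (~4.7e−3 L/min/kg) exceeds the printed 2.57e−3 L/min/kg but
  agrees with the observed renal clearance (~50.67 mL/h for a ~0.21 kg
  rat); the printed value cannot reproduce the observed urinary fraction
  together with the observed total clearance.
* **Rat absorption.** The effective absorption area is fitted (three
  fixed-point rounds) to the observed oral AUC0–t at 100 mg/kg TFDS
  (204.75 h·ng/mL).
* **Human.** Elimination is renal-only with the printed human kidney
  plasma clearance (1.24e−3 L/min/kg): the printed human parameter list
  contains no hepatic or biliary term, and a renal-dominated human model
  is also what the published CKD exposure ratios imply. The partition
  scalar is fitted to the observed day-1 terminal half-life (1.62 h) and
  the absorption area to the observed day-1 AUC0–t (13.19 h·ng/mL).

After calibration the rat intravenous and human day-1 predictions fall
well within the two-fold qualification bands, and the excretion fractions
sit inside the observed ranges; the test suite asserts exactly these
bands, not point equality — the original analysis platform's internal
physiology database is not reproducible, and the published qualification
criterion is two-fold agreement.

## Analysis layers

**NCA** (`compute_nca()`): Cmax/Tmax from observed maxima, linear
trapezoidal AUC0–t to the last quantifiable point (log-down variant behind
a flag), terminal slope by log-linear least squares over automatically
selected windows (all trailing windows of ≥3 points after Tmax, best
adjusted R², ties to the longer window), CL/F = Dose/AUC0–inf,
Vz/F = CL/λz, interval metrics for a dosing interval τ. Concentrations
below the quantification limit are zeroed before Tmax and dropped after
(documented choice; the underlying study is silent). Renal clearance is
Ae/AUC0–t with unit reconciliation to mL/h.

**Qualification** (`fold_error_points()`, `afe()`, `aafe()`,
`fold_error_param()`, `evaluate_model()`): per-point fold errors
(acceptance band 0.3–3), average fold error and absolute average fold
error ($10^{\text{mean}(\log_{10} \text{pred}/\text{obs})}$ and the
absolute-log variant; band 0.5–2), and parameter fold errors (band
0.5–2); predictions are interpolated onto the observed sampling times,
and display rounding is two decimals.

**Sensitivity** (`local_sensitivity()`):
$S = (\Delta PK/\Delta p)\,(p/PK)$ by central difference at ±10% (two
simulations per parameter; central rather than one-sided for
second-order accuracy, the original description being ambiguous). Day-1
metrics are computed on the first dosing interval of the full regimen,
day-6 on the final one. In this model the dominant parameters for
exposure are the kidney plasma clearance, the fraction unbound (which
scales elimination through the restrictive-clearance assumption), the
intestinal permeability and the small-intestinal transit time; the
dissolution shape, influential in the original platform's absorption
model, is nearly inert here because the near-step Weibull releases ~50%
of dose regardless of small shape perturbations — a documented structural
difference.

**Populations** (`population_spec()`, `sample_population()`,
`simulate_population()`, `compare_populations()`): sex Bernoulli, age
uniform, multiplicative log-normal (median-preserving) perturbations on
organ volumes, flows, clearance and fu; a single integer seed makes the
draw reproducible element-wise. The published analysis does not state its
variability settings; the declared package defaults are CV 0.15 (volumes,
flows, fu) and 0.25 (clearance), chosen to give day-1 exposure spreads of
the order seen in the published population percentile bands. Percentiles
are empirical; day6:day1 ratio statistics are ratios of means (the
published mean rows are consistent with ratio-of-means arithmetic, e.g.
20.64/2.52 = 8.19), with percentile rows as ratios of the corresponding
percentiles, mirroring the published table layout.

**Synthetic data** (`generate_profile()`, `study_schedules()`,
`generate_predobs()`): proportional-plus-additive residual error with
LLOQ censoring (0.5 ng/mL rat assay, 0.05 ng/mL human assay), the
published sampling schedules, and a predicted/observed pair generator
with a target AFE. Defaults: 10% proportional CV and additive SD of half
the LLOQ — typical bioanalytical variability; the assay validation only
states ±15% acceptance limits, not an error model. The generator emulates
mean-profile shape, assay noise and censoring; it does not emulate
between-subject kinetic variability or absorption-phase irregularities
(multiple peaks, food effects), so parameter-recovery results bound
assay-noise effects only, not real-data robustness.

## Numerical choices

Integration uses `deSolve::lsoda` with rtol 1e−8 and atol 1e−10 mg
(overridable), restarted at every dose event with doses applied as state
jumps (intravenous into venous blood, oral into the gastric depots after
the analytic dissolution split). Output grids are caller-chosen; the
package defaults refine the first two hours. The test suite and
acceptance script use single simulations of at most a 144-hour regimen on
0.02–0.25 h grids and small populations (n ≤ 6 per arm, with n = 100
reserved for the pure sampling layer, and 200 subjects only for the
closed-form NCA recovery study); these sizes keep every check
deterministic and fast while exercising the same code paths as a full
n = 100 population run.

Degenerate inputs are handled explicitly: fewer than three quantifiable
points is an error; fewer than three usable terminal points reports the
λz-dependent fields as missing; an all-equal trough set reports F = 0 and
stationary; zero-variance ANOVA is flagged with a diagnostic note instead
of NaN.

## Known limitations

* The gastrointestinal model is three-segment with first-order transit;
  the original platform uses finer segmentation and a mechanistic
  permeability–surface-area model, so absorption-phase shape (Tmax) is
  approximate even where exposure matches.
* The effective absorption area is a lumped calibrated constant per
  species, not an anatomical area.
* No enterohepatic recirculation, no transporters, no nonlinear binding
  (all deliberately out of scope, matching the source analysis).
* Elderly scaling is a set of documented demographic adjustment
  constants. Because human elimination is renal-only and GFR declines
  with age, the model predicts a mild (~30%) exposure increase at 75
  years, somewhat larger than the near-null elderly effect reported by
  the original platform, whose internal ageing functions are not public.
* The residual clearance is a mass-balance closure, not an identified
  mechanism; it is reported separately from urine, bile and feces in all
  outputs.
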