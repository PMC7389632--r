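---
title: "PBPK-based pediatric dose scaling of lisinopril: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PBPK-based pediatric dose scaling of lisinopril: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its science: the model structure
and its assumptions, the calibration strategy, the choices made where the
design was genuinely open, and what the accompanying tests do and do not
demonstrate.

## Why lisinopril, and what question the package answers

Lisinopril is close to an ideal test case for mechanistic dose
extrapolation. It does not bind plasma proteins, is not metabolised, and
is excreted unchanged by glomerular filtration; its oral bioavailability
is poor (~25%) and limited by intestinal permeability rather than
solubility or first-pass loss. Pediatric dosing in practice relies on
empirical formulas (Young's and Clark's rules, mg/kg and BSA scaling)
that ignore developmental physiology. The package asks: if an adult
whole-body PBPK model is calibrated to published adult pharmacokinetics
and then re-parameterised with pediatric physiology, which doses give
children the same exposure as the adult 20 mg reference dose?

## Model structure

The system is a linear, time-invariant ODE model with 21 amount states.

**Disposition.** Venous and arterial blood bracket the lung; liver,
kidney, gut wall and lumped richly/poorly perfused tissues are
perfusion-limited, `dA_T/dt = Q_T (C_art − A_T/(V_T Kp_T))`. For a
hydrophilic non-binding drug the tissue partition coefficient is modelled
as `Kp_T = s · w_T` with `w_T` the tissue water fraction and `s` a common
scalar. `s` has no independent literature anchor here; it is solved in
closed form so that the steady-state distribution volume referenced to
venous plasma,

`Vss = V_blood + s Σ V_T w_T + (kin/kout) V_blood`,

matches the published 0.89 L/kg.

**Deep distribution.** Lisinopril binds saturably to tissue ACE, which
produces a fast initial decline followed by a long shallow terminal
phase. A mechanistic saturable binding model is out of scope; instead a
deep compartment exchanges linearly with plasma (`kin`, `kout`, both
1/h). This reduced form is linear (so dose superposition holds exactly)
and reproduces the single-dose tail and the slow multiple-dose trough
accumulation, which is the behaviour the dosing analysis needs. It will
not reproduce dose-dependent nonlinearity in the terminal phase, which
the analysis does not use.

**Absorption.** Each gut segment carries solid and dissolved amounts.
Release is first-order with `k_rel = −ln(0.2)/t80`, anchored at 80%
release in 30 min. At 97 g/L solubility the dissolved lumen concentration
never approaches saturation at 20 mg (a guard in the simulator asserts
it stays below 1% of solubility), so first-order release is an adequate
stand-in for a tabulated release profile. Transit is first-order between
segments; absorption flux is `Peff · SA_seg · w_seg · C_dissolved` into
the gut wall, with smooth-cylinder surface areas (mucosal amplification
is absorbed into the calibrated effective permeability `Peff`) and
regional weights duodenum = jejunum = 1, ileum = 0.5, colon = 0.1
reflecting the absorptive (PEPT1-mediated) regional pattern. The
literature quotes a simulator-internal permeability of 3.6e-7 cm/min for
this drug; that value lives on a software-internal scale and is treated
as a reference point, not a constraint — the absolute scale here is
calibrated.

**Elimination.** `CL_R · C_ven`, capped at kidney perfusion ×
arterial concentration (the cap is physically motivated but inactive at
therapeutic concentrations: CL_R ≈ 4 L/h against ~64 L/h of kidney blood
flow). Referencing elimination to the venous (sampling) compartment makes
moment analysis exact for the model, which the Vss round-trip test
exploits.

**Fed state.** A meal multiplies the gastric residence time by
`1 + α · kcal/524` with `α` calibrated; nothing else changes, so oral
bioavailability is food-independent in the model — consistent with the
reference finding that food delays but does not reduce absorption.

## Transit-time defaults

Gastric residence 1.5 h, total small-intestinal transit 5.5 h (split by
segment length), colon 15 h. The first two are deliberately at the slow
end of the physiological range: lisinopril's observed absorption is slow
(fasting Tmax ≈ 6 h), and with textbook-fast defaults (0.25 h gastric,
3.5 h small intestine) the simulated peak arrives 2–3 h early no matter
how the remaining parameters are set. The reference workflow for this
drug likewise adjusted absorption parameters manually until the simulated
profile matched the observed one. These values were fixed once during
adult model development and are not re-fit per run; the gastric value
also absorbs tablet disintegration, which is not modelled separately.

## Staged calibration

Stages mirror the order in which the data identify the parameters:

1. **Partition scalar** — closed-form solve to the Vss anchor
   (0.89 L/kg).
2. **Renal clearance** — golden-section fit to the IV AUC(0–72 h)
   observation (682 ng·h/ml at 2.97 mg). IV data identify disposition
   free of absorption confounding.
3. **Effective permeability** — golden-section fit to the oral fasting
   Cmax (86 ng/ml) and AUC(0–120 h) (1231 ng·h/ml) at 20 mg.
4. **Fed delay α** — golden-section fit to the fed Cmax (69 ng/ml) and
   Tmax (6.8 h); Tmax enters with weight 0.5 because it is quantised to
   the output grid.
5. **Deep exchange (kin, kout)** — fit to the day-1 (8.40 ng/ml) and
   day-10 (12.79 ng/ml) troughs of 20 mg once daily × 10 days.

The objective is `Σ w (ln(pred/obs))²` — scale-free across metrics with
different units; non-positive predictions receive a large penalty
(1e6) rather than an error so searches can recover.

Two design points in stage 5 deserve note. First, it is a genuinely
two-dimensional fit with a curved valley; alternating one-dimensional
golden sections stall on it, so the stage uses a deterministic
grid-seeded Nelder–Mead in log space. Second, the Vss anchor is enforced
*inside* the stage objective (the partition scalar is re-solved for every
candidate `(kin, kout)`): without this the search trades distribution
volume for trough height, and the next stage-1 solve undoes the "fit".
The kin/kout ratio is penalised above 12 to keep the anchor attainable.
Two outer passes over stages 2–5 absorb the remaining couplings
(clearance ↔ permeability through bioavailability, deep exchange ↔ peak
shape). The workflow contains no randomness: identical inputs give
identical results.

The calibrated adult model reproduces the full anchor set — peak
88.5 ng/ml (reference prediction 88.52), fasting Tmax 5.75 h, fed Tmax
7.8 h, bioavailability 24.6%, Vss 0.887 L/kg, troughs 8.40 → 12.79 ng/ml
with monotonically shrinking increments — each computed by the test
suite and the acceptance script, not asserted from memory.

## Pediatric physiology

* **Growth table.** Median weight/height by age, piecewise linear,
  anchored at the group values used throughout the dose comparison
  (10 kg at 1 y, 17 kg at 5 y, 40 kg at 12 y, 60 kg at 17 y; adult
  plateau 70 kg / 170 cm). A ±3% sex offset is phased in over ages 12–14
  and back out by 19, so curves stay monotone and the adult plateau is
  unisex.
* **Composition.** Organ volumes are fractions of body weight summing to
  0.95; the liver and the richly perfused lump (dominated by brain) carry
  higher fractions in infancy, tapering linearly to adult values by age
  15, with the poorly perfused lump absorbing the remainder. Blood flows
  are fixed fractions of an allometric cardiac output
  `CO = 336 (W/70)^0.75 L/h` and sum to it exactly.
* **Gut geometry.** Segment lengths scale with height; radii follow a
  separate age table (infant radii ~35–45% of adult).
* **Renal maturation.** `CL_R = CL_adult (W/70)^0.75 · f(age)` with
  `f` a Hill sigmoid in postmenstrual age (hill 3.4, TM50 47.7 weeks,
  PMA = 40 + 52.14·age). This standard maturation form gives f(1 y) =
  0.90, consistent with the qualitative statement that GFR-cleared drugs
  reach >90% of adult clearance by age one.
* **Population sampling.** Exactly `round(n·prop_female)` females (round
  half up), ages uniform in the group range, heights lognormal with 10%
  CV around the age/sex median (the stated population variability), and
  weight co-varying through a constant-BMI rule
  `W = W_med (H/H_med)²`. Draws are reproducible given the seed.

## Dose finding

The adult reference window is Cmax 38–124 ng/ml, AUC(0–120) 611–1851
ng·h/ml (Tmax 5.1–7.3 h is reported but not classified on, because the
published decision rules mention only Cmax and AUC). The color rules as
printed are incomplete, so the package adopts one explicit precedence,
isolated in `classify_dose()` for easy revision: **green** if min, mean
and max of both metrics are in range; else **blue** if the AUC min and
mean are in range; else **yellow** if both minima are in range; else
**out**. The recommended range for a group is the lowest-to-highest grid
dose not labelled `out`; endpoints are restricted to grid members because
only grid doses are ever simulated.

Because the model is linear, each group's population is simulated once at
the top of its grid and per-subject Cmax/AUC are scaled exactly to the
other doses — the linearity is itself verified to 1e-6 by the property
tests, so this is an optimisation, not an approximation.

## Conventional-dose report

The four formulas return unrounded doses; the comparison report applies
the printed precision of the published table, which is not uniform:
values are truncated (not rounded) to 2 decimals below a column-specific
threshold and rounded to whole milligrams above it (10 mg for Young's
rule, 4 mg for Clark's and mg/kg scaling). The BSA column of the
published table implies an adult reference BSA of ~1.82–1.92 m²
depending on the row; the package defaults to the conventional 1.73 m²
and exposes `adult_bsa_m2` instead of guessing. The lb/kg consistency
check on dual-unit inputs tolerates 3% because published tables print
both units rounded (37 lb alongside 17 kg).

## Synthetic data

`gen_observed()` simulates each subject of a virtual population under a
known parameter set and multiplies each sample by lognormal noise with
geometric mean 1 (meanlog 0), keeping concentrations positive —
the standard residual model for concentration data. The drug's reported
inter-individual variability spans 6–60%, so the default 15% CV is
conservative. `gen_reference_observation_set()` condenses such profiles
into the same observation table the calibration consumes, enabling
round-trip tests: with zero residual noise and anthropometric variability
switched off, the staged workflow recovers the true clearance and
permeability within 2%; with 15% residual noise and 10% height
variability over 12 subjects, within 10% (sampling error of a 12-subject
mean dominates that figure). What the generator does **not** emulate:
between-occasion variability, assay quantification limits and censoring,
non-lognormal outliers, or model misspecification — recovery tests
therefore demonstrate internal consistency of the estimation machinery,
not robustness to structural error in real data.

## Numerical choices

* Integration: `deSolve::lsoda` with the constant system matrix supplied
  as an analytic Jacobian; default tolerances rtol 1e-8 / atol 1e-10
  (population screening runs use 1e-6/1e-8).
* Output grid 0.05 h; Tmax is reported at the grid point of the maximum,
  first occurrence on ties, with no interpolation — so Tmax is quantised
  to 0.05 h (hence its reduced calibration weight).
* IV bolus protocols are resolved on a 0.01 h grid wherever AUC or
  moments are computed from them: on the 0.05 h grid the trapezoid
  overestimates the area of the unresolved post-bolus distribution spike
  by ~2%, which biases moment-analysis Vss ~4% low. The Vss target uses
  a 480 h horizon so the extrapolated tail stays below 20% of AUC∞.
* AUC: linear trapezoid on the dense grid (discretisation error < 0.01%
  against an analytic exponential); AUC∞ adds `C_last/λz` with `λz` from
  a log-linear fit over the last 20% of the time span. AUC is exactly
  additive over adjacent windows; windows may end between grid points
  (linear interpolation, consistent with the trapezoid).
* Multiple doses are solver events aligned to the output grid; at a dose
  instant the reported lumen state may be pre- or post-event by solver
  convention, which the mass-balance check accommodates (plasma is
  continuous either way).
* Degenerate inputs: zero permeability is allowed (everything leaves in
  feces — a limiting-case test), zero meal leaves the model untouched,
  non-positive doses/ages/weights are rejected with domain errors.

## Problem sizes in the shipped tests

The test suite calibrates the adult model once (~20 s) and reuses it;
dose finding in the acceptance tests runs the full study design (five
groups × 100 subjects); recovery tests use 3 identical subjects
(noise-free) and 12 variable subjects (noisy), chosen to exercise the
workflow end to end while keeping the suite a few minutes long. The
acceptance script simulates the 18-subject adult oral study design for
the population metrics.

## Known limitations

* The deep compartment is a linear surrogate for saturable ACE binding;
  terminal-phase dose-dependence is outside the model.
* PEPT1 is represented as fixed regional weights, not transporter
  kinetics; ontogeny of the transporter is not modelled.
* Fasting gastric pH, dynamic gastric emptying, enterohepatic
  recirculation and preterm physiology are not modelled.
* The growth table is a median-anthropometry sketch adequate for dose
  banding, not a population growth standard.
* Ethnicity-specific physiology is not modelled; the adult reference is a
  70 kg / 170 cm male.
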