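---
title: "Comparing spirometric reference equations for COPD staging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing spirometric reference equations for COPD staging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spiroref)
```

## The problem

Whether a spirometry result is "abnormal" depends on the reference
equation it is judged against. A COPD patient's severity grade under the
GOLD system is driven by FEV1 as a percentage of *predicted* FEV1, so
switching reference equations can move patients between severity stages
even though nothing about the patient changed. spiroref implements three
prediction sources for adults and the machinery to quantify how much
staging actually moves between them:

* **study** — sex-specific equations derived from 500 healthy
  never-smoking Greek adults (18–89 years), with a piecewise-linear age
  effect knotted at 25 years;
* **ecsc** — the 1993 European Coal and Steel Community linear equations,
  the long-standing default of many European spirometers;
* **gli** — a GLI-2012-style lambda-mu-sigma (LMS) model with an
  age-indexed spline lookup, which additionally yields z-scores and the
  5th-centile lower limit of normal (LLN).

## The prediction models

**Study equations.** FEV1 (litres) is linear in height (men also carry a
height-squared term) with a piecewise-linear age effect: a `min(A, 25)`
slope for the rising limb and a `max(A − 25, 0)` slope for the decline,
each branch published with its own intercept. FVC is modelled on the
natural-log scale (`ln FVC`), with height, height squared and a negative
weight coefficient. The FEV1/FVC ratio (percent) depends on age only —
linearly for men (86.07 − 0.0707·A), with a quadratic flattening for
women (105.38 − 0.7852·A + 0.0069·A²; vertex near 57 years). Height,
weight and BMI were not significant ratio predictors.

Two coefficient variants ship: `"corrected"` (default) flips the sign of
the young-branch height-squared coefficient in the male ln(FVC) model
from +0.00041 to −0.00041 — the positive sign yields ln(FVC) ≈ 26, i.e.
an FVC of e²⁶ litres, so it can only be a sign typo — and `"as_printed"`
keeps the published text verbatim for audit. The male ln(FVC) branch
intercepts genuinely disagree at the knot by 0.066 on the ln scale
(−13.028 implied by the young branch versus −13.094 published); both are
retained without smoothing, and the refitting basis models that offset
explicitly (below).

**ECSC.** One linear equation per sex and outcome in height (metres in
the original; this package stores centimetres and converts at the call
site) and age, with ages 18–25 clamped to 25 per the source's young-adult
convention. The ratio equations use age only.

**GLI-style LMS.** `M = exp(a0 + a1 ln H + a2 ln A + Mspline(A))` is the
predicted median, `S = exp(p0 + p1 ln A + Sspline(A))` the coefficient of
variation and `L` the Box–Cox power; `z = ((y/M)^L − 1)/(L·S)` and
`LLN = M(1 + L·S·(−1.645))^{1/L}`. Spline contributions are tabulated on
an integer age grid (18–95) and linearly interpolated; no extrapolation.
The shipped lookup is **synthetic**: it preserves the genuine model
structure but its median trajectories were calibrated once to the adult
trajectories implied by the study equations, scaled by the mean offsets
between GLI and study predictions observed in the healthy cohort (about
+4% for FEV1, +8–10% for FVC, −3 to −5% for the ratio). It exercises
every code path and keeps the three sources in a realistic envelope, but
it is not the published GLI-2012 coefficient set and must not be used
clinically; users with the published tables can pass them to `gli_predict()`
via `lookup`.

## Staging and agreement

`gold_stage()` converts percent-predicted FEV1 to the GOLD ordinal
grades with half-open bands: mild ≥ 80%, moderate [50, 80), severe
[30, 50), very severe < 30%. Percent predicted is never rounded before
thresholding. An optional fixed-ratio gate (`require_obstruction`)
returns "none" when the *measured* FEV1/FVC is at least 70%; it defaults
off because cross-staged cohorts are normally already diagnosed COPD
patients, and it deliberately uses the fixed 70% cut rather than a
source-specific LLN.

Agreement between two stagings uses the 4×4 cross-tabulation:
percent agreement, and Cohen's kappa with identity, linear
(`w = 1 − |i−j|/3`) or quadratic weights. **Linear weighting is the
default**: recomputing kappa from the shipped 124-patient COPD staging
tables reproduces the published coefficients 0.936 (study vs ECSC),
0.895 (study vs GLI) and 0.862 (ECSC vs GLI) to three decimals under
linear weights, while unweighted kappa gives ≈ 0.909 for the first
table — so linear weights are the convention those coefficients were
computed under. Continuous agreement uses Lin's concordance correlation
coefficient, `ρc = 2·cov(x,y)/(var x + var y + (x̄ − ȳ)²)`, with 1/n
population moments as in the original definition (a 1/(n−1) variant is
selectable); reported differences follow the predicted-minus-measured
convention.

## Refitting the equations

`refit_study_models()` re-derives the six published model structures
from a cohort by least squares. The age basis is `min(A, 25)`,
`max(A − 25, 0)` **plus an explicit level-offset indicator `1(A ≥ 25)`**
(`knot_jump`): the published equations carry branch-specific intercepts
(the 0.066 male ln(FVC) gap, ±0.001 rounding elsewhere), and without the
offset term no continuous basis can reproduce them exactly. With it, a
noiseless cohort generated from the corrected coefficients returns all
printed coefficients to machine-level accuracy. Fits without `knot_jump`
remain continuous at the knot by construction. The design matrix is
column-equilibrated before QR factorisation (height-squared is four
orders of magnitude larger than the jump indicator) and rank deficiency
is reported by naming the collinear columns. Residual SD uses
`sqrt(RSS/(n − p))` with p counting the intercept; R² is computed on the
fitting scale (ln scale for FVC). When a sex stratum has fewer than two
distinct ages below the knot the offset (and with no young subjects at
all, the young slope) is inestimable and is dropped with a message.

The published covariate-selection path is not reproducible, so the
canonical refit fixes the published term sets. An `"exploratory"`
variant performs backward elimination by partial-F tests at 0.05 and
labels itself non-canonical; because H and H² are nearly collinear,
either may end up carrying the height effect there.

## The synthetic cohorts

`generate_healthy()` draws sex-stratified demographics from truncated
normals with the healthy cohort's published means and SDs (239 men of
500; age 46.92 (16.16) / 48.20 (17.19) years, height 175.80 (7.25) /
162.69 (7.18) cm, weight 84.90 (4.90) / 69.70 (15.92) kg; truncation at
age 18–89, height 140–205 cm, weight 40–160 kg), then sets measured
FEV1 = study equation + N(0, 0.38/0.28 L) and measured
ln FVC = study ln-model + N(0, 0.12/0.13), the published residual SDs.
The measured ratio is always derived from the volume pair; its own
residual SDs (6.82/8.45) describe the published ratio regressions, not a
third noise source. The two volume noises share a residual correlation
(default 0.7, chosen once so the derived ratio's spread lands near the
observed 7–9 percentage points — repeated indices from one test session
are strongly coupled); the marginal SDs are untouched by it.

Two validity rules operate by default. Demographics whose
*equation-implied* ratio exceeds 98% are redrawn, because the published
young-age branches make the two volume equations mutually inconsistent
in a corner of the demographic space — for women under about 21 the
implied ratio passes 100% — and no noise draw can repair that. This
rejection depends only on covariates, so it cannot bias coefficient
recovery, though it thins young-female support. Second, noise pairs
producing a row that would fail validation (FEV1 more than 2% above FVC)
are redrawn; this slightly truncates the noise distribution (in
development runs it moved the male ln(FVC) old-age slope by roughly half
a standard error at n = 500, because the printed male equations imply
ratios near 94% over much of the age range). For estimator-calibration
work, `enforce_validity = FALSE` yields the exact unfiltered generative
model, and that is the mode the package's own recovery tests use.

What the generator does *not* emulate: age–height correlation (secular
trends; drawn independently, which mostly lowers refit R² rather than
biasing coefficients), correlated repeat maneuvers, smoking exposure or
longitudinal decline. A consequence worth knowing: the printed *male*
volume equations evaluated at the cohort's mean covariates give
FEV1 3.93 L / FVC 4.01 L, while the published cohort means of the male
predictions are 3.75 / 4.52 L — the male equations and those summary
means cannot both be exact, so synthetic male cohorts have measured
ratios centred near 92 rather than 83. The female equations are
internally consistent (2.70 L FEV1 exactly; FVC within ~2%).

`generate_copd()` inverts the stager: each of 124 (by default) patients
draws a target stage from the 17:44:42:21 mix, a percent-predicted FEV1
uniformly within that stage's band (mild capped at 95%, very severe
floored at 15%), sets measured FEV1 to that fraction of the
study-predicted FEV1, and chooses FVC so the measured ratio is uniform
in [40, 69) — bracketing the cohort's observed 57.9 (10.6) while
guaranteeing the <70% diagnosis gate. Staging such a cohort with the
study source reproduces the drawn stages exactly; other sources then
disagree only through genuine prediction offsets, which is what makes
the near-diagonal cross-tabulations a meaningful end-to-end check.
COPD ages span 24–91 as in the validation cohort, so the top two years
extrapolate the study equations slightly beyond their 18–89 derivation
range.

## Numerical conventions and problem sizes

* Branch assignment: age < 25 uses the young branch, age ≥ 25 (exactly)
  the old branch. BMI is always derived, never read from a file.
* Percent predicted and kappa inputs are never pre-rounded; reports
  round to one decimal, coefficient displays to six.
* All randomness flows through explicit integer seeds; seeded generation
  restores the caller's RNG state.
* The package's own validation uses cohorts of 400–500 subjects for
  recovery studies (100 replicates at n = 500 for the noisy Monte Carlo,
  matching the healthy cohort's size) and n = 1000–1240 for staging
  pipelines; these sizes put binomial/chi-square concentration well
  inside the asserted tolerances while keeping the full suite in a few
  seconds.

## Known limitations

* The GLI lookup is a synthetic emulation (see above) — agreement
  statistics involving the `gli` source characterize the pipeline, not
  the published GLI-2012 equations.
* The study equations are printed to 3–4 significant figures; quantities
  derived from them inherit that rounding (e.g. the expected female
  ratio mean computes to 85.60 against a published 85.63).
* Between-source concordance on *measured* values requires
  individual-level data; on synthetic cohorts those statistics reflect
  the generator's assumptions, in particular the independent-demographic
  simplification.
* The fixed-ratio 70% COPD gate is implemented as published;
  LLN-based diagnosis is available through the GLI source's `lln_fev1`
  but is deliberately not wired into `gold_stage()`.
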