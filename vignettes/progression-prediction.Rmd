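---
title: "Predicting PD progression from baseline gait and balance panels: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting PD progression from baseline gait and balance panels: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitprog)
```

This vignette is the package's account of its statistical machinery: what
is modelled, which choices were genuinely open and how they were settled,
and what the synthetic cohort generator does and does not emulate.

## The question and the data model

The scientific question is whether a single session of instrumented gait
and balance testing at baseline carries information about how fast a
person with Parkinson's disease will subsequently progress. The data
model is a longitudinal cohort (`pd_cohort`): subjects examined every 6
months, with the MDS-UPDRS and medication record at every visit and
MoCA, PDQ-39 and Schwab & England (S&E) annually; and, at each visit, up
to three trials of each gait/balance test panel (iTUG: 96 parameters,
iSway version 1: 46, iSway version 2: 33). The *baseline* visit is the
first visit at which any gait or balance data exist. A subject is
analyzable with at least two clinical assessments (baseline plus one
later visit) and at least one visit with gait/balance data.

Three deliberate data-model choices:

* **Long, tidy feature storage** (`subject, month, panel, trial,
  parameter, value`): the three panels have different parameter sets, and
  a wide layout would need 96 × 3 trial columns; the long layout is the
  simplest lossless form.
* **Missing is empty.** Annual instruments are simply not administered at
  months 6 and 18; empty CSV fields map to `NA`, never to 0 or a
  sentinel, and the writer preserves that (`write_cohort` /
  `read_cohort` round-trip bit-exactly).
* **Synthetic parameter names** (`itug_p001`…): the native parameter
  names belong to the motion-analysis vendor; the pipeline needs only
  stable identifiers and counts.

## Outcomes

Progression for outcome y at horizon h is the annual rate of change
`(y(h) − y(0)) / Δt`. Two open points had to be fixed:

* **Annualization denominator.** The nominal horizon (0.5, 1, 1.5, 2
  years) is the default; `use_elapsed = TRUE` switches to the recorded
  elapsed time between the two visits. The nominal default keeps rates
  comparable across subjects whose visits drift by a few weeks.
* **The GCO reference population.** The global composite outcome
  z-scores MDS-UPDRS I–III, S&E and MoCA (signs inverted for the latter
  two, so higher is worse) against a mean and SD that must come from
  somewhere. The package uses the baseline values of the horizon group
  under analysis, applied unchanged to follow-up visits, so a change in
  GCO always reflects a change in raw scores rather than a change of
  yardstick; a pooled-cohort reference is available as
  `gco_reference = "pooled"`. Inside cross-validation the reference is
  refit *on the training fold only* — see the leakage discussion below.

LEDD uses the standard dose-conversion convention with extended-release
carbidopa/levodopa (Rytary) at 0.7 and enteral suspension (Duopa) at
0.97; the remaining factors in `ledd_conversion_factors()` are ordinary
published conversions and are user-replaceable.

Quartiles in `median_change_table()` are type-7 (linear interpolation
between order statistics) — a stated convention, since quartile
definitions differ.

## Ridge models

Each cell (panel configuration × outcome × horizon) gets its own ridge
regression, fitted by the SVD of the column-centered design: exact,
deterministic, and equal to least squares at λ = 0. The intercept is
never penalized. Features are standardized to mean 0, SD 1 *within each
training fold*; zero-variance columns are dropped there because their
z-scores are undefined (their coefficients are effectively 0 for
prediction).

The penalty λ is not a quantity the analysis is allowed to tune by hand:
it is selected by inner 5-fold cross-validation over a 50-point
log-spaced grid (`lambda_grid()`, 10⁻² to 10⁶), run inside each training
sample, with ties broken towards the larger (more conservative) penalty.
On pure-noise responses the selection lands at or near the grid maximum,
shrinking the model towards the intercept; with strong signal and n ≫ p
it picks small values.

**Covariate adjustment.** Baseline disease severity (MDS-UPDRS total),
LEDD, age, sex and disease duration can be appended as ordinary penalized
columns (`covariates = TRUE`, the default for cohort-level analyses).
How adjustment should interact with a penalized model is genuinely open
(residualizing first is the main alternative); appending them as columns
is the simplest choice that lets the model use them. Note that such
covariates legitimately predict annualized change even when the gait
features are pure noise — baseline severity correlates with subsequent
measured change through regression to the mean — so chance-level
benchmarking of the *gait features* is done with `covariates = FALSE`.

## Concordance accuracy

Goodman–Kruskal gamma over all subject pairs: γ = (C − D)/(C + D),
with pairs tied in either vector excluded from both counts (the
classical definition). Ties are not a corner case here: LEDD change is
exactly 0 for many subjects over short follow-up, and integer-valued
scores tie constantly. If *every* pair is tied, γ is undefined; a
cross-validation fold in that state is skipped and counted.

Accuracy is reported as 100·(γ+1)/2 = 100·C/(C+D), the concordance
probability among untied pairs: 50% is chance, 100% a perfect ordering.
Raw γ sits at 0 at chance, which makes an "accuracy" of 0 misleading;
the percent mapping is the only affine transform that puts chance at 50%
and perfection at 100%, and it is used everywhere in the package. This
mapping convention is flagged here prominently because other tie
treatments (splitting ties between C and D, Kendall-type corrections)
would give slightly different percentages on heavily tied outcomes.

## Cross-validation protocol

"k-fold with R replicates" is read as R independent replicates of a full
balanced k-fold partition, each yielding k train/test evaluations
(default k = 10, so 90%/10%); a Monte-Carlo alternative — one random
90/10 split per replicate — is available as `scheme = "monte-carlo"`.
Reported means and SDs are over *fold-level* evaluations, the finest
unit at which both in-sample and out-of-sample accuracies exist.

Everything fold-local is computed from training rows only: scaling
statistics, the λ selection, and (for the GCO) the z-score reference.
This is asserted by tests that replay the recorded per-fold artifacts
from the training indices alone and demand exact equality. All
randomness derives deterministically from a master seed (per-replicate
and per-fold sub-seeds), so a grid run reproduces exactly.

For desk-scale runtime the replicate default is 100 (configurable to
1,000); because the fitter evaluates the whole λ grid from one SVD per
inner fold, a 200-subject, 46-parameter cell with 20 replicates runs in
a few seconds.

## The synthetic cohort generator

`simulate_cohort()` emulates the structure of a longitudinal PD
biomarker cohort, not its biomechanics:

* **Baseline distributions** are scaled-beta draws whose shape is solved
  so the median matches the published cohort's baseline median within
  its observed range (e.g. age 65.75 in 34.75–85.58, MDS-UPDRS total
  around 36, LEDD 600, S&E 0.9, MoCA 27), then discretized to each
  instrument's grid (integers, 0.1 steps for S&E, half-points for H&Y).
* **Progression** is driven by one latent scalar rate r ~ N(0, 1)
  (z-units/year) per subject; each outcome's slope is an affine gain on
  r plus outcome-specific noise. This mirrors the premise behind a
  composite outcome — that the outcomes share a progression signal — and
  can be switched off (`correlate_outcomes = FALSE`) to stress-test it.
  Mean slopes (UPDRS total ≈ 4.8 points/year, MoCA ≈ −0.4, S&E ≈ −0.02)
  were chosen once to echo the scale of published 24-month median
  changes.
* **LEDD** moves by zero-inflated positive increments on a 25 mg grid,
  with increment probability increasing in r — reproducing the heavy
  tying at 0 that stresses the gamma tie handling.
* **Features**: each channel has a subject-level value with arbitrary
  location and scale (so standardization is genuinely exercised); the
  first `n_informative` channels per panel correlate with r at exactly
  `signal_strength` at the subject level; visit-level and trial-level
  noise are layered on top so the median-of-three-trials step does real
  work. `signal_strength = 0` makes features statistically independent
  of progression — the null model.
* **Schedule**: visits at 0/6/12/18/24 months with independent
  per-visit attrition (default 8%) and per-panel missingness (2%);
  annual instruments absent at months 6 and 18.

What it does **not** emulate: real inter-parameter correlation structure
of the sensor panels (a within-panel block-correlation option exists but
its level is the generator's invention), medication state
("on"/"off"), informative dropout, floor/ceiling pile-ups beyond simple
clamping, or non-linear trajectories. Consequently, a pipeline that
passes its tests is shown to be *correct and leak-free as software and
as a statistical procedure*; nothing about passing implies the real
cohort's features do or do not predict progression, and the flat
6-month medians seen in real short-horizon data (where measured change
is mostly noise) appear here only for LEDD, whose zero-inflation is
modelled explicitly.

## Numerical and degenerate-input conventions

* Ridge solutions come from one SVD per training design; at λ = 0 with
  rank-deficient designs the minimum-norm solution is returned
  (directions with numerically zero singular values, below 10⁻¹² of the
  largest, get zero coefficients).
* λ-selection ties go to the largest candidate.
* A GCO reference with any zero-SD component is refused
  (degenerate-reference error) rather than silently producing infinite
  z-scores.
* An all-tied pair set raises an undefined-gamma error; inside
  cross-validation that fold is skipped, counted, and reported.
* Fold sizes differ by at most one; `n ≥ k` is enforced.

## Test problem sizes

The operating-characteristic tests run at n = 200 subjects, one panel
(46 parameters), 20 replicates of 10-fold cross-validation for the
chance-level check and 5 replicates for signal recovery; distributional
calibration checks use n = 400–800 with a single baseline visit. These
sizes were chosen as the smallest at which the Monte-Carlo envelopes of
the checked quantities (for example ±2 percentage points around the 50%
chance level for the out-of-sample mean) are comfortably below the
effect being asserted. On null-signal cohorts the fold-mean converges,
as replicates grow, to a cohort-conditional value that itself scatters
around 50% by a percentage point or two across cohort draws — a
consequence of spurious in-sample correlations at p/n ≈ 0.25, not of
leakage — which is why the chance-level check fixes the cohort seed as
part of the study conditions.

## Known limitations

* The accuracy mapping and tie treatment are conventions (documented
  above); heavily tied outcomes are sensitive to them.
* Complete-case handling of missing panels/parameters; an imputation
  flag exists in the design space but is deliberately not implemented —
  complete-case is the conservative reading for baseline-only features.
* No inference on accuracies (no p-values or confidence intervals across
  cells) and no inference on ridge coefficients; the package answers an
  ordering question, not an estimation one.
* The elapsed-time option trusts the recorded `elapsed_years`; no visit
  windowing rules are applied.
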