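---
title: "Methods behind squatcrf: signal cleaning, features, models and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind squatcrf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(squatcrf)
```

## The measurement model

The squat self-test produces one beat-to-beat RR recording covering three
phases: supine rest (nominally 300 s), 30 squats in 45 s, and supine
recovery (180 s). The package treats the recording as a noisy, irregularly
sampled observation of an underlying heart-rate trajectory with a resting
plateau, an exercise rise, and an approximately exponential recovery
decay. Everything downstream — features, prediction equations, validation
statistics — operates on a cleaned 1 Hz version of that trajectory.

Assumptions worth making explicit:

* HR is the reciprocal of the RR interval (HR = 60000/RR bpm); no beat
  classification is attempted, so ectopy and sensor dropouts appear as
  amplitude spikes and are handled by the despiking rule.
* Phase markers are *inputs*. The package validates their ordering and
  warns when durations deviate more than 10% from nominal, but it does
  not detect phases from the signal.
* Prediction targets absolute V̇O2max in L·min⁻¹. Relative values
  (mL·kg⁻¹·min⁻¹) are derived only for classification and reporting.

## Signal cleaning

**Resampling.** Beatwise HR samples sit at each interval's end time;
linear interpolation maps them onto integer seconds, holding the first
and last values constant beyond the observed beats. Any input already on
the grid is reproduced exactly.

**Despiking.** For each interior sample the short-term variation (sample
SD, n−1 denominator, over the centred 3-sample window) is compared with
the long-term variation over the centred 21-sample window. Three
conventions had to be fixed where the idea leaves room:

1. *The long window excludes the 3 central samples.* If it included them,
   a single spike would inflate both SDs and the 10× criterion could
   never fire for any single artifact.
2. *The centre sample must itself be the extreme.* The short windows of a
   spike's two neighbours also contain the spike, so the ratio criterion
   fires there too; replacing those samples would corrupt clean data
   (the neighbour's replacement would average in the spike itself). The
   rule therefore fires only where the centre sample carries the largest
   absolute deviation from the long-window median within its short
   window. This pins each isolated artifact to exactly one replacement,
   which is also what makes the replacement-count bookkeeping meaningful.
3. *Zero long-term variance.* On a perfectly flat segment any short-term
   variation is an artifact; the rule fires whenever the long SD is zero
   and the short SD is not.

Replacement is the mean of the previous and following samples (nearest
non-flagged neighbours for consecutive flags; a run longer than the short
window triggers a morphology warning). The first and last 10 samples are
never evaluated — all windows of interest are interior. Window lengths
and the ratio are `run_config()` parameters; the defaults (3, 21, 10×)
are the published procedure.

The rule's reach should not be oversold: on fast transients (the squat
rise) the long-term SD is itself large, so an artifact there is
indistinguishable from physiology at any sensible ratio. The original
workflow handled those by visual inspection; the package instead reports
the replacement count per test (`n_despiked`) so unusual recordings can
be flagged.

**Smoothing.** A centred 5-sample moving average with symmetrically
shrinking edge windows. Smoothing is part of the default cleaning
(`clean_hr(smooth = TRUE)`) because real recordings carry beat-to-beat
jitter. The round-trip tests run with `smooth = FALSE`: on a noiseless
synthetic trace the filter has nothing to remove and its only measurable
effect is attenuating the squat peak (a centred mean across a local
maximum is strictly below it), which would turn an exact recovery check
into a filter-response check.

## Features

All windows are half-open `[start, end)` on the 1 Hz grid.

* **Rest HR mode** — mode over the rest phase excluding its first and
  last minute. HR is rounded to integer bpm first (the mode of a
  real-valued signal is otherwise degenerate); ties break to the smallest
  value so the statistic is order-independent and reproducible.
* **Squat peak** — maximum over the squat phase.
* **Recovery linear fit** — OLS of HR on seconds since recovery onset;
  x = 0 at the first recovery sample, so the intercept *is* the fitted
  start-of-recovery HR (start HR_rec).
* **Recovery exponential fit** — nonlinear least squares of d·e^{f·x},
  exactly two parameters, no asymptote offset (the model is implemented
  as printed; with an offset the pure-decay interpretation of d and f
  changes). Start values come from the log-linear fit;
  Levenberg–Marquardt, 200 iterations, relative tolerance 1e-8. A
  zero-variance recovery short-circuits to (mean, 0). Non-convergence is
  an error that carries the log-linear fallback.
* **RDI** — ((P1 − 70) + 2(P2 − P0))/10 with P0 = mean HR over rest
  seconds [225, 240), P1 = max HR over recovery seconds [0, 15), P2 =
  mean over recovery seconds [60, 75). "After the first minute" is read
  as [60, 75).
* **Normalised features** — start HR_rec divided by height² (m²) and by
  age² (y²). Height scaling compensates the larger mechanical work of
  taller subjects per squat; age scaling absorbs the age–fitness decline.

## Prediction models

The three published coefficient sets are hard-wired in
`builtin_model()`. Two conventions are inferred rather than stated in
the source material and are therefore worth flagging prominently:

* **Sex coding: male = 1, female = 0.** Inferred from the positive sex
  coefficients together with higher male V̇O2max in the cohort summary.
* **Height in meters for Model 2.** A coefficient of 4.533 L·min⁻¹ per
  meter is physiological; per centimeter it would not be.

Refitting uses plain OLS (`lm.fit` on an explicit design matrix).
Stepwise forward selection adds, at each step, the candidate with the
smallest partial-F p-value below `p_enter` (default 0.05, configurable —
the original entry criterion is not documented anywhere, so the
conventional threshold is used); ties keep the earlier candidate,
making selection deterministic; rank-deficient additions are skipped,
so a duplicated predictor can never enter twice.

## Validation statistics

* **LOOCV** is an explicit n-fold refit loop, not the hat-matrix
  identity. The explicit loop lets each fold fail independently with a
  named error, and its equivalence to an independent naive loop is part
  of the test suite.
* **Bland–Altman**: differences are predicted − measured; LoA = bias ±
  1.96·SD (sample SD; multiplier configurable). A proportional-bias
  check — the slope of differences regressed on pairwise means, with its
  p-value — is always reported but never used as a gate; a significantly
  negative slope is the signature of overestimating unfit subjects and
  underestimating fit ones.
* **ICC** = (MSr − MSe)/MSr, exactly as defined for the original
  analysis. Note this is *not* the Fisher consistency ICC
  (MSr − MSe)/(MSr + (k−1)MSe); the printed formula is followed. The
  default ANOVA dialect is two-way without interaction (occasion as a
  fixed effect), under which a constant shift between occasions does not
  reduce repeatability; a one-way dialect is available via
  `run_config(icc_dialect = "oneway")`.
* **Classification**: RDI bands good ≤ 5, poor ≥ 11, fair otherwise —
  the published integer bands leave (5,6) and (10,11) unassigned, and
  assigning them to fair keeps the three bands exhaustive for continuous
  scores. Norms-based classification converts to mL·kg⁻¹·min⁻¹ and looks
  up a user-supplied sex × age-band table with half-open bands (a value
  at a threshold takes the upper class). No reference norms ship with
  the package: the established tables are copyrighted, so tests and
  examples use a clearly labelled synthetic table
  (`inst/extdata/synthetic_norms_3class.csv`).
* **Agreement counts** follow the study's operating definitions on the
  ordered scale poor < fair < good: matches on good/fair are true
  positives, matches on poor true negatives, underestimates false
  negatives, overestimates false positives — the four counts partition
  all pairs. κ is computed on the full 3×3 table; the two-category miss
  rate counts poor↔good confusions.
* **Stability simulation**: for each training size, 100 iterations
  (default) of: draw a disjoint 10% test subset, draw the training
  subset, fit, score RMSE; then average. Training sizes below the
  coefficient count, and degenerate draws (e.g. single-sex training
  sets with a sex term), contribute nothing rather than erroring.

## The synthetic generators

`generate_cohort()` emulates the validation cohort's *marginal*
structure: sex by a 63/81 Bernoulli draw; per-sex age, height and weight
from truncated normals with the cohort's means, SDs and observed ranges
(truncation uses the inverse-CDF, so draws are exact and reproducible);
start HR_rec and RDI from a bivariate normal; V̇O2max from a chosen
published equation plus Gaussian residuals defaulting to that model's
published RMSE. Two feature parameters are the package's own choices,
made once: start HR_rec ~ N(110, 15) bpm (plausible for a population
whose rest HR is 67 ± 11 and whose squat peak is near 128 bpm) and a
start HR_rec–RDI correlation of 0.6 (both features are driven by
recovery HR, so independence would be unrealistic for classification
tests). RDI ~ N(8, 3). Note that the mean of a truncated normal is not
the untruncated mean — the generator's age distribution, truncated at
(18, 67) around 29, has expectation near 30.3 — and the tests check
against the closed-form truncated means, not the nominal ones.

`generate_trace()` builds a continuous HR curve (plateau; saturating
exponential rise with a 20 s time constant, normalised to reach the
configured peak exactly at the end of the squat phase; exponential
recovery) and inverts it into RR intervals beat by beat, evaluating the
curve at each accumulated beat time and rounding intervals to 1 ms. By
default the recovery decay starts at the squat peak, making the curve
continuous at recovery onset; with a lower `recovery_d` the grid sample
at the boundary interpolates across the jump and the measured P1 depends
on beat alignment relative to the grid. Artifact beats are injected at
seeded positions in the rest plateau, pairwise ≥ 21 s apart — the
despiking rule can only separate artifact from physiology on
quasi-stationary segments (see above), so placing them on the squat rise
would test the impossible.

What passing the synthetic suite does **not** show: the generators use
white jitter and exact exponential recoveries, so they say nothing about
HRV structure, breathing modulation, ectopy bursts, posture transients,
or the joint distribution of demographics and fitness in a real
population. Coefficient-recovery results show the estimation machinery
is unbiased under the stated model, not that the published equations
transfer to a new cohort.

## Numerical and design choices, collected

* Sample SD (n−1) throughout; half-open windows; 0-based grid seconds.
* HR samples sit at the interval's *end* beat time.
* Exponential fit: Levenberg–Marquardt, log-linear start, 200-iteration
  cap, ftol 1e-8.
* Stepwise: partial-F entry at 0.05, candidate-order tie-break.
* All randomness flows through isolated RNG streams derived from
  explicit seeds; no function disturbs the caller's `.Random.seed`, and
  every generator is bit-reproducible from (config, seed).
* Problem sizes used by the test and acceptance runs, chosen to make the
  statistical checks sharp while keeping a full run interactive:
  coefficient recovery on 5000-subject cohorts (sampling error ≈ 1/70 of
  the feature SD scale, small enough to resolve 3-standard-error bands);
  LOOCV calibration as the mean over 50 cohorts of 81 (the original
  cohort's size); despiking and round-trip properties on full 525 s
  traces.

## Known limitations

* The despiking convention (centre-extreme condition, edge skipping) is
  one reasonable reading of an under-specified procedure; other readings
  replace different sample sets on the same recording.
* Only the features defined above are extracted; the original feature
  inventory was larger but is not enumerated anywhere, so the remainder
  cannot be reproduced.
* The exponential recovery model has no asymptote, so d·e^{f·x} decays
  to zero; over 180 s this is harmless, but the fitted f should not be
  extrapolated.
* Phase markers must be supplied; there is no automatic squat detection.
* Classification quality against real norms depends entirely on the
  norms table the user supplies.
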