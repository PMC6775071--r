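---
title: "Point-wise functional inference for crossover actigraphy: models, choices and limits"
author: "CircadianFLM package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Point-wise functional inference for crossover actigraphy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CircadianFLM)
```

## The problem

Accelerometers worn by trial subjects produce one activity count per
minute for weeks. The traditional analysis collapses each night (or
day) to a single mean and feeds it to a mixed model; a treatment that
*redistributes* activity across clock time — suppressing a few restless
bouts here, adding a little morning activity there — can leave those
means untouched and go undetected, even while caregivers report a clear
change. Functional data analysis keeps the within-day resolution:
each subject-condition record becomes a smooth function of clock time,
and inference is made point-wise along the 24-hour clock.

This package implements that comparison for a two-period crossover
(each subject receives both conditions, separated by a washout), with
the crossover's natural exchangeable unit — the subject — driving the
permutation scheme.

## The functional model

### From epochs to curves

Minute epochs are classified night/day from caregiver diaries
(half-open `[bed, rise)` on the circular clock), labeled with their
condition through the design calendar, and collapsed onto a clock grid
of `G` cells (`gridSize`, default 144 cells of 10 min; any divisor of
1440 works). For the default paired analysis each subject contributes
one profile per condition: the cell-wise mean over that subject's
~14 days in the condition. Averaging days before smoothing treats the
subject-condition curve as the analysis unit, which is what the paired
permutation scheme requires; an all-days `per_day` aggregation is
available for unpaired exploration.

Each profile is then smoothed:

* transform: `log1p` by default. Counts are strongly right-skewed and
  heteroscedastic (variance grows with the mean); the log1p transform
  stabilizes variance while keeping zeros finite. `none` is available.
* basis: cyclic cubic B-splines, dimension `nBasis = 24`
  (one knot per hour on average), fitted by penalized least squares
  with the roughness penalty chosen by generalized cross-validation
  per curve (`mgcv`, `bs = "cc"`). Clock time is periodic, so the
  basis enforces continuity of the curve and its derivative at
  midnight. A fixed smoothing parameter can be supplied to bypass GCV.

### The point-wise permutation F-test

At each grid point the two condition groups of curve evaluations give
the one-way ANOVA statistic

$$F(t) = \frac{\mathrm{SS}_{between}(t) / (k-1)}
             {\mathrm{SS}_{within}(t) / (N-k)},\qquad k = 2 .$$

Significance is calibrated by permutation. Under the paired scheme the
drug/placebo labels are swapped independently within each subject
(2^n equally likely assignments under the null of no treatment
effect); `nPerm = 500` assignments are sampled by default, and for
small cohorts the full enumeration is available (`exact = TRUE`). The
unpaired scheme (a plain label shuffle preserving group sizes) is
provided for comparison but ignores the pairing and is not the
default.

Decisions fixed in the implementation:

* p-value counting: `p(t)` is the proportion of permutation F values
  **strictly larger** than the observed F — so p-values live on the
  grid `{0, 1/nPerm, ..., 1}` and a curve separated from its entire
  permutation ensemble reports p = 0. The more conservative
  `(1+b)/(1+n)` convention is a flag (`pRule = "plusone"`).
* critical curve: the nearest-rank empirical `(1-alpha)` quantile of
  the permutation F values at each point; a grid point is significant
  iff the observed F is **strictly** above it. With `nPerm = 500` and
  `alpha = 0.05` that is the 475th order statistic, giving point-wise
  type-I error ≈ 26/501 ≈ 0.052 — the small positive bias of sampling
  permutations with replacement.
* degenerate points: zero within-group variance with non-zero
  between-group variance yields an `Inf` sentinel (always significant);
  zero in both yields F = 0.
* intervals: maximal runs of significant points, merged across the
  midnight wrap, reported as half-open clock intervals with the
  direction (which condition's mean curve is higher) and an optional
  minimum length filter for reporting.

A computational note: within-pair label swaps leave the pooled total
sum of squares at each grid point unchanged, so the permutation F
ensemble reduces to one matrix product over signed paired differences.
This fast path is verified against explicit relabeling in the test
suite, and the observed F always goes through the general two-group
computation.

## The comparison arms

**Summary mixed model.** Per subject-date-segment mean counts (night
rows keyed and conditioned by their evening-onset date) are
log1p-transformed and z-scored, and modeled with fixed effects age,
weight, sex, baseline CBPI pain sub-score, weekend and treatment
(continuous covariates z-scored) plus a subject random intercept
(REML; Wald z-tests). "Model-averaged coefficients" follow the
standard information-theoretic recipe: all 64 subsets of the six fixed
effects are fitted by ML, weighted by AICc, and averaged with zero
substitution (a term absent from a model contributes 0) with
unconditional standard errors combining within-model variance and
between-model spread. The averaging machinery is implemented in the
package and validated against its defining identities in the tests.
No slope random effects are fitted: the design gives ~28
condition-nights per subject but only 15 subjects, and the averaging
procedure needs a common random structure across all 64 candidates.

**Questionnaire change scores.** Assessments on days 0 / 14 / 21 / 28 /
35 are mapped to conditions through each subject's randomized sequence;
end-of-period scores minus baseline give three contrasts per measure
(6 items, 5-item and 6-item totals), tested with two-sided matched-pairs
t-tests. The multiplicity threshold 0.016 (≈ 0.05/3, one per contrast
family) is applied as a strict inequality: p = 0.016 is *not*
significant. Days 21 and 28 are ingested but unused in contrasts.
Degenerate difference vectors are handled explicitly (all-zero → t = 0,
p = 1; zero variance with non-zero mean → p = 0 sentinel with warning).

## The synthetic cohort

The generator emulates the study conditions the analysis is designed
for, and its defaults *are* those conditions:

| quantity | default | note |
|---|---|---|
| cohort | 15 dogs, 10 F / 5 M | age 10.29 ± 2.48 y, weight 31.53 ± 5.39 kg, CBPI 3.85 ± 1.5 |
| design | 2 × 14 d periods, 7 d washout | balanced randomized sequence, trial starts on a Monday |
| counts | negative binomial, log link | dispersion 12: variance ≈ 3× mean at the mesor (~25 counts/min) |
| circadian mean | two-harmonic cosinor | 24 h amplitude 1.6 (peak 14:30), 12 h amplitude 0.35; night trough ~5, afternoon peak ~120 counts/min |
| subject effect | log-normal intercept, SD 0.3 | between-dog activity level |
| weekend | ×1.2 on Sat/Sun dates | caregivers at home → more activity |
| diary | bed 23:00 ± 30 min, rise 06:30 ± 30 min | truncated at ±2 h, drawn per night |
| drug effect | 23:00–06:00 ×0.5; 07:00–12:00 ×1.3 | the qualitative treatment signature: calmer nights, livelier mornings |
| questionnaire | 6 items, integer 0–10 | drug shifts peak on the twitching/dreaming items |

Choices worth flagging:

* **Negative binomial, not Poisson**: real activity counts are plainly
  overdispersed. The single dispersion parameter makes the
  variance-to-mean ratio intensity-dependent; 12 was set so the ratio
  is ≈ 3 at the mesor.
* **Two harmonics** are the smallest cosinor family giving a realistic
  unimodal day / trough night with an asymmetric plateau.
* **Windows are circular**: a night window crossing midnight is one
  window with wraparound semantics (`start > end`), and window
  multipliers apply under the drug condition only. An optional ramp
  (`doseRamp`) decays the multiplier toward 1 in the hour before
  18:00 dosing to emulate end-of-dosing-interval decay; off by default.
* **Weekend semantics**: the generator raises activity on Saturday and
  Sunday *calendar dates*; the classifier's weekend covariate flags
  Friday/Saturday *night onsets* for night rows and Saturday/Sunday
  dates for day rows. These deliberately differ — the process operates
  on physical days, the model covariate follows the convention that a
  Friday-night sleep belongs to the weekend.
* **The questionnaire response scale is an assumption** (integer 0–10
  per item): the instrument's published description does not state it.
  Shift recovery is unaffected because rounding is unbiased once the
  noise SD is a half-point or more.

What the generator does **not** emulate — and what passing tests
therefore cannot show about real data: accelerometer hardware effects
(axis saturation, placement), wear-time gaps and nonwear artifacts,
owner noncompliance with dosing or diaries, pharmacokinetics (a real
drug effect is not a square window), day-to-day serial correlation
beyond the shared subject intercept, and seasonal or weather-driven
trends. Simulation results validate the *machinery* — calibration,
recovery, localization — not the biology.

## Validation performed by the test suite

All of the following are computed, not quoted, by
`tests/testthat/test-acceptance.R`:

* **Type-I calibration**: 200 null crossover trials (all multipliers
  1); the mean fraction of significant grid points must match the
  nominal 0.05 within 3 Monte-Carlo SEs.
* **Permutation oracle**: for 4 subjects, the sampled (without
  replacement) and exhaustively enumerated permutation distributions
  are identical at every grid point.
* **F oracle**: the point-wise F agrees with a scalar one-way ANOVA to
  10⁻¹⁰ relative tolerance on random instances.
* **Recovery**: with the default injected windows, the median Jaccard
  overlap between detected (≥ 60 min) and injected windows over 50
  seeds must reach 0.6, with directions matching. The 60-minute
  reporting filter discards chance islands smaller than the smoother's
  own resolution.
* **The central contrast**: a night-internal redistribution
  (01:00–03:00 ×0.45 balanced by a compensating 03:00–05:00 increase
  computed from the model's own mean function, so the expected night
  mean is unchanged) must be flagged by the functional arm in > 80% of
  replicates while the summary model's treatment term rejects in
  < 20%.
* **Summary-arm sanity**: weekend multiplier 1.2 with no treatment
  effect → the averaged weekend coefficient positive and significant
  in > 80% of replicates, treatment rejections at the nominal level.
* Closed-form paired-t agreement and the I/O, partition and re-binning
  invariants.

Problem sizes (200 / 50 / 100 / 50 replicates, grid 144, 500
permutations) are the package's chosen validation scale: large enough
that Monte-Carlo error is well below every margin being tested.

## Numerical and degenerate-input conventions

* Timestamps are naive local clock time (stored as UTC); the intended
  use is a single-site trial, so no timezone or DST arithmetic exists
  anywhere.
* A diary bed time at or after 12:00 belongs to the onset date's
  evening; an earlier one is an after-midnight bedtime on the next
  calendar day. The rise is the first occurrence of its clock time
  after bed; equal bed and rise times are rejected as ambiguous.
  Nights missing from a diary fall back to a fixed 00:00–05:00 window
  (the fixed-night convention used before diary-based
  classification).
* Grid cells with no observed minutes are missing (`NA`), excluded
  from smoothing fits; a profile with more than 20% missing cells is
  dropped (configurable). Re-binning weights cells by member minutes,
  which is what makes it commute exactly with profile building.
* Ties at the critical quantile: nearest-rank, with strict exceedance
  for significance — a tie with the critical value is not significant.
* One master seed drives the pipeline; per-stage sub-seeds are derived
  with a fixed affine map so arms can be re-run independently yet
  reproducibly.

## Known limitations

* The point-wise test controls error per grid point, not family-wise
  over the curve; short significant islands at chance level are
  expected at rate alpha and should be read accordingly (or filtered
  by the interval length argument). Global band or max-statistic tests
  are deliberately out of scope.
* Spline smoothing blurs sharp effect edges by roughly the basis
  resolution (~1 h at `nBasis = 24`), so detected intervals
  systematically overshoot sharp injected windows at both ends; with
  very powerful designs adjacent effect windows can merge into one
  interval whose net direction is then dominated by the larger effect.
* The paired scheme requires exactly one curve per subject and
  condition; subjects missing a condition must be dropped before
  testing.
* Model-averaged inference uses Wald z statistics on the averaged
  scale; with 15 subjects these are approximations, which is part of
  why the summary arm is the *comparison*, not the recommendation.
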