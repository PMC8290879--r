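---
title: "Stride-level predictors of step length asymmetry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stride-level predictors of step length asymmetry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stridesla)
```

## The scientific question

Step length asymmetry (SLA) — the difference between non-paretic and paretic
step lengths, `SLA = SL_NP - SL_P` in millimetres — is a standard summary of
hemiparetic gait after stroke. Most of what is known about its biomechanical
correlates comes from *between-subjects* analyses: each participant is reduced
to a stride average, and averages are regressed across people. But a
rehabilitation target must act *within* a person. This package implements a
stride-by-stride analysis that asks which of 40 biomechanical variables (20
per limb: temporal, kinematic-peak, ground-kinetic and joint-moment features)
covary with the magnitude of SLA from one stride to the next, and whether
those within-subjects predictors coincide with the between-subjects ones.
Because asymmetry direction is heterogeneous — some people take longer paretic
steps, others shorter — all analyses are run separately per direction group.

## Signal-level extraction

Marker trajectories (10 markers: bilateral 5th metatarsophalangeal joint,
lateral malleolus, lateral tibial condyle, greater trochanter, iliac crest;
100 Hz) are smoothed with a zero-phase Butterworth low-pass filter with an
effective order of 4 (designed at order 2 and applied forward and backward)
and a 10 Hz cutoff. The zero-phase (two-pass) interpretation matters: a causal
fourth-order filter would delay the signal and bias every event time. Gait
events come from the fore-aft excursion of each lateral malleolus in the
treadmill frame: initial contact (IC) at the peak anterior excursion, foot-off
(FO) at the peak posterior excursion, with peaks closer than 0.4 s suppressed
(keeping the larger excursion) and a strict IC-FO alternation enforced.

Step length of a limb is the fore-aft malleolus separation at that limb's IC;
stance is IC to FO, swing FO to the next IC, and double-support time of a limb
runs from contralateral IC to ipsilateral FO. Sagittal joint angles use the
standard link-segment conventions (foot: MTP5 to malleolus; shank: malleolus
to tibial condyle; thigh: condyle to trochanter; pelvis: trochanter to iliac
crest), with the ankle offset by 90 degrees so anatomical neutral is zero and
dorsiflexion, knee flexion and hip flexion positive. Ground reaction forces
(1000 Hz per belt) are zero-phase filtered at 100 Hz; samples under 20 N of
vertical load are treated as unloaded (a common force-plate zeroing threshold;
the convention is configurable). Braking and propulsive impulses are
trapezoidal integrals of the negative and positive fore-aft force over a gait
cycle, divided by body mass.

Joint moments come from planar (sagittal) bottom-up Newton-Euler inverse
dynamics: segment masses, centre-of-mass locations and radii of gyration are
proportional-anthropometry values (Winter's classical table, shipped as a
swappable data frame), accelerations are central differences of the filtered
kinematics, and the recursion runs foot to shank to thigh with the ground
reaction force applied at the centre of pressure. Moments are internal,
extensor/plantarflexor positive, and normalized by body mass. Per-stride
features take the extremum over the full gait cycle in each anatomical
direction: raw extrema for angles, direction-wise magnitudes (clamped at
zero) for moments — the magnitude reading matches how peak moments are
conventionally reported.

Per participant, 50 consecutive strides centred on the halfway stride are
retained (25 before and 25 from the midpoint on; the window is shifted with a
warning if a short synthetic trial cannot flank the midpoint). A Student-t
95% interval on the per-stride SLA mean assigns each participant to the
longer-paretic (interval below zero) or shorter-paretic (above zero) group;
an interval spanning zero excludes the participant. Within a retained
participant, strides whose SLA sign opposes the group are dropped, and the
response for all modelling is the magnitude `|SLA|` in millimetres. The
t-based interval is a documented choice — the alternative normal interval is
indistinguishable at 50 strides.

## The multilevel sparse PLS model

Pooling strides across participants gives a matrix with one row per stride:
the response `|SLA|` (mm, never z-scored, so coefficients keep units of mm
per predictor SD) and 40 predictors z-scored across all rows of the group.
Because participants differ in overall asymmetry, each variable is split into
its participant mean and the within-participant deviation
(`X = X_within + X_between`, exactly); components are extracted from the
within part, which plays the role of a random intercept.

Sparse partial least squares regression (sPLS) with a univariate response is
a sparse NIPALS iteration. For component *k*, the raw loading is proportional
to the covariance of the deflated predictors with the response; it is
soft-thresholded at the `(keepX+1)`-largest magnitude so exactly `keepX`
loadings survive (ties broken toward the lower column index), renormalized,
and the score `t_k = X_k w_k` extracted. Predictors are deflated by their
regression on the score and the response by its fitted part — the standard
regression-mode deflation. Response-scale coefficients accumulate as
`beta = W (P'W)^{-1} d`, so with `keepX = p` and `K` equal to the predictor
rank the fit reproduces ordinary least squares; this algebraic limit, the
top-`k` selection property of a single component, and score orthogonality are
all enforced by tests against independent oracles (and cross-checked against
the mixOmics implementation on a small instance).

The variance accounted for (VAF) by component *k* is reported as
`d_k^2 ||t_k||^2 / ||y - ybar||^2`, the fraction of *response* variance. An
alternative reading — fraction of predictor variance — is implemented behind
the `denominator` switch of `vaf_per_component()`; the response reading is
the package default because the VAF is quoted for predictors *of* `|SLA|`.
The response is within-centred along with the predictors before component
extraction; the between-participant part of the response is carried by the
random intercept of the validation model, not by the sPLS fit.

## Model-size selection

Two free parameters — the number of components `K` and the per-component
sparsity `keepX` — are chosen by an exhaustive grid search (10 x 10 for the
stride-level analysis; 5 x 5 for the participant-average analysis, where only
a handful of rows exist and a larger grid invites overfitting) under
leave-one-out cross-validation. Each fold refits *everything*: the predictor
scaling, the within-participant split (the held-out row is centred with its
participant's training-fold mean, so the fold never sees the held-out value)
and the sparse fit. The mean squared prediction error (MSPE) and its standard
error come from the N per-observation squared errors. Selection follows the
one-standard-error rule: among all cells whose MSPE is within one SE of the
minimum, take the one whose full-data refit uses the fewest *distinct*
predictors; ties fall to fewer components, then lower MSPE. Cells requesting
more components than the data can support are recorded with infinite MSPE and
skipped. Cross-validation is observation-level (stride-level), exactly as the
protocol prescribes; participant-level folds would test a different
generalization claim and are deliberately not the default.

Because fits for `K = 1..maxK` share one component path, each fold costs one
path per `keepX` value rather than one fit per cell; the fold loop runs in
compiled code (RcppArmadillo), with a plain-R reference implementation kept
in the package and equality between the two asserted in the tests.

A property of this rule worth knowing when interpreting selections: with
N ~ 550 strides the SE of the MSPE is roughly `sqrt(2)*sigma^2/sqrt(N)`, so
any predictor whose squared effect (in mm per SD, against the residual
variance) is smaller than that SE can be trimmed by the sparsity preference
even when it is genuinely nonzero. On the synthetic reference scenario below,
the minimum-MSPE cell is the designed five-predictor, one-per-component
model, while the one-SE step usually trims the weakest (4 mm/SD) effect to a
four-predictor model.

## Validation with a random-intercept mixed model

When each selected component carries a single distinct predictor, the sPLS
fit spans the same space as a linear regression on the selected predictors;
with within-centred predictors, the mixed model
`|SLA| = b0 + X b + u_subject + e` fitted by REML reproduces those
coefficients exactly (a tested identity). The mixed model is what supplies
the inferential summaries the sPLS fit lacks: Wald 95% confidence intervals
and normal-theory p-values for fixed effects (the CI method is a documented
choice), BLUP random intercepts with conditional-SD intervals, and variance
explained as `r2_marginal = var(Xb) / (var(Xb) + tau^2 + sigma^2)` and
`r2_conditional = (var(Xb) + tau^2) / (...)` — the fitted-values-variance
(Nakagawa-style) formulation. Whether individual differences carry the random
intercept is probed by an ordinary regression of the BLUPs on walking speed
and the lower-extremity Fugl-Meyer score, with the overall F test.

For the participant-average (between-subjects) analysis, confidence intervals
for the sPLS coefficients come from a percentile bootstrap over participants
(default 1000 resamples; the source protocol's printed count is
typographically ambiguous between 1,000 and 10,000, and 1000 is comfortably
sufficient for percentile intervals at this scale — the count is
configurable). Each resample refits the z-scoring; coefficients are mapped
back to full-sample SD units so resamples are comparable, which also makes
the bootstrap exactly degenerate (zero-width intervals) for a noiseless
linear relation, a useful self-check. Resamples in which a predictor
collapses to zero variance are skipped and counted; more than 20% of them
aborts the bootstrap as unstable. For each predictor selected by the
within-subjects analysis, the report also fits the univariate
participant-average regression and flags sign reversals — the
Simpson's-paradox pattern in which between-subjects and within-subjects
relationships disagree.

## What the synthetic generators do and do not emulate

The **signal-level generator** produces marker and force time series whose
ground truth is exact by construction, not a physics simulation. Malleolus
fore-aft tracks are phase-warped cosines (a monotone C1 Hermite phase through
the event knots, giving a C2 track) whose extrema fall exactly on prescribed
frame-aligned IC/FO times; a shared excursion and a per-side fore-aft offset
are solved so the prescribed step lengths hold exactly at each IC. The
remaining markers follow a planar chain with prescribed sinusoidal ankle and
knee waveforms (hip follows analytically); vertical GRF is a double-bump
profile scaled to a prescribed peak, the fore-aft GRF a braking-then-propulsion
wave with closed-form impulses. Defaults describe a slow hemiparetic treadmill
walker: 1.2 s stride period, 62% stance, 12% double support, 520/440 mm
paretic/non-paretic step lengths (SLA = -80 mm), 1.1 body-weight vertical
peaks, 0.5 mm marker noise. What it does *not* emulate: realistic pathological
waveform shapes, stride-to-stride spatiotemporal variability, soft-tissue
artefact, or dynamically consistent forces — so passing extraction tests shows
the *code* recovers what the signals contain, not that the pipeline is robust
to every feature of real data.

The **feature-level generator** draws the 40 predictors from a standard
Gaussian with block-exchangeable correlation 0.4 inside the paretic and
non-paretic blocks (gait variables are correlated; 0.4 keeps designs
well-conditioned) and builds the response as
`|SLA|_ij = b0 + sum_k beta_k x_ijk + b_i + e_ij`, floored at 0 mm (the
response is a magnitude; the default intercept of 140 mm keeps flooring below
1% of strides). The default benchmark uses 12 participants x 50 strides,
three true predictors with effects {-32, +22, -17} mm/SD, intercept SD 30 mm
and residual SD 20 mm. Two scenario configurations mirror published findings
structurally: their supports, signs and coefficient magnitudes follow the
reported fixed effects, and their intercept/residual variances are *solved*
so the generative marginal/conditional R-squared equal 0.59/0.84
(longer-paretic, 11 participants) and 0.19/0.77 (shorter-paretic, 8
participants). These are design targets, not re-estimates of the original
data. A separate sign-reversal construction gives one predictor a negative
within-subject slope (-9 mm per unit) and a positive between-subject slope
(+32) via participant-level predictor means that feed the intercept.

## Numerical choices and degenerate inputs

* Filtering subtracts the mean and reflection-pads before the two passes, so
  constants are returned exactly and edge transients are suppressed.
* Marker gaps up to 10 frames are bridged linearly; longer gaps, or gaps
  touching the record ends, are errors naming the channel and span.
* Ties at the soft-threshold boundary zero both competitors; the
  implementation then falls back to hard selection of the lower column index,
  keeping selection deterministic.
* Saturated component paths (rank exhausted before the requested `K`) carry
  the last coefficient vector forward for prediction, while grid cells whose
  full-data refit cannot reach `K` are marked infeasible.
* Zero-variance predictors raise an error naming the columns; in
  cross-validation folds a zero training SD falls back to unit scale (the
  fixtures avoid this; real 50-stride data make it vanishingly unlikely).
* All randomness (generators, bootstrap) is seed-scoped and restores the
  caller's RNG state; identical configurations and seeds are bit-reproducible.

Test problem sizes were chosen to exercise the study-scale configurations
directly (550-stride grids, 50-replicate recovery benchmarks, 200-replicate
coverage checks) while keeping the default suite in the minutes range.

## Known limitations

* Stride-level LOOCV shares participants between training and test folds; its
  MSPE measures within-protocol prediction, not transfer to new participants.
* The inverse dynamics is planar; frontal/transverse moments, joint powers
  and centre-of-mass mechanics are out of scope.
* Peak features are extrema over the whole gait cycle, not within functional
  sub-phases.
* The one-SE rule deliberately trades small true effects for sparsity at
  moderate N (see above); report readers should inspect the full candidate
  set (`selection$candidates`) alongside the chosen cell.
* Percentile bootstrap intervals from 8-11 participants are honest about
  instability (degenerate-resample accounting) but remain small-sample
  intervals.
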