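---
title: "Regression-standardized cervical intervertebral motion metrics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regression-standardized cervical intervertebral motion metrics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivmetrics)
```

## The measurement model

All metrics derive from four corner landmarks per vertebral body (C2–C7) on
paired flexion and extension radiographs, in image coordinates (x right,
y down, pixels of unknown magnification). Corner labels carry the anatomy;
a `facing` flag records which screen direction is anterior, and every
signed angle is oriented so that anterior disc opening (extension) is
positive. Every primary metric is either an angle or a length normalized by
an endplate width, so all outputs are invariant under similarity transforms
(rotation, translation, uniform magnification) of either radiograph — the
property that makes uncalibrated radiographs usable.

Per motion segment:

- *Disc angle*: signed angle between the inferior endplate of the superior
  vertebra and the superior endplate of the inferior vertebra.
  *Intervertebral rotation* is the extension-minus-flexion difference of
  disc angles, so normal full-effort motion is a positive number of the
  same magnitude as published reference tables. (The opposite sign
  convention is sometimes written; we report ext − flex throughout.)
- *Translation*: the extension pose of the inferior vertebra is registered
  onto its flexion pose by least-squares similarity (rotation + uniform
  scale + translation, solved in closed form via complex linear least
  squares — scale is included because the two films may differ in
  magnification). The registered displacement of the superior vertebra's
  posterior-inferior corner is projected onto the flexion inferior
  vertebra's superior endplate direction and divided by that endplate's
  width (% EPW, anterior positive). Millimetre values use assigned
  per-level average endplate widths (defaults 14.9, 14.9, 14.9, 15.8,
  16.7 mm for C2–C3 … C6–C7, user-overridable).
- *Disc heights*: corner-to-corner Euclidean distances (anterior-inferior
  corner of the superior vertebra to anterior-superior corner of the
  inferior vertebra, and the posterior analogue), in % EPW. Schematic
  illustrations of these measurements admit either a corner-to-corner or a
  perpendicular-to-endplate construction; corner-to-corner is
  landmark-native, parameter-free and reproducible, so it is used here.
- *Segment angle* (AMA convention): inferior endplate vs inferior endplate.
  Adjacent-level difference statistics are the maximum absolute difference
  against available neighbors; rotation differences use flexion–extension
  rotations, segment-angle differences use the flexion radiograph only.
  A level with no measurable neighbor has an undefined (absent)
  difference, not zero.
- *Total C2–C7 rotation* is computed as the relative orientation change of
  C2 with respect to C7 between phases (from the similarity registration of
  each vertebra's own corners), which equals the sum of the five segmental
  rotations for rigid bodies but remains available when intermediate
  levels are missing. Segmental shares (%C2C7) divide by this total.

Missing data are handled per level: a segment is computed iff both of its
vertebrae are visible in both phases.

## The normative reference and the instability indices

Reference fitting first excludes segments rotating less than 5° (too little
motion to engage the discoligamentous restraints; the boundary value 5.0°
is kept since the exclusion is "< 5°") and, when Kellgren–Lawrence grades
are supplied, segments graded ≥ 2 (the "definite degeneration" cutoff is
configurable; the published analyses do not print theirs). It then stores:

- per-level mean, SD (n − 1 denominator; standard for reference cohorts)
  and upper 95 % reference limit `mean + 1.96·SD` for rotation,
  translation (%EPW, mm), the two difference statistics and %C2C7;
- per-level ordinary least-squares regressions of translation on rotation
  (RDT; slopes differ across levels);
- pooled regressions of the anterior opening `ADH_ext − ADH_flex` and the
  posterior opening `PDH_flex − PDH_ext` on rotation (RDDW; slopes are
  near-identical across levels so one relation per side is fitted on all
  levels combined);
- per-level average disc-height reference (mean, SD) for the standardized
  disc height;
- total C2–C7 rotation statistics and the abnormality thresholds.

Each regression stores n, x̄, Sxx and the residual SD so the standard error
of the forecast is available in closed form:

$$\mathrm{SEF}(x_0) = s\sqrt{1 + \tfrac1n + \tfrac{(x_0-\bar x)^2}{S_{xx}}}$$

SEF is used instead of a single SD because it is a point-specific estimate
of variability at a given rotation; it exceeds the residual SD everywhere
and is minimal at x̄. (The original workflow approximated variability
bounds as a quadratic in a commercial statistics package; the closed form
is the exact equivalent for simple regression — quadratic in $x_0$ under
the square root — and is reproducible without that package.)

The indices standardize observed-minus-predicted by SEF:
`TI` for translation against the level's RDT model, `AVI`/`PVI` for the
anterior/posterior openings against the pooled RDDW models, and `SDH` is
the z-score of average disc height. Values in [−2, +2] are within normal
limits; on a cohort drawn from the fitted model each index is approximately
standard normal, so slightly more than 95 % of normal segments fall within
the limits (the calibration asserted by the acceptance suite).

Abnormality flags use strict inequalities — `TI > 2`, `AVI > 2`, `PVI > 2`,
`SDH < −2`, rotation difference `> 11°`, flexion segment-angle difference
`> 11°`, `|translation| > 20 %EPW` — so boundary values are normal. The
translation criterion uses the absolute value (anterolisthesis or
retrolisthesis; the guidelines are silent on sign). The legacy `> 3.5 mm`
criterion is implemented but disabled by default: it presumes ~30 %
radiographic magnification that magnification-free measurements do not
have. Prevalence tables count segments (not exams) in their denominators,
exclude unscored segments, and use per-criterion denominators so that a
missing neighbor does not deflate an unrelated estimate. The exam-level
effort filter keeps exams with total C2–C7 rotation strictly above 60°
(about one SD below the asymptomatic mean); exams without a measurable
total are dropped while the filter is active, since their effort cannot be
verified.

## ROC analysis

`rocCurve()` enumerates cutoffs at midpoints between consecutive distinct
values plus infinite sentinels, classifies strictly (`value > threshold`
positive, mirroring the strict scoring criteria) and integrates the curve
trapezoidally, which equals the pairwise concordance statistic with ties
counted one half. Youden's J = sensitivity + specificity − 1 is maximized
over all cutoffs; ties are broken toward the most sensitive cutoff
(screening intent). Stage labels can be pooled against intact or analyzed
stage-by-stage.

## What the synthetic generator emulates — and what it does not

The generator exists so the whole pipeline is testable without any patient
data. It emulates the *statistical structure the method assumes*:

- per-level rotation ~ Normal with the published asymptomatic means and
  SDs (8.7 ± 2.8, 14.1 ± 3.4, 17.9 ± 3.2, 19.1 ± 4.5, 16.5 ± 4.7 deg for
  C2–C3 … C6–C7), scaled by an effort multiplier (0.6 emulates the reduced
  global motion of symptomatic cohorts);
- translation = M·rotation + B + noise per level, with M and the noise SD
  derived from the published translation means/SDs and R² values
  (`M = σ_t√R²/σ_r`, `σ_ε = σ_t√(1−R²)`, B matching the means), so a refit
  reproduces the published marginal statistics and R² band;
- pooled disc openings `ΔADH = 0.8·rotation + ε` (σ_ε = 1.55 %EPW) and
  `ΔPDH = 0.6·rotation + ε` (σ_ε = 1.30 %EPW). The anterior/posterior
  slopes and intercepts are not published; these values were chosen once
  so that (a) pooled R² lands in the published 0.81–0.95 anterior band,
  (b) the anterior side opens more than the posterior side closes, as the
  disc geometry implies, and (c) posed geometry stays feasible;
- baseline disc heights (anterior 20 ± 2, posterior 18 ± 1.5 %EPW) split
  the openings symmetrically between phases. No per-level disc-height
  reference is published; these are synthetic conventions recorded in the
  generated provenance. The posterior baseline must comfortably exceed
  half the translation scale, because the posterior corner distances bound
  the realizable translation (triangle inequality at the measured corner).

`poseLandmarks()` inverts the measurement pipeline: vertebrae are convex
quadrilaterals stacked caudal to cranial, and for each segment the pose
(two posterior-corner bearings, the superior vertebra's width, and a common
disc-angle offset) is solved by minimum-norm damped Gauss–Newton with a
deterministic multi-start fallback, to residuals below 1e−11 of the
endplate width, so measured rotation, translation and all four disc heights
match the prescription to better than 1e−6. Prescriptions violating
feasibility (non-positive disc heights, or no rigid pose satisfying all
constraints simultaneously) raise an error naming the segment rather than
being clipped. Because the metric-level model draws translation and disc
heights independently, a sub-percent tail of draws is unrealizable; the
landmark cohort generator redraws such exams from the model and documents
this truncation here. A random global similarity per radiograph exercises
the magnification invariance.

The sectioning experiment emulates the cadaveric pattern: each sectioned
stage adds cumulative shifts at the target level (default C4–C5) —
rotation +2/+4/+6°, anterior opening +5/+8/+11 %EPW and posterior opening
+4/+6/+9 %EPW *beyond* what the shifted rotation predicts, and no direct
translation shift. Translation for injured segments is generated from the
pre-injury rotation, reflecting preserved facet joints maintaining
translational stability, which reproduces the qualitative finding that the
vertical indices discriminate sectioning while translation does not. The
shifts are design choices for a qualitative pattern, not a fit to any
published AUC.

Features of real data the generator does **not** emulate: landmark
placement noise, level-to-level correlation of effort within a subject
(totals therefore vary less than in real cohorts), degeneration structure,
kyphotic alignment, or hypomobility. Passing tests therefore demonstrate
correctness of the computational pipeline and its statistical calibration
under the stated model — not clinical performance on real radiographs.

## Numerical choices

- Similarity registration is the closed-form complex least-squares fit; it
  rejects coincident or collinear landmark sets (reflection-ambiguous) with
  an error.
- Similarity invariance holds to 1e−9 and pose→measure round trips to
  1e−6; both tolerances are asserted in the test suite (200 random posed
  exams).
- The index denominators error out when SEF is zero (a degenerate
  reference fitted on exact-line data), rather than returning infinities.
- Canonical JSON output (sorted levels, fixed corner order, 17 significant
  digits) makes writes byte-stable and read–write round trips exact.
- All thresholds live in the reference object and are overridable; the
  defaults are the published criteria (±2 index limits, 11°, 20 %EPW, 5°
  minimum rotation, 60° effort filter, 3.5 mm disabled).

## Problem sizes

The test suite fits references on 120–2,000 synthetic exams, poses 200
landmark exams for the geometry suite, scores a 10,000-segment cohort for
the index-calibration check, and replicates the 12-per-arm sectioning
experiment over 20 seeds with a majority criterion on the AUC ordering.
`scripts/acceptance.R` uses a 2,000-exam reference and an independent
10,000-segment scoring cohort. These sizes keep every Monte-Carlo check
well inside its sampling error while remaining quick on a laptop.

## Known limitations

- Disc-height construction (corner-to-corner) is one of two defensible
  readings of the schematic measurement figures; a perpendicular-distance
  variant would differ slightly on tilted endplates.
- The printed upper reference limits of the source tables were computed on
  unrounded statistics; recomputing from the rounded printed means/SDs
  reproduces most, but not all, cells at one decimal. The package asserts
  the arithmetic on cells that are exactly consistent.
- Real cohort prevalence tables cannot be reproduced without the original
  radiographs; the package reproduces the *machinery* (criteria, filters,
  denominators) and validates it on synthetic cohorts.
- Only sagittal-plane motion is modelled; coupling with axial/coronal
  motion is out of scope, as is landmark detection from images.
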