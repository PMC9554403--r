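---
title: "Methods: quantifying lung aeration from lung ultrasound"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying lung aeration from lung ultrasound}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lusaer)
```

## Overview

`lusaer` estimates the proportion of air in the superficial lung of a
newborn from lung-ultrasound (LUS) cine clips, using CT as the volumetric
reference. The chain has five stages: ordinal grading of the sonographic
appearance, four quantitative image statistics pooled per clip,
CT-threshold measurement of the true air proportion in the superficial
1 cm of lung, OLS models linking the two, and a synthetic generator of
paired clips and phantoms that makes every stage testable against known
ground truth. This vignette records the modelling choices, their defaults
and units, what the simulations do and do not establish, and the problem
sizes at which the package checks itself.

## The measurement model

### Grading

The ordinal scale follows the accepted description of the aerating
neonatal lung: type 0 (hepatization — the liquid-filled lung conducts
ultrasound and is imaged directly), 0.5 (speckled, discontinuous pleural
line at varying depths), 1 (white-out: confluent B-lines), 2 (distinct
B-lines with A-line bands) and 3 (A-lines only). Two blinded raters grade
each clip; on disagreement a third rater's grade is taken as is
(`consensus_grade()`). For regression the grade enters as a numeric
covariate with its face values (0, 0.5, 1, 2, 3), since a single
coefficient is wanted for the whole scale.

### Image statistics

All statistics are computed per ROI per frame, averaged over the frames of
the 3-s clip within each ROI, then pooled across ROIs by an area-weighted
mean. ROIs are rectangles below the pleural line, between the rib shadows,
at depths of 2, 3 and 4 cm; MPI and both spectral areas are read from the
4-cm ROIs and CoV from the 2-cm ROIs. Pooling frames first and ROIs second
commutes with the reverse order only when every ROI contributes the same
number of frames, which the package requires.

- **MPI**: arithmetic mean of pixel intensities (0–255).
- **CoV**: population standard deviation over the mean. The population
  (not sample) convention matches the default of the numerical stacks this
  kind of analysis is normally run on; at ROI sizes of 10^4–10^5 pixels
  the distinction is far below measurement noise.
- **Spectral areas**: per line, the discrete Fourier power
  `|X_k|^2 / N^2`; per-line spectra are averaged across the orthogonal
  axis and integrated over the band by the trapezoid rule. "Parallel to
  the pleural line" transforms across columns and responds to vertical
  B-line streaks; "perpendicular" transforms with depth and responds to
  horizontal A-line bands. Averaging 1-D spectra (rather than collapsing a
  2-D transform) reduces noise while preserving directional selectivity.

The frequency band is a genuinely open parameter: no published value
exists for it, so the package defaults to 0.1–2.0 cycles/cm per axis,
chosen to bracket A-line spacing (the reciprocal of the ~0.5–1 cm
transducer–pleura distance) and B-line streak widths, while excluding DC
so that the statistic is offset-invariant. It is configurable per
analysis (`feature_config()`). No window function is applied by default —
an optional Hann window sits behind a flag — because windowing was judged
a second-order effect for band-integrated (not peak-resolved) power.

Pixel coordinates are 0-based with row 0 at the transducer face, so depth
increases with row index; depths in cm must divide exactly into pixel
rows.

### CT ground truth

Air is segmented by a strict threshold: gray value `< 0.15 m^-1`
(attenuation scale) inside the supplied lung mask. The superficial region
is the set of lung voxels within 10 mm of the probe-facing lung boundary —
the boundary voxels whose neighbour one step toward the probe is outside
the lung — with distances from an exact separable Euclidean distance
transform honouring anisotropic voxel sizes (implemented in C++; no
installed R package provides a 3-D anisotropic EDT). The 10-mm depth is
used because it excludes large vessels and airways and because ultrasound
rarely penetrates deeper in a partially aerated lung. Membership uses a
strict inequality, so a 10-mm depth on a 1-mm grid selects exactly the ten
most superficial layers of a flat surface. The depth is measured from the
lung boundary, not the skin, matching the anatomical definition of the
pleural line. `P_air` is then air voxels over region voxels.

### Regression models

Only type-1 and type-2 observations enter the models: type 0/0.5 indicate
near-absent aeration and type 3 full aeration, so the quantitative
statistics are informative precisely in the intermediate range.
Simple OLS models are fitted for each statistic on all data, inflation
only, and deflation only; the parallel-axis spectral area is linearized
with `log10` first, as its relationship with percent air is logarithmic.
The response is percent air (0–100). The 95% prediction interval is
reported as the half-width at the covariate mean,
`t[0.975, n-p] * s * sqrt(1 + 1/n)`; because the evaluation point of a
single reported half-width is inherently ambiguous, the leverage-aware
mean half-width over the training points is also stored
(`pi95_halfwidth_mean`). Predictions at arbitrary covariate points use the
full interval with the leverage term, with raw bounds retained and display
bounds clamped to [0, 100]%.

The multivariate model starts from MPI, CoV, `log10` parallel spectral
area, perpendicular spectral area and grade, and prunes by stepwise
backward elimination: refit, drop the covariate with the largest p-value
while it exceeds `alpha`, repeat. `alpha` defaults to 0.05, the
conventional significance level of this literature; nothing else in the
procedure depends on it. If everything is eliminated an intercept-only
fit is returned with a warning. Group contrasts use the Kruskal–Wallis
test (mid-ranks, standard tie correction, chi-square approximation) and
the paired t-test, via the standard `stats` implementations.

The models are pooled OLS across lungs and pressure steps. Observations
from the same lung are not independent, so a mixed-effects treatment
would be defensible; the package replicates the pooled approach
deliberately, as that is the analysis it models, and notes it as a known
limitation.

## The synthetic generator

The generator is first-class, tested code. It emulates the statistical
structure the analysis assumes, not ultrasound physics:

- **Study design**: two lungs per lamb; a static-pressure schedule of
  stepwise inflation (0, then 15 to 50 cmH2O in 5-cmH2O steps), deflation
  in 10-cmH2O decrements, and a final suction step; 45-frame clips (3 s at
  15 frames/s).
- **Pressure response**: per lung, air fraction follows a saturating Hill
  curve `af_max * P^4 / (P50^4 + P^4)` with lung-specific
  `af_max ~ N(0.68, 0.05)` and `P50 ~ N(26, 2) cmH2O`. These values place
  the first type-0.5/1/2 appearances near 15/20/35 cmH2O and give a
  maximum aerated proportion near 63% at 50 cmH2O — the regime observed in
  near-term lambs whose lung tissue retains liquid. On deflation the lung
  holds more air at equal pressure (hysteresis fraction ~0.6 of the gap to
  peak, never below the realized inflation value); suction collapses to a
  residual ~7% air. With these settings no clip reaches type 3 during
  inflation, reproducing the saturation behaviour of liquid-retaining
  lungs.
- **Morphology**: grade-dependent artifact rendering — no pleural echo
  (type 0); bright discontinuous segments 0.5–2 cm deep (0.5); a bright
  confluent subpleural field (1) that, as air fraction rises through the
  type-1/2 range, dims (200 down to ~90 gray levels), sharpens into
  distinct full-depth B-line streaks and grows A-line bands at integer
  multiples of the pleural depth with geometric intensity decay (ratio
  0.55); A-lines only (3). Two dark rib-shadow bands frame the field of
  view. This makes MPI a decreasing, and CoV and the parallel spectral
  area increasing, monotone readouts of aeration over the type-1/2 range;
  the perpendicular area declines as the speckle power of the dimming
  field falls, with A-line reverberation superimposed.
- **Noise**: multiplicative log-normal speckle per pixel per frame
  (sigma 0.25), chosen because it preserves non-negative 8-bit
  intensities; a per-clip log-normal gain jitter (sigma 0.10) that does
  not average out across frames; and a per-clip jitter on the
  aeration-to-morphology mapping (sigma 0.06), the dominant clip-level
  noise source for all four statistics. During deflation all three sigmas
  are multiplied by 1.5, encoding the observation that image–aeration
  relationships are stronger during inflation; this multiplier is the
  single knob behind the inflation-vs-deflation r-squared ordering.
- **Grades** are the bins of the true air fraction under breakpoints
  (0, 0.15, 0.50, 0.85), chosen so the synthetic per-grade medians echo
  the reported ordering and rough magnitudes (~7% for type 0.5, ~36% for
  type 1, ~67% for type 2).
- **CT phantoms**: a gently curved probe-facing lung surface; air voxels
  drawn near 0.05 m^-1 and tissue near 0.40 m^-1 with noise bounded away
  from the 0.15 threshold, so segmentation is error-free by construction
  and the recorded superficial air fraction is exact (within rounding to
  whole voxels, < 0.02); a bright vessel-like tube strictly below the
  superficial centimetre, so the 10-mm restriction demonstrably excludes
  it.
- **Suction** is rendered as deflation to a small residual air fraction;
  how airway reflooding changes image texture beyond that is not
  modelled, as no quantitative description exists to emulate.

What passing tests on this generator show: that the feature definitions,
CT measurement, grading logic and model machinery are correct, and that
the pipeline recovers known structure (grade ordering, hysteresis,
inflation-vs-deflation asymmetry, coefficient recovery, interval
coverage) from data built to contain it. What they do not show: clinical
performance on real images, whose artifact physics (beam geometry, motion,
operator variability, pathology-specific patterns) the generator does not
attempt.

The rule-based `auto_grade()` is a surrogate rater for synthetic clips —
its thresholds are calibrated to the generator's morphology and it is
documented as such, not as a clinical classifier. Because morphology is
continuous across the type-1/2 boundary while labels are binned,
near-boundary clips are intrinsically ambiguous; agreement with generator
labels is ~95% over the full grade range at default noise.

## Numerical choices and degenerate inputs

- Determinism: every generator takes an explicit integer seed;
  per-observation seeds are derived from the master seed by a fixed
  integer recurrence (kept within 32-bit range), and the caller's RNG
  state is always restored. Identical configuration and seed give
  bit-identical frames, phantoms and result tables.
- The EDT uses the lower-envelope (parabola) algorithm per axis with
  physical spacings; "no seed" is encoded as 1e20 rather than infinity to
  keep the intersection arithmetic finite. It is checked against an
  exhaustive per-voxel distance oracle, including anisotropic cases.
- The spectral band is converted to discrete frequencies `k/(N*spacing)`;
  if fewer than two frequencies fall inside the band the integral is 0 by
  convention (the trapezoid rule needs an interval). Bands must exclude
  DC and stay at or below Nyquist.
- CoV is undefined for non-positive means and errors rather than
  returning a sentinel; the same policy applies to `log10` of
  non-positive spectral areas, empty regions, constant covariates and
  zero-variance paired differences.
- The pipeline skips the regression stages with a warning (rather than
  failing) when fewer than 8 type-1/2 observations exist; the grading
  summary and manifest are still produced.
- CSV outputs are written with fixed formatting and no timestamps, so
  reruns are byte-identical; percentages in summary tables are rounded to
  one decimal.

## Problem sizes used for self-checks

The package's own test battery runs at sizes chosen to be informative per
unit time: unit tests use a 128 x 64 px, 5-frame, 0.04 cm/px geometry and
24-voxel phantoms; cohort-level checks use the desk-scale configuration
(240 x 192 px, 0.02 cm/px, full 45-frame clips, 64-voxel phantoms) with 7
lambs through the default 15-step schedule (210 paired observations);
statistical operating characteristics use 100 replicates of n = 168 for
coefficient recovery, 1,000 test points for interval coverage, and 500
replicate fits for the elimination false-retention rate. The full-scale
default imaging geometry (480 x 384 px at 0.01 cm/px) is used for
single-clip and phantom checks.

## Known limitations

- The generator's artifact model is stylized: no beam divergence,
  curvilinear geometry, motion, or pathology-specific artifact patterns;
  rib shadows are fixed vertical bands.
- `auto_grade()` is generator-calibrated and should not be applied to
  clinical images.
- Pooled OLS ignores the repeated-measures structure of lungs within
  lambs.
- CT cannot distinguish retained liquid from collapsed tissue; the
  phantoms inherit that ambiguity by construction (both are simply
  "non-air").
- Clip input is multi-frame TIFF (plus JSON sidecar); DICOM cine export
  is not provided, as no DICOM writer is available to the package's
  dependency set.
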