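---
title: "Methods: radiomics of visually FET-negative gliomas from dynamic PET"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radiomics of visually FET-negative gliomas from dynamic PET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fetradiomics)
```

## The problem

A sizeable fraction of gliomas — roughly a third of low-grade and a few
percent of high-grade tumors — show no visually increased uptake of the
amino-acid tracer O-(2-[18F]fluoroethyl)-L-tyrosine (FET) on PET.  Two
phenotypes are distinguished on visual read: *isometabolic* tumors,
indistinguishable from healthy background in static images, and
*photopenic* tumors, whose uptake is visibly *below* background.  The
question this package operationalizes is whether quantitative image
features still separate such "FET-negative" tumor tissue from healthy
tissue, and in particular whether the *dynamics* of the tracer (per-voxel
time-to-peak) carry information that static images do not.

The pipeline has five stages, each usable on its own:

1. **Synthetic cohort** (`simulate_patient()`, `cohort_plan()`,
   `simulate_cohort()`): a seeded digital phantom emulating dynamic FET
   acquisitions of both phenotypes.
2. **Parametric maps** (`sum_frames()`, `tbr_normalize()`, `ttp_map()`):
   early (5–15 min) and late (20–40 min) tumor-to-background-ratio images
   and the time-to-peak (TTP) map.
3. **Radiomics** (`extract_all()`, `feature_map()`): 93 features — 18
   first-order plus 75 texture (GLCM 24, GLRLM 16, GLSZM 16, GLDM 14,
   NGTDM 5) — from the tumor VOI and its mirrored contralateral twin.
4. **Screening** (`paired_wilcoxon()`, `significance_census()`): paired
   signed-rank tests of tumor vs. mirrored background per feature.
5. **Classification** (`nested_cv_auc()`, `univariate_auc()`): nested
   cross-validated, balanced, L2-regularized logistic regression.

## The acquisition model

The standard dynamic protocol records 16 frames over ~40 min p.i.:
7 × 10 s, 3 × 30 s, 1 × 2 min, 3 × 5 min, 2 × 10 min
(`default_frame_schedule()`).  These durations sum to 2380 s (39.67 min),
slightly short of a nominal 40 min; the package treats the duration list
as authoritative everywhere (frame mid-times, window selection, TTP
values).  Frame mid-times are the only time coordinates used downstream:
a frame belongs to a summation window `[t0, t1)` iff its mid-time does,
and TTP values are frame mid-times (no sub-frame interpolation), so a TTP
image takes at most 16 distinct values — the final one being 34.67 min.

## The kinetic model of the phantom

No kinetic model is prescribed by the analysis itself, only the
qualitative behavior the literature reports: healthy gray matter peaks
early (perfusion-driven) and then plateaus; FET-negative gliomas show
*ascending* curves peaking after 30 min p.i. (attributed to reduced blood
volume), with photopenic tumors globally reduced.  The package models the
noiseless unit-amplitude curve as a saturating uptake plateau plus a
localized perfusion peak:

$$s(t) \;=\; L\left(1 - e^{-t/\tau}\right) \;+\; \rho L\,
  e^{-(t-c)^2 / 2\sigma^2},$$

with defaults τ = 2 min, σ = 2 min, ρ = 0.5.  Two constraints calibrate
the two remaining degrees of freedom: the plateau level \(L\) is solved
*linearly* so the 20–40 min mean of \(s\) equals the configured
`late_level` (the background reference at equal amplitude is
`late_level = 1`), and the bump center \(c\) is iterated (a few
fixed-point steps on a 0.5 s grid) until the dense-grid argmax lands
exactly on the configured `peak_time`.  The fixed-point step is needed
because the plateau still rises slightly at early peak times, which would
otherwise drag the maximum past the bump center.  This form was chosen
over a gamma-variate-plus-linear mixture because the latter cannot place
an early global maximum under a high late level on a finite acquisition —
the growing linear term overtakes the washed-out gamma peak at the end of
the scan.  Any form meeting the two constraints would serve; this one is
closed-form up to the one-dimensional centering iteration and
well-behaved for every phenotype.

Noise is zero-mean Gaussian per voxel and frame with standard deviation
`noise_scale * sqrt(level / duration_s)` — the count-statistics scaling
of reconstructed frames, making short early frames noisy (≈30 % at 10 s
frames) and long late frames quiet (≈4 % at 10 min frames) at the default
`noise_scale = 1`.  Poisson projection-domain simulation, attenuation,
partial-volume and motion effects are out of scope; consequently the
phantom's VOIs are internally homogeneous up to noise, which real lesions
are not — passing tests show the *pipeline* recovers designed contrasts,
not that real tumors exhibit them.

### Phenotype parameters

`cohort_plan()` draws per-patient parameters around the phenotype
defaults (all draws derived from one base seed):

| parameter | default | spread |
|---|---|---|
| amplitude | 1 | log-normal, sdlog 0.1 |
| background peak time | 4 min | normal, sd 0.5, clamped 2.5–6 |
| tumor peak time | 36 min | uniform 33–39 |
| isometabolic late level | 1.00 | normal, sd 0.02, clamped 0.96–1.04 |
| photopenic late level | 0.75 | normal, sd 0.07, clamped 0.55–0.92 |
| ventricle late level | 0.30 | fixed |

The 2 % tolerance on the isometabolic late level is the package's
operational definition of "visually FET-negative": the noise-free
isometabolic phantom has a tumor TBR(20–40) mean within 2 % of 1 while
every tumor voxel's TTP sits in the final frame — visually invisible,
kinetically distinct.  A consequence of tying the tumor's late level to an
ascending curve is a genuinely reduced *early* uptake (early TBR ≈ 0.8),
so synthetic isometabolic tumors carry more early-window signal than the
clinical cohort showed; the phantom makes no attempt to null that window.

### Geometry

The default grid is 64 × 64 × 48 voxels at 3 mm isotropic resolution,
with an ellipsoidal tumor of 15 mm semi-axes strictly in one hemisphere,
a peri-midline ventricle ellipsoid, and a crescent-shaped background
region — the contralateral sector of a 27–39 mm spherical shell, minus
ventricle and mirrored tumor — used solely for TBR normalization.  The
mirrored VOI is a pure index reflection about the midsagittal plane
(integer or half-integer plane index), minus ventricle voxels; with the
default geometry the exclusion removes ~1 voxel, so tumor and mirrored
VOI have essentially identical shape, deliberately neutralizing
shape-driven feature differences (shape features are excluded from the
profile for the same reason).  An index flip is adequate for symmetric
phantoms; real data would require registration to a symmetry template,
which is documented as a limitation, not attempted.

Tests and the acceptance script run the same physics on a 36 × 36 × 26
grid (identical voxel size, tumor size, and a geometry with zero
ventricle exclusion); cohort classification there uses 10 × 5 (unit
tests: 2 × 5) repeats of the nested CV.  These are the package's
desk-scale problem sizes; package defaults remain 64 × 64 × 48 and
50 × 5.

## Radiomic features

Feature definitions follow the IBSI-style conventions of the widely used
reference radiomics tooling, with camel-case names (`firstorder_Mean`,
`glcm_Idmn`, `glszm_SizeZoneNonUniformity`, ...) so tables are comparable
across tools.  Choices that the source material leaves open, fixed here:

* **Discretization**: fixed bin count, default 32, spanning the in-mask
  range.  TBR images are O(1) ratios and TTP images take ≤ 16 discrete
  values, so a fixed absolute bin width suited to SUV or CT scales would
  collapse the histogram.  Width mode (`floor((x - min)/w) + 1`) is
  available and recorded in output metadata.
* **Aggregation**: GLCM and GLRLM matrices are built per direction (the
  13 unique Chebyshev-distance-1 3D directions), features evaluated per
  direction and averaged.  This makes all texture features exactly
  invariant to axis flips and axis-aligned 90° rotations, which the test
  suite asserts.
* **Neighborhoods**: GLSZM zones are 26-connected; GLDM dependence is
  1 + the number of equal-level 26-neighbors (α = 0); NGTDM uses the
  in-mask 26-neighborhood mean, excluding voxels with no in-mask
  neighbor.
* **Degenerate conventions**: a constant VOI yields skewness = kurtosis
  = 0, correlation-type GLCM features = 1, information measures and
  NGTDM contrast/busyness/strength = 0; every such evaluation is flagged
  and the flag count travels with the feature table.  First-order
  percentiles use linear interpolation; kurtosis is not excess-corrected;
  entropy and uniformity are computed on the discretized histogram; total
  energy scales with voxel volume.
* **No resampling or filtering**: original-image features only; the
  wavelet/LoG feature classes are not part of the 93.

The texture machinery is verified against an independent brute-force
oracle: naive nested-loop matrix builders in the test helpers, compared
on random ≤ 8³ VOIs to ≤ 10⁻⁹ relative error across all 75 features.
`feature_map()` evaluates any of the 93 features in a sliding window
(default 5³, shrinking at image borders) for visualization, e.g. Idmn
homogeneity maps over TTP images.

## Screening

Per feature and image kind, the tumor-minus-mirrored differences across
patients enter a two-sided Wilcoxon signed-rank test.  Zero differences
are dropped (Wilcoxon's convention; Pratt handling is intentionally not
the default and a fully-zero feature is flagged instead of tested).  For
n ≤ 25 pairs the *exact* null distribution is used, computed by
generating-function convolution over all 2ⁿ sign assignments with
midranks — unlike the textbook exact test this remains valid under tied
absolute differences, and it reproduces the classical values (n = 10
all-positive differences: p = 2/1024) while agreeing with
`stats::wilcox.test(exact = TRUE)` whenever ranks are untied.  Larger n
uses the normal approximation with continuity correction.  Per the
original analysis design, no multiple-testing correction enters the
census (features with p < 0.05, strict, per image kind × subgroup); a
Benjamini–Hochberg column is reported alongside as clearly separated
supplementary information.

One behavior worth knowing: the 93 features are strongly correlated, so
the *census count* is heavy-tailed across simulation seeds — a single
chance noise dimension can drag dozens of correlated features below
p < 0.05 together in a null window.  The per-feature false-positive rate
is calibrated (≈5 % on null phantoms); the joint count is not a
calibrated statistic and should be read qualitatively, as the ordering
between image kinds.

## Classification

Samples are VOIs (tumor = 1, mirrored = 0), two per patient.  The
pipeline per training set is: standardize to zero mean/unit variance →
drop zero-variance features → tune the inverse regularization strength C
by inner stratified 5-fold CV over 7 log-spaced candidates in
10⁻³…10³ → refit.  This pipeline sits inside an outer loop of repeated
stratified 5-fold CV (default 50 repeats); scaler, feature filter and C
are computed from outer-training rows only, and a regression test
verifies that an intentionally leaky variant (feature selection on all
rows) measurably inflates null AUC while the proper pipeline stays near
chance.  The solver is ridge logistic regression (`glmnet`, α = 0) with
balanced class weights; the inverse regularization strength C maps to
the ridge penalty as λ = 1/(nC).  Outer
AUC uses the continuous decision score with midrank tie handling and is
cross-checked against an independent ROC implementation.

Stratification is on the class label only — folds may split a patient's
tumor and mirrored VOI across training and test.  This deliberately
reproduces the original design's acknowledged limitation (the classifier
ignores the paired structure and shares per-patient information across
folds, which can inflate AUC); `group_by_patient = TRUE` provides the
corrected grouped design, off by default.  Repeats are implemented as
differently-seeded stratified partitions with fold seeds derived
deterministically from the master seed, so every report is bit-reproducible
and `mean`/`sd` are recomputable from the stored per-fold AUCs.
Univariate ranking applies the identical nested procedure to every
(image kind, feature) singleton; note the maximum over 279 correlated
nulls is selection-biased upward, which the ranking reports do not
correct.

## Numerical choices and degenerate inputs

* TTP tie-break: earliest frame attaining the maximum; optional centered
  moving-average TAC smoothing (odd window, shrinking at edges), off by
  default.
* Summation images are duration-weighted means, not raw sums, so TBR is
  independent of frame binning; the ratio is identical either way for
  uniform windows.
* TBR requires a strictly positive crescent mean and clamps negative
  noise excursions to 0 after division.
* `glmnet` is always handed the full descending λ sequence so
  coefficients at each C are exact, not interpolated; single-feature
  models pad a zero column to satisfy its two-column minimum.
* All randomness (phantom noise, cohort jitter, fold assignment) derives
  from explicit integer seeds; identical seeds give bit-identical
  volumes, tables and CV reports.

## Known limitations

Homogeneous-up-to-noise VOIs; Gaussian (not Poisson/reconstruction)
noise; reflection instead of registration for the mirrored VOI; a
geometric stand-in for the manually drawn crescent; no scanner, motion or
partial-volume modeling; and synthetic isometabolic tumors carry more
early-TBR signal than clinical ones (see above).  Clinical effect sizes
in the source cohort are therefore not reproduced quantitatively — the
synthetic cohort tests the machinery and the qualitative ordering
(TTP-derived features dominate the isometabolic contrast; first-order TBR
features with negative direction dominate the photopenic one), which is
exactly what the acceptance checks assert.
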