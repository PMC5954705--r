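---
title: "PET texture analysis and predictor screening: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PET texture analysis and predictor screening: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petrad)
```

## The problem

Focal thyroid [18F]FDG uptake found incidentally on PET/CT ("thyroid
incidentaloma") carries a non-trivial malignancy risk, but conventional PET
metrics such as SUVmax discriminate benign from malignant nodules only
moderately. Radiomic texture analysis asks whether the *spatial and
distributional heterogeneity* of tracer uptake inside the nodule carries
additional diagnostic signal. `petrad` implements this workflow end to end:

1. **Segmentation** of the lesion at 40% of its local SUVmax;
2. **Quantization** of ROI intensities to 64 absolute gray levels over
   0–20 SUV;
3. **Feature extraction**: 44 features across conventional SUV metrics,
   intensity histogram, mesh-based shape, and four texture-matrix families
   (GLCM, NGLDM/NGTDM, GLRLM, GLZLM), with matrix and shape features gated
   at 64 ROI voxels;
4. **Univariate predictor screening**: one-way ANOVA against cytology
   category and final diagnosis, ROC/AUC pre-selection at 0.55, a
   mutual-correlation audit, Fisher-exact optimal dichotomization with a
   p < 0.08 final gate, and truth-table predictive scores.

Because clinical images cannot be redistributed, the package ships a
synthetic phantom generator that produces cohorts with *known* class
structure, so every stage is testable against ground truth.

## Segmentation and quantization

`segment_nodule()` finds the maximum SUV `M` within a configurable search
radius (default 15 mm) of a seed voxel, thresholds the volume at
`0.4 * M`, and keeps the 26-connected component containing the maximum.
Choices worth knowing:

* The threshold comparison is **inclusive** (`SUV >= 0.4 M`). On continuous
  data the choice only matters on measure-zero ties; it is fixed and
  documented rather than configurable.
* 26-connectivity is the conventional choice for 3D hot-spot growing.
* The seed + search radius replaces interactive VOI placement on a clinical
  workstation; segmentation is idempotent from any seed inside the returned
  ROI, and raising the threshold fraction can only shrink the ROI.

`quantize_roi()` maps SUV to gray levels `1..64` in **absolute** terms over
`[0, 20]` SUV: `level = 1 + floor(SUV / 0.3125)`, clipped to `[1, 64]`.
Bins are left-closed/right-open with the last bin closed. Absolute (rather
than per-lesion min–max) resampling keeps levels comparable across lesions
and is what the histogram and all texture families consume. Conventional
SUV features use the raw values. Lesions hotter than the 20 SUV ceiling
saturate at level 64; a fully saturated ROI is constant-level, and the
zero-variance degenerate values (e.g. `NaN` GLCM correlation) then apply
regardless of ROI size.

## The feature bank

`feature_catalog()` lists all 44 features in fixed column order.

* **Conventional** (always computed): SUVmin/max/mean, SUVstd (population
  divisor `N`, matching the `a = 1/N` moment convention used throughout),
  SUVpeak as the mean over grid voxels whose centers fall in 0.5 mL and
  1 mL spheres centered on the SUVmax voxel (the sphere is not relocated),
  MTV (segmented volume, mL) and TLG = SUVmean × MTV.
* **Histogram** (always computed): skewness and kurtosis as population
  moment ratios of the per-voxel gray levels (kurtosis non-excess: a normal
  distribution gives ≈ 3; both are `NaN` for a zero-variance ROI), plus
  entropy (`-Σ p log2 p`) and energy (`Σ p²`) of the 64-bin level
  distribution.
* **Shape** (gated at 64 voxels): a closed surface mesh of the mask is
  built by marching tetrahedra — each grid cell is split into 6 tetrahedra
  and the 0.5 iso-surface of a lightly Gaussian-smoothed (σ = 1 voxel) copy
  of the binary mask is triangulated. Smoothing gives facets sub-voxel
  orientation, so area converges with resolution (a raw binary field
  yields axis-aligned facets whose total area does not); if a ragged mask
  smooths entirely below the iso-level the kernel backs off (σ/2, then
  raw). Enclosed volume comes from the divergence theorem over
  outward-oriented triangles. From mesh area `A` (mm²) and volume `V`
  (mm³): sphericity `π^{1/3} (6V)^{2/3} / A` and compacity `A^{3/2} / V`
  (the printed functional form, ≈ `6√π ≈ 10.63` for a sphere). On a
  rasterized sphere of radius 10 voxels both are within 1% of the analytic
  limits; the tests assert 5%.
* **GLCM** (gated): one symmetric normalized co-occurrence matrix per each
  of the 13 unique displacement directions at 1-voxel distance (each pair
  counted in both orders); homogeneity, energy, contrast, correlation,
  entropy, dissimilarity computed per direction and **averaged across
  directions** (not pooled into one matrix). Directions without valid pairs
  are skipped; correlation is `NaN` for a constant ROI.
* **NGLDM** (gated): Amadasun–King-style neighborhood statistics — for
  each ROI voxel, the absolute difference between its level and the mean
  level of its in-ROI 26-neighbors; coarseness is the reciprocal
  intensity-weighted total difference, capped at 10⁶ when the total
  difference is zero (documented degenerate value for constant ROIs), and
  contrast is the standard two-factor form (0 when only one level occurs).
* **GLRLM** (gated): maximal same-level runs of collinear in-ROI voxels per
  direction, runs broken at the ROI boundary; the 11 standard functionals
  (SRE … RP), averaged over the 13 directions.
* **GLZLM** (gated): one zone matrix from 26-connected equal-level
  components in 3D; the same 11 functionals applied to zone sizes.

The 64-voxel gate encodes "too small for texture" as `NaN` rather than
omission, so cohort tables stay rectangular. Sub-voxel lesions and
partial-volume effects are *not* corrected.

All four matrix families are verified against brute-force enumeration
oracles (exhaustive pair/run/zone/neighborhood enumeration on random ≤ 5³
ROIs) at 1e-10 relative tolerance, and the whole bank is
translation-invariant by construction and by test.

## Screening workflow

`screen_features()` runs per feature on pairwise-complete data:

* **ANOVA**: classical one-way fixed-effects F-test (via `stats::aov`)
  against the 5-level cytology category and the binary diagnosis. A zero
  between-group sum of squares returns `F = 0, p = 1` instead of 0/0.
* **ROC/AUC**: the rank (Mann–Whitney) formulation with ties counted ½.
  Features whose raw AUC is below 0.5 are *oriented*: the reported AUC is
  `1 - raw` with `orientation = -1`, so "higher oriented value" always
  points toward malignancy, and the dichotomization direction follows the
  orientation. The 95% CI uses a seeded stratified bootstrap (2000
  resamples by default; the CI method is a package choice — distribution-free
  and reproducible — and exact reproduction of any particular published CI
  is not expected).
* **Pre-selection** keeps oriented AUC ≥ 0.55 (boundary inclusive).
* **Correlation audit**: pairwise Pearson r on the pre-selected set with a
  two-sided t-test flag at α = 0.01. Correlated features are *flagged, not
  removed*.
* **Optimal dichotomization**: candidate thresholds are midpoints between
  consecutive sorted distinct values (any threshold between the same two
  order statistics yields the same table, so midpoints are canonical); the
  two-sided Fisher exact p — the sum of hypergeometric probabilities of
  same-margin tables no more probable than the observed one (1e-7 relative
  slack) — is minimized over candidates. Ties are broken toward maximal
  Youden's J, then the smaller threshold, making the output deterministic.
* **Final set**: Fisher p < 0.08. Average PPV and NPV over the final set
  average the integer-rounded percents, the way score tables print them;
  full precision is kept internally.

**No multiple-testing correction is applied** — deliberately, to mirror the
screening design this package re-implements — and the report carries that
caveat. The suite demonstrates the consequence: under permuted labels the
minimized Fisher p is stochastically smaller than a fixed-threshold p
(threshold optimism), so final-set membership of weak effects should be
read as exploratory.

## The phantom generator

`phantom_spec()`/`make_phantom()` build an ellipsoidal nodule (membership
by voxel center) in truncated-Gaussian background noise (SUV is
non-negative, so negative draws clip at 0). In-nodule intensities follow a
constant, Gaussian (symmetric), or lognormal (right-skewed) model; the
ground-truth record stores the analytic mean/sd/skewness (for the
lognormal, skewness `(e^{σ²}+2)√(e^{σ²}-1)`) and the exact ellipsoid
volume. Noise is spatially independent by default; an optional Gaussian
PSF blur (FWHM in mm) exists but is off, because texture matrices are
sensitive to smoothing and it must be an explicit choice.

`cohort_spec()`/`make_cohort()` draw a cohort of 50 subjects (18
malignant) on a 28³ grid at 3 mm isotropic spacing — an 84 mm cropped
neck field of view, a realistic thyroid subvolume that keeps simulation
studies tractable. Class structure:

* benign: Gaussian uptake, per-subject mean ~ N(5, 0.8) SUV (floored at
  2), within-nodule sd 0.8; large nodules r ∈ [8, 9.5] mm, small
  r ∈ [3.5, 5] mm;
* malignant: lognormal uptake, per-subject median ~ exp N(log 9, 0.25),
  log-sd 0.3; large r ∈ [12.5, 15] mm, small r ∈ [5, 6.8] mm;
* per-axis radii jitter U(0.95, 1.05) makes nodules true ellipsoids;
* per-class small-nodule probabilities (default 0.5 benign, 1/3
  malignant) size a subset of nodules to segment below 64 voxels,
  emulating a cohort in which texture features are only available for
  roughly 28 of 50 subjects (16 benign / 12 malignant).

These defaults are *dials*, not estimates of any patient population: the
classes separate strongly on uptake level (SUVmax), volume (MTV) and
intensity asymmetry (skewness). Sizing control is approximate by design —
an extreme hot voxel in a lognormal nodule occasionally raises the 40%
contour enough that a "large" nodule segments small. A simulated 5-level
cytology category (TIR1–TIR5) is assigned by a fixed stochastic map from
the true class (benign mostly TIR2, malignant mostly TIR4/TIR5), purely so
the category-ANOVA stage has realistic labels to consume.

For the parameter-recovery study the cohort uses small-nodule
probabilities (0.5 benign, 0.1 malignant) so that the injected volume
effect has true AUC ≥ 0.85: with one third of malignant nodules below 64
voxels (hence below 1.73 mL) while half the benign ones exceed it, the MTV
AUC is bounded above by `1 − 1/3 × 1/2 ≈ 0.83`, so the study-emulating
sizing cannot carry a 0.85 volume effect by construction. Under the
recovery settings the suite requires each injected effect (skewness,
SUVmax, MTV) to reach the final predictor set in at least 90 of 100 seeded
runs; the problem sizes throughout (50-subject cohorts, 28³ grids, 100
runs, 2000 bootstrap resamples) are the package's chosen defaults for a
desk-scale, fully reproducible study.

What passing these tests does **not** show: phantoms have no scanner
physics (attenuation, reconstruction artifacts, spatially correlated
noise, motion), no partial-volume effect, and idealized ellipsoid
geometry. Agreement with the oracles and recovery of injected effects
validate the *computations*, not clinical performance on real images.

## Numerical conventions and degenerate inputs

* Population (divisor-N) moments everywhere; kurtosis non-excess.
* Internally, voxel coordinates are 1-based array indices (the natural R
  convention); physical mm appears only at interfaces.
* Constant ROI: histogram skewness/kurtosis `NaN`, entropy 0, energy 1;
  GLCM energy/homogeneity 1, contrast/entropy/dissimilarity 0,
  correlation `NaN`; NGTDM contrast 0, coarseness at its 10⁶ cap; one
  zone spanning the ROI.
* Empty masks, absent classes, single distinct values, and zero margins
  raise errors or return the documented degenerate values (`p = 1` for a
  zero-margin Fisher table).
* All randomness is seeded: phantoms per subject via child seeds from the
  cohort master seed, the AUC bootstrap via an explicit seed, and the RNG
  state of the caller is never disturbed.

## Known limitations

* The texture-feature conventions (which exact functional each named
  feature denotes) follow the radiomics literature's standard definitions;
  numerical identity with any specific clinical software build is not
  guaranteed.
* The mesh's "enclosed volume" differs slightly from voxel-count volume;
  compacity/sphericity use the mesh consistently.
* Screening is strictly univariate: no multivariable model, no
  cross-validation, no harmonization across scanners.
* DICOM/DICOM-RT input is out of scope; volumes are exchanged as NIfTI.
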