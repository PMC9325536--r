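---
title: "Voxel-wise radiomics and radiomic decision maps: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-wise radiomics and radiomic decision maps: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdmap)
```

## The problem and the model

Radiomic models built from engineered features usually compute one scalar
feature per tumor region of interest (ROI) and feed a vector of such
features into a classifier. That design makes the model opaque in space:
nothing ties the prediction back to *where* in the tumor the signal lives.
`rdmap` implements an alternative: every feature is computed **voxel-wise**
with a cubic sliding window, the ROI feature is defined as the **mean** of
the voxel-wise map,

$$g_p(i) = \frac{1}{N_v(i)} \sum_{v=1}^{N_v(i)} x_p(i, v),$$

and the classifier is a logistic regression on the aggregated features,

$$P(i) = \frac{1}{1 + e^{-D(G(i))}}, \qquad
  D(G(i)) = \beta^\top G(i) + \beta_0.$$

Because both the mean and $D$ are linear, backprojecting the coefficients
onto the voxel-wise maps gives a **radiomic decision map** (RDM)

$$DV(X(i,v)) = \beta^\top z(i,v) + \beta_0$$

whose ROI mean equals $D(G(i))$ *exactly* on the aggregation grid, so the
logistic transform of the map mean reproduces the model's predicted
probability. This is the same algebra as class-activation mapping with
global average pooling in convolutional networks, but with features that
have explicit mathematical definitions. Features without voxel-level
counterparts (shape descriptors) contribute a per-patient scalar offset
$\beta'^\top G'(i)$; the map then explains the mappable part of the model.

`backproject()` asserts the mean identity on the native aggregation grid.
Resampling maps to a common display grid is supported
(`resample_maps_common_grid()`), but interpolation breaks the identity by
a small residual; we therefore aggregate on the native grid and treat
resampling purely as an export step. Exported maps carry `NaN` outside the
ROI, where the decision value is undefined.

## Feature catalog and windowing

Five families are computed inside each window: 18 first-order statistics,
24 gray-level co-occurrence (GLCM), 14 gray-level dependence (GLDM,
dependence threshold 0), 16 run-length (GLRLM) and 5 neighbouring
gray-tone difference (NGTDM) features — 77 per modality, so a
four-modality patient yields 308 maps, and a two-modality model consumes
a $2 \times 77 + 14 = 168$-long ROI vector including the 14 shape
features. The window is 9 voxels per axis by default; its size is the
model's receptive field and is the main resolution/stability trade-off.

Conventions that matter for reproducibility, all verified against an
independent single-region reference implementation in the test suite:

* **Window masking.** Only in-ROI voxels inside the window contribute
  (no signal leaks from outside the tumor). The unmasked variant is
  available behind the `masked` flag of `extract_feature_maps()`.
* **Gray levels.** Texture matrices use the image-wide discretized levels
  restricted to those present in the window; there is no per-window
  re-binning, so levels are comparable across voxels and patients.
* **Matrix accumulation.** GLCM (symmetric, distance 1) and GLRLM are
  accumulated over the 13 unique 3D directions before feature
  computation; NGTDM and GLDM use the 26-neighbourhood.
* **Degenerate windows.** A window whose ROI intersection holds fewer
  than 2 voxels inherits the nearest computable voxel's values, so
  aggregation is defined at every ROI voxel. A window∩ROI set with no
  voxel pair at distance 1 has all GLCM features defined as 0.
* **First-order Energy** is the unnormalized sum of squares over the
  window∩ROI voxels, as in the standard catalog; it therefore correlates
  with local ROI occupancy near the boundary. We keep the standard
  definition rather than inventing a normalized variant.
* **Moments** are population moments (divide by $N$), percentiles use
  linear interpolation (R type 7).

## Preprocessing

* **Resampling** to isotropic voxels uses order-3 B-spline interpolation
  (recursive coefficient prefilter, mirror boundaries; exact for
  constants and, away from borders, for polynomials up to degree 3).
  Masks are resampled nearest-neighbour. Defaults: 3 mm for PET, 1 mm
  for CT and MRI.
* **T1 normalization** rescales against fat as a reference tissue:
  $(I - \mu_{fat})/\sigma_{fat}$ over voxels pooled from fat-sphere
  masks. The map is affine with positive slope, so inter-patient
  intensity ordering is preserved. Statistics are computed on the
  native-grid image, before any resampling. Bias-field correction is
  accepted as an upstream hook; the package does not re-implement it.
* **T2 (fat-suppressed) normalization** is a per-tumor z-score over the
  ROI — it removes inter-patient scale, which is the price of having no
  reference tissue in these sequences.
* **CT ROI conditioning** drops voxels outside the closed interval
  $[-230, 600]$ HU (air and bone) while keeping hypodensities and
  calcifications.
* **Discretization**: fixed bin size for calibrated units (0.3125 SUV
  for PET, 10 HU for CT), with bins anchored at multiples of the width;
  fixed bin count (128 bins over a cohort-wide range, top edge
  inclusive) for MRI. Out-of-range values in count mode are clamped with
  a warning. The population-SD and anchoring conventions are recorded
  here once and used consistently everywhere.

## Model building

* **Score.** The average stratified Brier score
  $ASB = 1 - (SB_{C0} + SB_{C1})/2$ weighs both classes equally and is
  calibration-aware. Anchors: perfect model 1, always-wrong 0, constant
  0.5 predictor 0.75, majority-class dummy 0.5. These four anchors are
  asserted exactly in the tests.
* **Fit.** L1-penalized logistic regression with balanced class weights
  (each class carries half the total loss), solved by a deterministic
  proximal-Newton coordinate descent with tolerance $10^{-4}$ and at
  most 100 iterations; `C` is the inverse regularization strength. The
  solver is cross-checked against `glmnet` and an independent proximal
  gradient optimizer in the tests. Features are z-scored with
  training-set statistics; the statistics travel with the coefficients
  in the model spec.
* **Selection.** Multicollinearity is first reduced without labels:
  iterative pairwise-Pearson pruning (threshold stepping down by 0.001
  until the correlation determinant exceeds $10^{-12}$; the pair member
  with the higher mean |R| is removed, re-evaluating after each removal)
  followed by VIF pruning to max VIF < 10. "Null determinant" is
  operationalized as $|\det| < 10^{-12}$ since exact zero is
  unattainable in floating point; ties break toward the later column so
  traces are reproducible. Then a forward sequential wrapper grows the
  subset under repeated stratified cross-validation (defaults
  200 × 5-fold), scaling refit inside every training fold.
* **Grid search.** Ten C values from 0.1 to 100 on a log10 scale,
  evaluated on shared folds. The original procedure selected the
  configuration manually by a tradeoff (high mean ASB, low SD,
  parsimony, regularization); for reproducibility the package automates
  it as a one-SD parsimony rule — the smallest $k$, then smallest $C$,
  within one SD of the best mean — with the manual choice still
  available by inspecting `tidy(grid_search_result)`.
* **Validation.** A label-permutation test re-runs the whole pipeline
  (selection + grid search) on shuffled labels; the empirical p-value
  uses the add-one estimator $(1 + \#\{null \ge obs\})/(1 + B)$, which
  the source procedure leaves unspecified. Final models are bagged over
  stratified bootstrap resamples (default 1000) with out-of-bag ROC AUC;
  stratification (not stated in the original, chosen here) guarantees
  fittable resamples in small imbalanced cohorts. Per-bootstrap
  standardized coefficients are averaged and reported with their SD;
  averaging across per-resample standardizations is a documented
  approximation — the full-cohort scaling attached to the final spec is
  what deployment and decision maps use.
* **Distillation.** A fitted model can be approximated by a student
  model on simple surrogate features (sub-volumes below SUV/HU
  thresholds, their unions/intersections, log10 transforms with volumes
  floored at 0.01 ml). The teacher's output is binarized at 0.5 by
  default; a continuous-target option fits the soft probabilities
  directly (resampling still stratified on the binarized labels). With a
  sparse teacher the student reproduces the teacher almost exactly; with
  a dense teacher the parsimony rule may legitimately choose a smaller
  student, trading agreement for simplicity.

## The phantom generator

Every stage is testable without clinical data through a multimodal tumor
phantom: an axis-aligned ellipsoid (semi-axes jittered per case so shape
features vary) with a central necrotic core — PET-cold (1 SUV), CT
hypodense (10 HU, inside the 0–20 HU band so the surrogate thresholds
segment it), T1-dark, bright on fat-suppressed T2 — and a metabolically
active rim. Class 1 draws a larger necrotic fraction (default means
0.12 vs 0.35) and a higher rim uptake (5 vs 9 SUV); tumor size is
class-independent, so the anatomical volume is deliberately an
uninformative comparison biomarker. Twenty fat spheres of ~240 mm³ with
textured intensity are placed outside the tumor on the T1 grid to
exercise the fat-reference normalization realistically. Additive Gaussian
noise is applied per modality. The generator records its drawn truth
(necrotic fraction, rim uptake) and the tests verify that both are
recoverable from the images by direct measurement.

What the phantoms do **not** emulate: anatomical background, scanner
point-spread and reconstruction noise correlations, registration error
between modalities, irregular tumor shapes, and heterogeneous MRI
protocols. Passing tests therefore demonstrate the correctness of the
algebra and the sanity of the statistics, not clinical performance.

## Numerical choices

* Shape surface: the ROI surface is meshed by marching tetrahedra on the
  0.5 iso-level of the box-smoothed (3³) indicator field. Meshing the
  raw binary mask overestimates the area of curved surfaces by the
  staircase effect (a digital sphere comes out ~10–25% too large); the
  level-set variant recovers sphere area within ~2% and sphericity
  0.99. The cost is a chamfer on sharp edges of blocky masks — for
  smooth tumor-like masks this is negligible; masks too small to
  survive smoothing fall back to the raw mesh. Masks touching the grid
  border are padded internally so the surface is always closed.
* Axis lengths come from the principal components of the voxel-centre
  cloud ($4\sqrt{\lambda}$), diameters from pairwise distances over
  surface voxels.
* VIF uses a least-squares solve with intercept; $R^2$ within
  $10^{-12}$ of 1 returns `Inf`.
* All RNG-dependent steps (phantoms, folds, permutations, bootstraps)
  take explicit seeds and are bit-reproducible.

## Problem sizes used in the shipped tests

The test-suite phantoms are 24³–40³ voxel grids (2 mm spacing) with
window 5 for pipeline-level checks and window 9 where map counts are the
claim; the statistical block runs 100 permutations at 20 × 5-fold CV on a
50-phantom cohort with an 8-candidate feature set, 20 pure-noise cohorts
at lighter settings, and 200-resample bagging. These sizes are the
package's chosen verification scale; the defaults
(`cv_config()`, `bag()`, `permutation_test()`) remain at the full
200 × 5-fold / 200-permutation / 1000-bootstrap settings.

## Known limitations

* Mean aggregation ties the method to linear decision functions; the
  identity does not survive non-linear classifiers.
* Aggregated voxel-wise features are not numerically comparable to
  whole-ROI features of the same name, so published whole-ROI signatures
  cannot be mapped with this machinery.
* The exported 1 mm common-grid maps are for display; quantitative
  statements should use the native-grid maps where the mean identity is
  exact.
* Sliding windows cannot see pairwise structure at distances beyond the
  window; tumor-scale structure is carried only by the shape features.
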