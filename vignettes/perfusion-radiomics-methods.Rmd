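---
title: "Perfusion radiomics for neurological impairment: models, assumptions and design"
author: "perfrad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Perfusion radiomics for neurological impairment: models, assumptions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Acute ischemic stroke (AIS) injures brain tissue through interrupted blood
supply; the degree of neurological impairment is assessed clinically with the
NIHSS scale, dichotomized here into *good* (NIHSS 0--4) and *poor* (NIHSS
5--42) function. perfrad implements a quantitative, image-based assessment of
that dichotomy from co-registered perfusion parameter maps (CBF in
mL/100g/min, CBV in mL/100g, MTT and Tmax in s), a DWI signal pair, and a
quantitative susceptibility map (QSM, ppb). The pipeline has five stages:
region delineation, radiomics feature extraction, feature selection, group
assembly, and a six-classifier benchmark. Because no patient data ship with
the package, a synthetic phantom generator reproduces the study conditions so
every stage is exercised end to end.

## Region delineation

Three regions are delineated per subject, all with *strict* inequalities
(boundary voxels excluded; the delineation rules are printed as strict
inequalities and we keep them that way):

* **Ischemic** tissue: `Tmax > 6` s.
* **Infarct** core: `ADC < 620e-6` mm^2/s, with
  `ADC = -(1/b) ln(S_b / S_0)` from the DWI pair at `b = 1000` s/mm^2.
  Voxels with non-positive signal are flagged invalid and never thresholded.
* **Hypoxic** tissue, via venous oxygen saturation (SvO2) from QSM:
  1. the susceptibility volume is *upright-aligned*: the brain-mask centroid
     is translated to the in-plane volume centre and the in-plane deviation
     angle is estimated by minimizing the left--right reflection mismatch of
     the brain mask over a +/-20 degree search at 0.25 degree steps
     (coarse-to-fine). The record of shift, centre and angle makes the
     alignment invertible.
  2. each hemisphere's per-slice bounding box is partitioned into a
     10 x 10 x 1 grid of units; the in-plane index `i` counts away from the
     midline so unit (i, j) of one hemisphere mirrors unit (i, j) of the
     other. Remainder voxels join the last unit per axis, which keeps the
     partition total and deterministic.
  3. vein voxels are those with susceptibility strictly between 90 and
     300 ppb (the lower bound isolates draining veins against the
     approximately zero-susceptibility parenchyma, the upper bound removes
     spuriously high values). Per unit, the mean vein susceptibility
     Xbar is computed, missing when the unit holds no vein voxel.
  4. with the mirrored contralateral unit as reference and an assumed healthy
     reference saturation `SvO2_ref = 0.7`, the saturation change of a unit
     is `dSvO2 = -(1 - SvO2_ref) (Xbar_ref - Xbar_roi) / Xbar_ref`, and
     `SvO2 = SvO2_ref - dSvO2`. The blood-susceptibility constant (0.18 ppm
     between fully oxygenated and deoxygenated blood) and the hematocrit
     cancel in this contralateral-ratio form; they are carried in
     `svo2Params()` as documentation only. A zero or missing reference mean
     flags the unit invalid -- never infinite.
  5. units of the affected hemisphere (the side holding the ischemic-mask
     centroid; the cohort design assumes unilateral lesions) with
     `SvO2 < 0.7` form the hypoxic mask, mapped back to the native grid.

SvO2 values are reported unclipped: the ratio form can leave [0, 1] on noisy
input, and preserving the raw value keeps the computation auditable; the
hypoxia comparison is performed on the raw value.

Two open choices deserve note: the 10 x 10 grid is anchored to the
hemisphere *bounding box* (not the fixed half-volume), and hypoxic regions
are *unit-granular* (the whole unit is flagged, not individual voxels). Both
are configurable anchors rather than facts about the data.

## Radiomics features

Features are extracted per region, per perfusion map, per filtered image.
The filter bank (18 images per map) contains the original image;
Laplacian-of-Gaussian at physical scales 1--5 mm (per-axis kernels in voxel
units, DC-corrected so linear ramps map exactly to zero); the eight subbands
of a one-level undecimated separable coif1 wavelet decomposition (undecimated
so every subband stays on the native grid under the region mask); and four
range-normalized intensity remaps (square, square root, logarithm,
exponential) that keep outputs on a scale comparable to the input.

Matrix features require discretized gray levels. The default is a fixed bin
width of 25 map units (the de-facto toolkit default); a fixed bin count
(default 16) is available and is what the shipped analyses use, because the
four perfusion maps live on very different scales (CBV spans a few mL/100g,
CBF tens of mL/100g/min) and a fixed count gives every map a usable level
range. Fixed-bin-count features are invariant to affine intensity rescaling,
which the tests assert.

Six feature classes follow the IBSI formulary: 18 first-order statistics
(moments on raw intensities, entropy/uniformity on the discretized
histogram), GLCM (23 features; symmetric co-occurrences at Chebyshev
distance 1), GLRLM (16), GLSZM (16; 26-connected zones), GLDM (15;
dependence = equal-level 26-neighbours, column index includes the centre so
it starts at 1), and NGTDM (5). GLCM and GLRLM are computed for the 13
unique 3D directions and feature-averaged by default (merging is available).
Degenerate inputs fall back to documented constants (e.g. correlation 1 for
a single gray level, skewness 0 for a constant region, coarseness 1e6 when
no voxel has an in-mask neighbour) so every emitted value is finite. Every
matrix builder is checked bit-exactly against an independent brute-force
coordinate-loop oracle in the test suite.

Feature names follow `region__map__filter__class__Feature`, e.g.
`ischemic__Tmax__log-sigma-3__glszm__ZoneEntropy`. Regions smaller than
`minVoxels` (default 10) yield an all-NA row flagged per subject -- features
are never fabricated -- and flagged subjects are dropped cohort-wide with a
warning before selection.

## Feature selection

Features are standardized as `(F - mean) / (max - min)` with statistics
fitted on the training rows only and applied to all rows; constant features
map to 0 with a warning. Whether the original analysis standardized on the
training set or the whole cohort is not stated; the train-only choice avoids
leakage and a `standardizeOn = "all"` flag reproduces the alternative.

A two-sided Student (equal-variance) two-sample t-test screens features at
`p < 0.05` (strict; `p = alpha` is dropped; Welch is available). The
survivors enter an L1-penalized least-squares regression of the 0/1 label
(poor = 1) with the penalty chosen by 5-fold cross-validation over a
~100-point logarithmic grid -- the least-squares (not logistic) form mirrors
the named CV-Lasso routine -- and features with non-zero weight at the
chosen penalty are retained. Selection runs separately per perfusion map and
the retained sets are concatenated, matching the per-map
selection-then-combination design. The fold assignment is seeded, making
selection deterministic.

The 14 experimental groups cross seven region combinations (ischemic,
infarct, hypoxic and their unions) with two feature types: the selected
radiomics features, or the four regional perfusion parameter means per
region (so e.g. `Ischemic_infarct_hypoxic_parameters` has exactly 12
columns).

## Classifier panel and metrics

Subjects are split stratified 7:3 once per run; the per-class train counts
use floor for the good class and ceiling for poor, so 45 + 45 subjects give
31 + 32 train and 14 + 13 test. Six classifiers are fitted on the training
rows only: RBF-kernel SVM, a single-hidden-layer MLP (16 units, weight decay
1e-4, 200 iterations), a 500-tree random forest, AdaBoost (SAMME over
depth-1 CART stumps, 50 rounds, implemented in-package), logistic
regression, and Gaussian naive Bayes. Hyperparameters are ecosystem defaults
with fixed seeds -- the original settings are not printed -- and all are
exposed. A failing classifier is reported as NA, not fatal to the panel.

Each (group, classifier) cell reports the confusion metrics (accuracy,
sensitivity, specificity, PPV, NPV; positive class = poor, which is the
class the printed sensitivity tracks) and AUC as the Mann-Whitney rank
statistic with ties counted half, verified against a brute-force all-pairs
oracle. The per-group best classifier is selected by AUC.

## The synthetic cohort

`cohortConfig()` defaults encode the study conditions: 45 subjects per
class; unilateral ellipsoidal lesions (in-plane semi-axes 5--9 voxels,
Gaussian-tapered boundary) with a concentric infarct core; regional
perfusion targets from the printed per-region class statistics (ischemic,
infarct and hypoxic rows for all four maps); mirrored random-walk vein trees
(baseline susceptibility 120--180 ppb) and, per subject, a handful of
affected-hemisphere grid units whose vein susceptibility is elevated 1.5x,
dropping their SvO2 to 0.55 < 0.7. Subject seeds derive from the master seed
by increment, so cohorts are reproducible and subjects distinct.

Key generator mechanics:

* Subject-level regional means are drawn from a normal with the configured
  class mean/SD, truncated at zero with a location correction so the
  *realized* expectation still equals the target (an uncorrected truncation
  would bias the good-class Tmax mean by ~0.7 s). Voxel noise is additive
  Gaussian, rectified at the physical floor of each map.
* The infarct core draws its own target and the surrounding ring receives
  the complementary value, so the ischemic and infarct regional means both
  converge to their targets although the regions nest.
* The DWI pair is synthesized by inverting the ADC relation from a
  ground-truth ADC field (core uniform in 430--560e-6, parenchyma 800e-6
  mm^2/s), so thresholding the recomputed ADC recovers the core exactly in
  the noise-free default.
* Susceptibility noise defaults to zero, which keeps the mirrored vein
  pairing exact: designated hypoxic units are recovered *exactly* by the
  full alignment-grid-SvO2 chain, and non-designated units sit exactly at
  the reference saturation (strictly-below comparison keeps them out).

One inconsistency is inherent to the printed statistics and survives in the
phantom: a good-class ischemic Tmax of 6.24 +/- 4.49 s places roughly half
the good-class subjects *below* the 6 s threshold that defines the region,
which is impossible for a mask thresholded on the same map (in the source
data the statistics were computed after cross-modality registration). The
generator treats the printed values as targets for the ground-truth lesion;
consequently the *measured* Tmax > 6 s mask of a low-target subject is
nearly empty and that subject is dropped, mimicking a patient without an
evident perfusion lesion. The noise-free exact-recovery property of the
ischemic mask therefore holds whenever the drawn targets clear the
threshold, and the test suite asserts it under a configuration that
guarantees this; infarct recovery is unconditional.

What the phantoms do *not* model: realistic lesion morphology (ellipsoids
with tapered rims only), spatial autocorrelation of perfusion noise,
inter-map correlation of subject effects, DSC-PWI time-series physics,
registration error, or QSM reconstruction artifacts. Passing tests
demonstrate that the *pipeline* recovers what the generator planted under
the printed effect sizes -- not that the printed patient-level accuracies
are reproducible, which without the original cohort they are not.

## Numerical and scale choices

* All thresholds strict; ties at a threshold are excluded everywhere.
* The angle search is coarse-to-fine at a 0.25 degree final step over
  +/-20 degrees; ties prefer the smaller magnitude. Rotation uses
  nearest-neighbour resampling so mask and vein values are preserved
  exactly and a zero-rotation alignment is the identity.
* Lasso uses `standardize = FALSE` (features are already standardized by
  the range rule) and `lambda.min`.
* Shipped analyses run on 36 x 36 x 10 to 48 x 48 x 12 voxel grids with
  4 x 4 x 5 mm spacing -- about a quarter of clinical in-plane resolution.
  This is a deliberate phantom-scale choice: regional statistics, not voxel
  counts, carry the class signal, and the test-suite cohorts (n = 48-90,
  10-20 seeds) complete in minutes at this scale. The acceptance analyses
  use the original-image filter with all six feature classes and
  fixed-bin-count discretization (16 bins) for the reasons above.

## Known limitations

* AdaBoost is a plain SAMME implementation with CART stumps; it matches the
  panel role of a boosting baseline but not any specific toolkit's variant.
* The MLP is a single-hidden-layer network; very wide layers are not
  attempted at these sample sizes.
* The hemisphere grid assumes a roughly symmetric brain mask; gross mask
  asymmetry would shift the midline estimate.
* With `chiNoiseSd > 0` the mirrored vein pairing is no longer exact and
  units fluctuate around the reference saturation; hypoxic delineation then
  acquires a noise floor that the defaults deliberately avoid.
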