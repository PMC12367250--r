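---
title: "Methods: dual-sequence MRI body-composition analysis with bodycomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-sequence MRI body-composition analysis with bodycomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bodycomp)
```

## The problem

Quantitative body composition — the partition of a body region into bone,
skeletal muscle and adipose-tissue compartments — is a biomarker family for
cardiometabolic risk. Paired fat/water MRI reconstructions make the tissue
classes separable: adipose tissue is bright on the fat image, lean tissue on
the water image, and the two sequences are acquired co-registered. `bodycomp`
implements a complete analysis chain for such data:

1. **Segmentation** of abdominal compartments (vertebral bone VB, psoas
   muscle PM, core muscle CM, superficial/deep subcutaneous fat sSAT/dSAT,
   intraperitoneal/retroperitoneal fat IPAT/RPAT) and thigh compartments
   (femur, vessel, SAT, muscle) with a dual-channel 2D U-Net.
2. **Quantification**: compartment volumes, bone circumference, and
   intermuscular adipose tissue (IMAT) by two-cluster K-means on fat-channel
   intensities within the muscle compartment.
3. **Agreement statistics** between automated and reference measurements:
   Pearson correlation, absolute-agreement ICC(2,1), Bland–Altman limits,
   and an ordinal trend test for IMAT grades.

Because real cohort data of this kind are access-restricted, the package
ships a first-class synthetic phantom generator so that every stage is
testable end to end with known ground truth.

## The phantom generator

`phantom_params()` / `generate_phantom()` build seeded dual-sequence
phantoms. Geometry is procedural — nested ellipses and annuli with seeded
jitter — chosen to exercise every label, merge rule (SAT = sSAT + dSAT,
VAT = IPAT + RPAT) and quantification step rather than to be anatomically
realistic. An abdominal phantom is a ring stack (skin → sSAT → dSAT →
core-muscle wall → visceral cavity split into IPAT and a posterior RPAT
band, with a vertebral body and paired psoas ellipses); a thigh phantom is a
SAT annulus around muscle with a central femur and two vessel discs.

Key modeling choices:

* **Voxels are anisotropic** (default 10 mm slices, 1 mm in-plane),
  mirroring the anisotropy that motivates a slice-wise 2D model.
* **IMAT speckle** is planted as seeded clusters of 1–3 voxels inside the
  muscle compartment (core muscle in the abdomen, muscle in the thigh) until
  exactly `round(f * n_muscle)` voxels are fat-bright, so the realized
  fraction equals the target up to voxel quantization. Real intermuscular
  fat has streak-like morphology along fascial planes; the speckle model is
  a stand-in that preserves the *fraction*, which is the quantity the
  K-means step estimates, not the texture.
* **Intensities are arbitrary units** (MRI is uncalibrated). Defaults put
  the fat-channel adipose and muscle modes 650 units apart — more than five
  noise SDs at the default `noise_sd = 40` — so the two-cluster IMAT problem
  is well posed. Noise perturbs intensities only; truth masks are
  noise-invariant by construction.
* **The BMI-like covariate** is lognormal (median 25, sdlog 0.15) and
  drives the subcutaneous-fat ring thickness, so covariate-stratified
  splitting is meaningful. Per-case IMAT fractions are Beta-distributed with
  mean equal to the configured fraction (concentration 50).

What passing tests on phantoms do **not** show: robustness to bias fields,
chemical-shift artifacts, partial-volume mixing at tissue boundaries, or
anatomical variability. The phantom suite validates the *machinery*
(geometry handling, losses, metrics, statistics), not clinical performance.

## Preprocessing

Each case is normalized and resampled deterministically:

* **Z-scoring** is per channel over the whole 3D volume (not per slice),
  with population SD; a constant channel maps to zeros.
* **Resampling** is in-plane only (default target 0.820 × 0.820 mm):
  third-order spline interpolation for images (separable natural cubic
  splines, center-aligned coordinates) and nearest neighbor for masks, so
  the mask value set is closed under resampling. The slice axis is never
  interpolated — processing is slice-wise because the data are anisotropic.
  The output dimension convention is
  `round_half_up(dim * old_spacing / target_spacing)`.
  Normalization precedes resampling; the pipeline applies them in that
  order and each step is exposed separately, so the order can be changed by
  composition if desired.
* **Crop/pad** to the network size (default 512 × 512) is centered; pads are
  zero (background for masks) and the inverse transform is recorded so
  predictions can be mapped back by `restore_geometry()`.

## Augmentation

`augment_pair()` applies, each with independent probability 0.5: rotation
(±30°), isotropic scaling (0.7–1.4), mirroring, additive Gaussian noise
(variance 0–0.1 on Z-scored intensities), Gaussian blur (σ 0.5–1.0 px) and
gamma correction (0.7–1.5). Geometric transforms hit image and mask
identically (bilinear vs nearest interpolation); intensity transforms touch
the image only. The 0.5 firing probability is the one fixed design
constant; the ranges are the conventional segmentation-training defaults
and are all configurable. The probability is interpreted *per transform* (the
alternative — one coin for the whole block — is obtainable by composing
configs).

## The segmentation model

`net_config()` describes a symmetric 2D U-Net: per level, two 3×3
convolutions (padding 1) each followed by LeakyReLU (slope 0.01), 2×2 max
pooling down and 2×2 transposed convolution up, skip connections by channel
concatenation, and a 1×1 linear head. The full preset has six levels with
filter pairs (32,32), (64,64), (128,128), (256,256), (480,480), (480,480)
and a (480,480) bottleneck: a 512×512 input reaches an 8×8 bottleneck. No
normalization layers are inserted (pure conv + LeakyReLU). The `tiny`
preset (four levels, filters capped at 64, native 64×64 input) is the
desk-scale configuration used throughout the tests; both presets share all
code paths.

**Output channels.** The thigh head emits 5 channels (4 labels +
background). For the abdomen, seven foreground labels cannot share seven
softmax channels with a background class, so the abdominal head emits 8
channels (7 + background); a 7-channel sigmoid multi-label head is
deliberately not provided, because softmax-over-classes is what the
composite loss and the argmax decoder assume.

At inference, `predict_volume()` applies the model slice-wise, softmaxes and
takes the per-pixel argmax with ties broken toward the lower class id
(`which.max` semantics), then restacks into a mask with the volume's
geometry.

The network and its backpropagation are implemented in
Rcpp/RcppArmadillo (im2col + BLAS) with analytic gradients; the test suite
checks every layer type against central finite differences.

## Training

`train_model()` runs SGD with Nesterov momentum (μ = 0.99, PyTorch-style
update `v ← μv + g; w ← w − lr(g + μv)`), initial learning rate 0.01 and
the poly decay `lr = lr0 (1 − epoch/epochs)^0.9`. The 0.9 exponent is the
standard convention for the poly policy and is exposed in the config. The
loss is soft Dice plus cross-entropy, equally weighted:

* cross-entropy is the mean negative log-probability of the target class;
* soft Dice uses smoothing ε = 1e−5 in numerator and denominator and is
  averaged over **foreground** classes only (background dominates the voxel
  count and would otherwise swamp the term).

Deep supervision attaches 1×1 auxiliary heads at the half- and
quarter-resolution decoder levels; targets are downsampled by nearest
neighbor and the per-resolution weights halve at each coarser level,
normalized to sum to one — (4, 2, 1)/7. Disabling deep supervision reduces
the objective to the top-resolution term exactly.

Minibatches draw slices uniformly with replacement, so "minibatches per
epoch" is a free parameter independent of cohort size. The reference
schedule is 200 epochs × 250 minibatches × batch 10; the desk-scale runs in
this package use 25 epochs × 15 minibatches × batch 4 on 20 phantoms
(64×64, 8 slices each), which recovers ≈ 0.95 mean foreground Dice on
held-out phantoms in a few minutes on one CPU core. The final checkpoint is
the last epoch (no model selection; the validation score is logged, not
optimized against).

## Evaluation metrics

Per case and compartment, from voxel confusion counts (derived compartments
SAT/VAT are unions of their member labels before counting):

* Dice `2TP/(2TP+FP+FN)`, Jaccard `TP/(TP+FP+FN)`, true-positive fraction
  `TP/(TP+FN)`, oversegmentation rate `FP/(TP+FN)`, and relative area
  difference `|(TP+FP)−(TP+FN)|/(TP+FN) × 100`.
* The area difference is reported as an absolute value (the signed variant
  is available behind a flag), matching how such tables are conventionally
  reported; the sign carries over/under-segmentation direction that OSR and
  TPF already express.
* A compartment empty in both masks scores Dice = Jaccard = 1 and missing
  (NA) for the truth-normalized metrics, so perfect predictions on
  compartment-free cases do not drag cohort averages; cohort aggregation
  weights cases equally.

## Quantification

* **Volumes** are voxel counts × voxel volume, mL, with no morphological
  refinement; SAT = sSAT + dSAT and VAT = IPAT + RPAT hold exactly by
  construction.
* **Circumference** (femur, or vertebral body in the abdomen) is measured
  per slice as the marching-squares iso-0.5 contour of the largest
  connected component after Gaussian pre-smoothing (σ = 1 px), scaled by
  the in-plane spacing, averaged over slices (a single-slice mode exists).
  The smoothing removes the staircase bias of binary contours: a digitized
  circle of radius 50 px measures within 1% of 2π·50, at the price of
  rounding convex right-angle corners (an axis-aligned 10×10 px square
  measures ≈ 36.6 rather than 40). The convention is frozen and tested
  against analytic shapes.
* **IMAT** is the higher-mean cluster of a 1-D two-cluster K-means on the
  raw fat-channel intensities inside the muscle compartment (core muscle in
  the abdomen — psoas is deliberately excluded; thigh muscle in the thigh):
  k-means++ seeding, Lloyd iterations, termination at relative center
  movement < 1e−4 (Frobenius) or 300 iterations. Clustering runs on raw
  rather than Z-scored intensities: a monotone transform does not change a
  1-D 2-means partition, and raw units match the acquisition. Because the
  optimal 1-D 2-means partition is always a threshold cut,
  `threshold_2means()` provides an exhaustive, deterministic global optimum
  that doubles as a fallback and as the exactness reference.
  The IMAT percentage is 100 × IMAT voxels / muscle voxels, and
  `grade_bins()` maps it onto the 3-level fatty-infiltration scale; the cut
  points default to (5%, 25%) — the scale's stage descriptions are
  qualitative, so the numeric mapping is configuration, not doctrine.

## Agreement statistics

`icc_2way_absolute()` is the single-measure ICC(2,1) from the two-way
random-effects ANOVA with absolute agreement — it penalizes a constant
offset between raters, unlike the consistency form. Single-measure is the
right variant here because each method contributes one measurement per
subject; the average-measure ICC(2,k) sits behind a flag. Bland–Altman
limits are bias ± 1.96 SD of paired differences. The IMAT trend test is OLS
of the measured percentage on the ordinal grade treated as continuous, with
a two-sided t-test on the slope. Group comparisons default to Welch's
t-test (robust to unequal variances; pooled variant selectable).
Significance is two-sided at 0.05.

## Splitting and the pipeline

`stratified_split()` bins the covariate into quantile strata (default 4)
and apportions each stratum by largest-remainder rounding of cumulative
totals: global sizes follow largest-remainder rounding of `n × fractions`
exactly (100 cases at 8:1:1 gives 80/10/10) and every stratum stays within
one case of proportional. `run_pipeline()` chains
simulate → split → train → segment → quantify → evaluate → agree under one
master seed with fixed per-stage offsets; two identical runs produce
byte-identical metric tables.

## Numerical choices and degenerate inputs

* Softmax is computed with per-pixel max subtraction; log-probabilities are
  floored at 1e−300.
* Argmax ties break toward the lower class id (background first), making
  degenerate all-zero score maps decode deterministically.
* A constant intensity vector inside the muscle mask makes the K-means
  degenerate: the result is flagged and the IMAT fraction is 0.
* Zero between-subject variance makes the ICC undefined; it is reported as
  NA with a warning rather than a number.
* Two zero-variance samples with equal means give t = 0, p = 1 by
  convention in `group_ttest()`.
* Empty compartments: volume 0 with a warning in profiles; an error for
  circumference (there is no contour to measure).

## Problem sizes used by the checks

The test suite and the acceptance script run entirely on synthetic data at
desk scale, chosen so the full chain (including training) completes in
minutes on a single CPU core: 64×64 × 8-slice thigh phantoms, 20 training /
5 validation cases, 25 epochs × 15 minibatches × batch 4 for the training
recovery check; 100 random mask pairs for the metric oracle; 50 phantoms
for the agreement experiment; n = 10,000 for the Bland–Altman coverage
check. The full six-level 512×512 preset is exercised for shape and
parameter-count contracts (forward pass only).

## Known limitations

* No MR physics: no Dixon reconstruction, bias fields, or chemical shift;
  noise is additive Gaussian only.
* No registration between the fat and water channels (assumed co-registered
  as acquired) and no bias-field correction.
* The 2D model never sees through-plane context; volumes with very few
  slices per case are by design, matching the anisotropy argument.
* DICOM series input is not supported; NIfTI-1 is the interchange format.
* Surface-distance metrics (Hausdorff, ASSD) are out of scope.
* Training at the full 512×512 / 200-epoch scale is a GPU-class workload;
  this package trains faithfully but is meant for desk-scale replication of
  the mechanism, not for reproducing cohort-level performance.
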