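---
title: "Volumetric GLCM texture analysis for lesion classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volumetric GLCM texture analysis for lesion classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Clinically significant prostate cancer (csPCa, Gleason score >= 3+4) must be
distinguished from indolent lesions and false-positive findings on
multiparametric MRI. The standard radiologist workflow assigns each
suspicious lesion a PI-RADS score (3-5), and a common rule calls a lesion
csPCa when PI-RADS >= 4 — but that rule is reader-dependent and notably
unspecific. Tumor *heterogeneity* is a primary imaging feature of csPCa, and
texture statistics of the lesion's intensity field capture it
quantitatively. This package implements a texture-first classifier: instead
of feeding images to a deep network, it feeds the network the lesion's
co-occurrence statistics, which are small, size-invariant, and directly
encode spatial heterogeneity.

## The method

For each lesion we take two volumetric patches that closely surround it —
one from the T2-weighted image and one from the ADC map — and process each
channel as follows.

**Normalization and quantization.** The patch is min-max normalized to
[0, 255] (per patch; a constant patch maps to zeros by convention) and
discretized into $n = 64$ gray levels with the uniform floor map
$\ell(v) = \lfloor v \cdot 64 / 256 \rfloor + 1 \in \{1, \dots, 64\}$.
Because the min-max map absorbs any gain/offset in the raw intensities, the
quantized volume — and everything downstream — is invariant to affine
intensity rescaling.

**3D gray-level co-occurrence matrices.** For a displacement
$d = (d_i, d_j, d_k)$ the GLCM is
$$\mathrm{GLCM}_d(x, y) = \sum_{i,j,k}
  \mathbf 1\{f(i,j,k) = x \wedge f(i+d_i, j+d_j, k+d_k) = y\},$$
counting ordered voxel pairs whose destination stays inside the patch, so
the total count is $(I-|d_i|)(J-|d_j|)(K-|d_k|)$. The 26 immediate
neighbors of a voxel fall into 13 equivalence classes under negation
($d \sim -d$; the reversed displacement merely transposes the matrix), and
`canonical_directions()` returns one representative per class (first
nonzero component $+1$, fixed lexicographic order). One matrix per
direction per modality yields a stack of $13 \times 2 = 26$ channels of
$64 \times 64$.

Two conventions are deliberately configurable:

* **Ordered vs symmetric pairs.** The defining sum counts pairs along $+d$
  only; `symmetric = TRUE` adds the transpose first (the common Haralick
  convention). The default follows the ordered-pair definition.
* **Counts vs probabilities.** By default each matrix is divided by its own
  pair count. Raw counts scale with lesion volume and would leak size into
  a classifier whose rationale is texture, so probabilities are the
  default; `normalize = FALSE` keeps counts.

**The compact CNN.** The 26-channel stack feeds a small network:
conv $3\times3$ (26 → 32, stride 1, padding 1) + batch norm + ReLU,
$2\times2$ max-pool, conv $3\times3$ (32 → 64) + batch norm + ReLU,
$2\times2$ max-pool, flatten ($64 \cdot 16 \cdot 16$) → 256 → 2, softmax.
That is 4,221,282 learnable parameters (`cnn_n_parameters()`). Training
minimizes class-weighted cross-entropy (weights default to inverse class
frequency on the training split) with Adam at learning rate $10^{-5}$,
$\beta = (0.9, 0.999)$, batch size 10, 200 epochs; the epoch with the
highest validation AUC is the selected checkpoint. Where the published
description leaves details open we chose: max pooling (the texture-CNN
convention), "same" padding so the spatial arithmetic is the clean
$64 \to 32 \to 16$, a 256-unit hidden FC layer, and validation *AUC* (not
loss) for checkpoint selection. Batch-norm statistics are frozen at
inference.

The network is implemented directly on BLAS (single precision, im2col +
GEMM) with all randomness — initialization and shuffling — drawn from the R
RNG, so a training run is a pure function of its seed: two runs with the
same configuration agree bit for bit.

**Baselines.** `train_rf()` fits the handcrafted-feature baseline: the four
Haralick statistics of each normalized directional GLCM — contrast
$\sum P(x,y)(x-y)^2$, correlation
$\sum P(x,y)(x-\mu_x)(y-\mu_y)/(\sigma_x\sigma_y)$ (defined as 1 when a
marginal variance vanishes), homogeneity $\sum P(x,y)/(1+(x-y)^2)$, energy
$\sum P(x,y)^2$ — giving $4 \times 13 \times 2 = 104$ features, fed to a
random forest (50 trees, Gini, nodes expanded until pure, bootstrap
resampling). `pirads_cla()` is the rule baseline: csPCa iff PI-RADS >= 4.
As a single-operating-point classifier its "ROC" is computed from the
binary prediction treated as a two-level score; this is the only reading
under which an AUC for the rule is well defined, and it equals
$(\mathrm{sens} + \mathrm{spec})/2$.

## The evaluation suite

`evaluate_models()` reports, per model and subgroup: the Mann-Whitney AUC
with a lesion-level percentile-bootstrap 95% CI (1000 resamples;
single-class resamples are redrawn), the Youden operating point (threshold
maximizing sensitivity + specificity − 1 over observed scores, ties broken
toward higher sensitivity then the lower threshold), Wald intervals
$\hat p \pm z_{0.975}\sqrt{\hat p(1-\hat p)/n}$ for
sensitivity/specificity/PPV/NPV, the fast midrank DeLong test on the paired
AUC difference versus the designated baseline, and McNemar tests on
sensitivity (positives) and specificity (negatives) at each model's own
operating point — exact binomial when there are fewer than 25 discordant
pairs, continuity-corrected chi-square otherwise. Subgroups follow the
clinical reporting scheme (zone, focality, PI-RADS score, index lesions by
PSA stratum); single-class subgroups are flagged not-evaluable rather than
erroring. No multiplicity correction is applied (each comparison is read at
p < 0.05). The Youden threshold is chosen on the set being reported, which
mirrors the published procedure but is optimistic; pick it on a validation
split for deployment.

Two numerical conventions worth knowing: the bootstrap is lesion-level
(the analysis unit is the lesion; patient clustering is ignored), and the
DeLong variance of a degenerate comparison (identical scores) is zero, in
which case the no-difference p-value is 1 by convention.

**Calibration caveat.** Both McNemar branches are conservative discrete
tests: their exact type-I level at n = 100 paired indicators is about
0.031-0.036 rather than the nominal 0.05 (computable in closed form from
$N_d \sim \mathrm{Bin}(n, p_{disc})$, $b \mid N_d \sim \mathrm{Bin}(N_d,
\tfrac12)$). The package reports the tests as defined; treat their p-values
as mildly conservative.

## The phantom generator

No clinical images ship with the package, so `generate_cohort()` emulates a
labeled cohort whose classes differ in exactly the property the classifiers
exploit: **texture heterogeneity**. Each lesion is a two-channel 3D patch
of white noise convolved with an isotropic Gaussian kernel and min-max
stretched; csPCa-like lesions use a small blur sigma (0.7 voxels,
fine-grained), non-csPCa-like a large one (2.5 voxels, smooth), plus for
csPCa a central spherical core in the ADC-like channel with a 40% relative
signal drop, and additive Gaussian noise (sd 8 intensity units). Patch
shapes vary per lesion (8-24 voxels per axis) and are *not* resized — the
CNN consumes fixed-size GLCMs, not images, so variable patch size is free
and deliberately preserved.

Defaults mirror a ~400-patient prostatectomy cohort: ~1.16 lesions per
patient, 65% csPCa prevalence, zones at PZ/TZ/AFS = 0.78/0.21/0.01,
focality 41% solitary. PI-RADS scores are sampled from a class-conditional
confusion table with $P(\geq 4 \mid \text{csPCa}) = 0.83$ and
$P(\geq 4 \mid \text{non-csPCa}) = 0.53$, so the rule baseline lands near
sensitivity 0.83 / specificity 0.47 — informative but beatable, as in the
clinical setting. Splits are assigned at the **patient** level
(largest-remainder rounding of 60/10/30; an explicit `sizes=` override
exists for externally specified counts) so no patient leaks across splits.

What the phantoms do *not* model: MR physics, anisotropic voxels,
registration error, prostate anatomy, or any realistic PSA-pathology
relationship. Passing tests on phantoms therefore demonstrate that the
pipeline's machinery — extraction, learning, statistics — behaves correctly
and that the classifiers recover a texture signal that is present by
construction; they say nothing about clinical performance on real mpMRI.

## Problem sizes and numerical choices

The shipped experiment uses 400 synthetic patients (~460 lesions,
~280 training) with the full 200-epoch schedule; on one CPU core this runs
in roughly ten minutes, with training dominated by the two convolutions.
Smaller test fixtures (16-40 patients, 2-3 epochs) exercise the same code
paths. Memory peaks around 1-2 GB, dominated by the cached conv1 im2col of
the training set. Degenerate inputs are handled by stated conventions
rather than errors wherever a convention is defensible: constant patches
quantize to level 1 everywhere, too-small volumes yield zero-count
(flagged) GLCMs, point-mass GLCMs have correlation 1, and a group
evaluation with one class present is reported not-evaluable.

## Known limitations

* The CNN is single-precision; bit-reproducibility holds for a fixed BLAS
  and thread count (the package is intended for single-threaded use).
* Wald intervals collapse at $\hat p \in \{0, 1\}$; they are reported as
  defined rather than switched to a score interval, for fidelity to the
  reference procedure.
* The phantom PSA values are independent of the label, so PSA-stratified
  subgroup reports exercise the reporting machinery only.
* No masking is applied inside the rectangular patch; background voxels in
  the crop contribute pairs, matching the crop-only reading of the source
  workflow.
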