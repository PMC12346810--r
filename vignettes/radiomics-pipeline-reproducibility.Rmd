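---
title: "Reproducible radiomics pipelines: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reproducible radiomics pipelines: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Radiomics models consume features computed from medical images after a
chain of preprocessing decisions — which structures enter the region of
interest, whether sub-zero-HU fat is pruned from the mask, how intensities
are windowed and rescaled, on what voxel grid the image is resampled, how
intensities are discretized, and how the resulting features are
standardized. Each decision looks innocuous, yet a deployed classifier sees
only the numbers at the end of the chain: if a second site reproduces the
chain imperfectly, the model's predictions can flip for a substantial
fraction of patients even when every individual step is "standard".

`radpipe` makes the chain an explicit, ordered, replayable artifact. A
pipeline is a structured text file; a training run freezes every statistic
that post-processing needs (ComBat batch parameters, z-score moments) into
a plain JSON file; derived test and deployment pipelines replay those
frozen statistics bit-identically on new subjects. A perturbation driver
then measures, on a synthetic cohort, how much each preprocessing decision
moves the predictions — the question that motivates the framework.

## The reference pipeline

The canonical chain (`reference_pipeline()`) has seven stages, in this
order:

1. **merge_labels** — pool the anatomical labels that constitute the ROI
   (organ tissue, duct, lesion), excluding vessels and neighbours.
2. **fat_removal** — drop ROI voxels with intensity below 0 HU. Fat sits
   near -100 HU on CT, soft tissue well above zero, so the threshold
   cleanly prunes fat that segmentation left inside the mask border. This
   runs on native HU, *before* windowing: after an affine map to 0-255 the
   "0 HU" threshold has no meaning. Voxels at exactly 0 HU are retained.
3. **window** — clip to the soft-tissue window, level 50 HU, width 500 HU
   (range [-200, 300]), then affinely rescale that range to 0-255. The clip
   and the rescale are independently removable: without the clip the
   rescale maps each image's own min/max to 0-255; without the rescale
   features are computed on clipped HU. No integer rounding is applied
   after the rescale — an 8-bit quantization flag exists but defaults off,
   avoiding an undocumented second discretization ahead of bin-width
   binning.
4. **resample** — interpolate onto a 1 mm isotropic grid, trilinear for
   the image, nearest-neighbour for the mask, with output dimensions
   `ceiling(dim * spacing_in / spacing_out)` and clamp-to-edge sampling.
5. **extract** — IBSI-style features with fixed-bin-width discretization
   (width 25, anchored at the ROI minimum).
6. **combat** — reference-batch ComBat across reconstruction kernels, the
   sharp "iterative" kernel as reference.
7. **zscore** — per-feature standardization by training-split moments.

Stage order is significant and preserved; the engine deliberately does not
canonicalize it, because order sensitivity (e.g. resampling before versus
after windowing) is one of the perturbations under study.

## Feature engine conventions

Where the standard leaves latitude, the engine fixes one convention and
states it:

* **Discretization** (`discretize()`): `floor((x - min) / W) + 1` with the
  bin count `ceiling((max - min) / W)` and the maximum clamped into the top
  populated bin (`ibsi` dialect). The `edge_variant` dialect is the plain
  floor rule with explicit right-exclusive edges and no top clamp, the
  behaviour of generic histogram utilities; the two can differ only for
  values lying exactly on a bin edge. The exact boundary semantics of
  third-party binning utilities vary; `edge_variant` is a documented
  stand-in, not an emulation of any one library.
* **First order**: population moments (N denominator); Pearson non-excess
  kurtosis; entropy in bits on the discretized values; percentiles by R's
  default (type 7) definition; robust mean absolute deviation over the
  10th-90th percentile band.
* **Texture**: 13 unique 3-D directions at distance 1 voxel, symmetric
  co-occurrence accumulation, features averaged over directions with equal
  weights (directions with no voxel pairs are skipped; if no direction has
  a pair the GLCM errors). GLSZM zones use 26-connectivity. Degenerate GLCM
  correlation (zero marginal variance) is defined as 1.
* **Shape**: face-count surface area (each exposed voxel face contributes
  its physical area), not a meshed surface — exactly testable, though it
  overestimates smooth surfaces, so voxelized spheres score sphericity
  well below 1; maximum 3-D diameter is the exact maximum pairwise
  distance between surface-voxel centers; elongation/flatness come from
  principal-axis second moments of voxel coordinates.
* The ten features the bundled classifier consumes are configuration
  (`default_model_features()`), not a claim about any published model's
  signature.

The whole engine is deterministic: the same volume, mask and configuration
produce a bit-identical feature row, which is what makes the replication
and deployment guarantees meaningful.

## Geometry and resampling

The framework operates in voxel index space; spacing and origin ride along
as metadata (world coordinate of voxel `(i,j,k)` = `origin + i*spacing`,
0-based), and orientation beyond scaling is stored but never used — the
pipeline assumes co-registered image/mask pairs on one grid, which the
cohort generator guarantees.

Two grid-placement conventions are implemented. `native` aligns voxel
(0,0,0) centers of the input and output grids; `alt` aligns volume
centers. Both are legitimate; real resampling libraries disagree in
exactly this way, so the `alt` convention is the package's model of a
"different implementation of the same step" — it is an explicit stand-in,
not an emulation of any particular external tool. The cubic B-spline
option is a true interpolating spline (recursive prefilter, pole
√3 − 2, mirror boundary), so it reproduces the samples on an identity
grid; trilinear interpolation reproduces globally affine intensity fields
exactly, which the tests exploit as an analytic oracle.

## Harmonization and frozen statistics

ComBat follows the parametric empirical-Bayes location/scale model in
reference-batch form: features are standardized by the reference batch's
mean and population variance; per-batch location and scale effects are
shrunk toward batch-level normal/inverse-gamma priors by the iterative
joint update (relative change < 1e-4); the reference batch itself is never
adjusted. The implementation matches the standard sva implementation to
machine precision on shared inputs (a cross-check in the test suite), but
unlike a one-shot `ComBat()` call it persists every parameter —
reference moments, shrunken `gamma*`/`delta*` per batch, prior
hyper-parameters — so the identical transform can be replayed on a single
new subject years later. No biological covariate enters the design: batch
means reconstruction kernel and nothing else, so deployment needs only the
kernel label. Whether the original modelling lineage conditioned ComBat on
outcome is unknowable from outside; the default here is the conservative
batch-only design.

Z-score moments (mean, sample SD) are fitted on the training split after
ComBat — fixed order, matching the description order of the chain. The
statistics file serializes all numbers with 17 significant digits, the
precision needed for doubles to round-trip exactly through text; the
deployment chain (fit → serialize → reload → apply) is therefore
bit-identical to the in-memory chain, and the test suite asserts exactly
that.

## Classifier

A gradient-boosted decision-tree classifier (xgboost, logistic objective)
stands in the deployed-model slot. Training is single-threaded with all
row/column sampling disabled, so the model is a pure function of the seed,
the hyperparameters and the feature table — determinism is the point of
the artifact, not a tuning choice. Hyperparameters
(`default_hyperparams()`: 150 rounds, depth 3, learning rate 0.1) are a
documented stand-in sized for small tabular problems; no cross-validated
tuning is performed, and retrained perturbation models reuse the reference
hyperparameters and seed verbatim.

The decision threshold is 0.5 with ties classed as cases (`p >= t`); the
rule is configurable through the threshold itself. AUC is the exact
Mann-Whitney statistic with half-credit ties — identical to pair
enumeration, no curve interpolation. Confusion-metric ratios with zero
denominators are reported as missing, never as zero.

## The perturbation study

`make_variant()` realizes nine deterministic single-decision alterations
(dropping fat removal, alternative binning edges, split-wise
post-processing, the `alt` resampler, resampling first, no window clip, no
spatial resampling, B-spline interpolation, no intensity rescale).
`run_variant_suite()` evaluates each in two regimes: *non-retrained* (the
frozen reference model applied to variant features — a site reusing a
published model through its own pipeline) and *retrained* (same
hyperparameters and seed, variant training features — a site replicating
the study). Agreement with the reference predictions is reported as
Cohen's kappa, discordance percentage and the mean ± SD absolute
probability difference, overall and within label groups, plus a pairwise
kappa matrix per regime. Variant pipelines that cannot run are recorded
per variant; the suite continues.

Two readings of "remove windowing" exist because the window stage bundles
a clip and a rescale; the variant set separates them (`v6` drops the clip,
`v9` the rescale) and the report's metadata says so. Because the reference
pipeline already removes fat, the fat variant is implemented as *skipping*
the removal.

## The synthetic cohort

The generator emulates arterial-phase abdominal CT crops: a 48³ grid at
0.7 × 0.7 × 3.0 mm spacing; an ellipsoidal soft-tissue organ
(default semi-axes 11 × 11 × 30 mm, mean 80 HU, texture SD 15 HU,
per-subject size jitter ±10% per axis and mean jitter SD 1.5 HU); a thin
fluid duct and a bright vessel so label merging has real work; a one-voxel
rim of ≈ −100 HU fat *inside* the mask border so fat removal is
non-trivial; and, in case subjects, a spherical hyper-enhancing lesion
(+40 HU, coarser texture, radius 8 mm — a small tumor sized so the
cohort-level case/control separation on the ROI mean reaches the
standardized effect size the study design calls for, > 0.8 at n = 60).
The two-level "reconstruction kernel" batch effect is injected in image
space, as kernels act in reality: the `iterative` level smooths with a
0.4 mm Gaussian and carries noise SD 10 HU, the `standard` level smooths
with 1.5 mm and carries SD 3 HU. This choice — image-space batch effects
rather than feature-space offsets — exercises the entire chain, and
texture features separate the two kernels with standardized differences
well above 0.5 before ComBat.

Per-subject seeds derive from the master seed by stable integer hashing,
so single subjects and whole cohorts are independently reproducible;
volumes are written as uncompressed NIfTI so regeneration is
byte-identical. What the phantom does **not** model: real anatomy and its
segmentation errors, scanner physics (beam hardening, partial volume
beyond Gaussian blur), intensity non-calibration, or inter-reader mask
variability. Passing tests on this cohort demonstrate that the *software
chain* is exact and that the *directions* of perturbation effects are
detectable; they do not certify effect magnitudes on patient data.

## Numerical and degenerate-input choices

* Resampling uses clamp-to-edge for out-of-support samples (deterministic
  and simple; the `alt` convention may legitimately differ at edges).
* Empty ROIs abort a subject, not a cohort: the subject is skipped with a
  logged reason and counted in the run manifest.
* A feature constant within the reference batch is an error at ComBat fit
  time (its reference scale is undefined), as is any constant feature at
  z-score fit time, and a singleton batch.
* Probabilities exactly at the threshold are cases; kappa for two
  identical constant raters is defined as 1.
* NIfTI-1 stores geometry as 32-bit floats, so spacing/origin round-trip
  to single precision; voxel data are written as doubles and round-trip
  exactly.

## Problem sizes

The bundled studies run at phantom scale, chosen so the full nine-variant
suite in both regimes, the replication checks and the cohort-invariant
checks complete comfortably on a single CPU: 30 subjects (20 train / 10
test) at 48³ for the pipeline studies, 60 subjects for the cohort
invariants, 200 random ≤ 6³ ROIs for the feature-engine oracle battery.
All statements the package makes about itself are recomputed by the test
suite and `scripts/acceptance.R`; nothing is quoted from elsewhere.

## Known limitations

* Feature families are limited to first-order, shape, GLCM, GLRLM, GLSZM;
  no filtered images (wavelet/LoG), NGTDM/GLDM, or per-slice extraction.
* Non-parametric ComBat priors and longitudinal designs are out of scope;
  so are image-space harmonization methods.
* The pipeline grammar is original to this package; it captures stage
  order and parameters but not arbitrary user-defined stages.
* Sequential execution only: parallel scheduling would complicate the
  determinism contract the package exists to provide.
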