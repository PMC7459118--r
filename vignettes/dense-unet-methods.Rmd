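---
title: "Dense U-nets for zonal prostate segmentation: models, phantoms and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dense U-nets for zonal prostate segmentation: models, phantoms and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(denseunet)
```

## The segmentation problem

T2-weighted MR shows prostate anatomy in detail, but delineating the gland —
and especially its zones — is hard: the capsule boundary is fuzzy, the tissue
is heterogeneous inside and outside the gland, and gland shape varies widely
between patients. This package implements a family of fully convolutional
encoder–decoder networks for slice-wise segmentation of axial MR-like volumes
into background, central zone (CZ, label 1) and peripheral zone (PZ, label
2), with the whole prostate defined as the union of the two zones. Everything
around the networks — preprocessing, augmentation, a synthetic phantom
generator, a full evaluation suite and a cross-validation harness — is part
of the package, so the complete training/evaluation protocol runs end-to-end
on seeded synthetic data without any patient images.

## Architectures

Both network variants share the same macro-structure: six encoder/decoder
stages plus a bottleneck, with feature widths doubling from 16 to 1024
(`network_spec()` defaults). Downsampling is 2×2 max pooling; upsampling is a
3×3 stride-2 transposed convolution that halves the feature count; mirrored
stages are joined by long skip concatenations; the head is a 1×1 convolution
to 3 channels followed by a pixel-wise softmax, so outputs sum to one at
every pixel and the networks are fully convolutional (the parameter count is
independent of input size).

* **Classical U-net** (`dense_blocks = 0`): two 3×3 conv+ReLU layers per
  stage. At full scale this is 34,604,147 trainable parameters.
* **Dense-X U-net** (`dense_blocks = X`, X ∈ 1..3): each stage is replaced by
  X DenseNet-style blocks. A block holds four 3×3 convolutions whose input is
  the channel concatenation of the block input and all previous layer outputs
  in the block, each emitting `growth` feature maps; a 1×1 *transition*
  convolution then compresses the concatenation back to the stage width, which
  keeps the stage interface homogeneous and the model compact. At full scale
  the Dense-2 variant has 15,570,939 parameters — 0.45× the classical
  baseline.

Design choices that were genuinely open, and how they were fixed:

* **Growth rate.** The per-stage growth defaults to `min(width / 8, 26)`
  (floored at one map). This convention was calibrated once so that the
  full-scale Dense-2 network lands on a 15.6-million-parameter budget, under
  half of the classical baseline, and it is locked by a parameter-count test
  against an independent closed-form enumeration. `growth` is exposed on
  `network_spec()` for reduced configurations, where `width/8` degenerates.
* **Transposed-convolution kernel.** 3×3 stride-2 (the common
  TensorFlow-era choice) rather than 2×2. With 2×2 kernels the Dense-2 /
  classical parameter ratio cannot drop below one half at this scale; the 3×3
  kernel keeps the halved-budget property that motivates the dense design.
* **Stage count reading.** "Six stages" is read as six pooling steps, i.e.
  seven resolution levels with widths $2^4 \dots 2^{10}$ and the 1024-wide
  level acting as the bottleneck.
* **No batch normalisation** anywhere — plain conv+ReLU — and He-uniform
  weight initialisation drawn from the session RNG (seed with `set.seed()`).
* **Block placement.** In a Dense-X stage all X blocks run before the
  pooling step; the decoder mirrors the encoder with block input
  `2 × width` after the skip concatenation.
* **Zonal output.** The head predicts three exclusive classes; the
  whole-prostate mask is derived as the union of the CZ and PZ predictions
  rather than being a separate output channel.

The engine itself (im2col convolutions via BLAS, pooling with argmax
bookkeeping, transposed convolutions composed from zero-insertion plus a
stride-1 convolution, hand-written backpropagation, Adam) lives in C++ via
Rcpp. Gradient correctness is tested against central finite differences for
every parameterised node type.

## Losses

Three pixel-wise losses and their combinations are available through
`loss_config()`:

* **Cross-entropy**: mean of $-(b\log a + (1-b)\log(1-a))$ over pixels and
  softmax channels, with $a$ the predicted probability and $b$ the one-hot
  target. We use the differentiable orientation — the logarithm acts on the
  prediction — since the gradient with respect to the prediction is what
  drives the optimiser. Probabilities are clipped at $10^{-7}$ before logs.
* **Focal**: $-(\alpha(1-a)^\gamma b \log a + a^\gamma (1-b)\log(1-a))$,
  defaulting to $\alpha = 1,\ \gamma = 2$; at $\alpha = 1, \gamma = 0$ it
  reduces exactly to cross-entropy (a property test asserts this to $10^{-9}$).
* **Soft Dice**: $1 - 2\sum ab /(\sum a + \sum b)$ averaged over the two
  foreground channels, with an $\varepsilon = 10^{-7}$ denominator guard for
  empty masks. On binarised inputs `dice_loss + dice_score = 1`.

Combinations (`dice+ce`, `dice+focal+ce`) are weighted sums with weights
defaulting to one; all-zero weights are rejected.

## Preprocessing and augmentation

The fixed preprocessing chain mirrors the acquisition target: resample every
slice to 0.5 mm pixels (bilinear for images, nearest-neighbour for labels, so
the label alphabet cannot change), crop a centred 256×256 window (offset
`floor((n-size)/2)`, ties toward the lower index; smaller inputs are
symmetrically zero-padded), and z-score each slice on the fly (sample SD;
constant slices map to zeros, making normalization invariant to affine
intensity rescaling).

Augmentation operates on image/mask slice pairs and always applies the same
geometric transform to both (bilinear vs nearest sampling). The elastic
recipe draws uniform noise in $[-1, 1]$, smooths it with a Gaussian of width
$\sigma$ (default 512 px — implemented exactly with dense row-normalised
smoothing operators, since $\sigma$ far exceeds the slice size) and scales by
$\alpha$ (default 21 px). $\alpha = 0$ is the exact identity. The four rigid
ops are flip, rotation, zoom and translation; their magnitudes are not fixed
by the protocol, so conservative seeded defaults (±15°, [0.9, 1.1], ±10 px)
are used and exposed. `augment_batch()` appends five elastic variants and/or
the four rigid variants per pair; when training with augmentation enabled the
variants are redrawn with a fresh derived seed each epoch. Out-of-bounds
samples are zero-filled, consistent with zero-padded crops.

## Synthetic phantoms

`phantom_params()` defaults encode the study conditions the package targets:
14–26 axial slices of 3.6 mm, 256×256 pixels at 0.5 mm, a gland with
superellipse cross-sections (random per-case semi-axes 17–26 mm × 13–20 mm,
exponent 2–2.5, centre jitter), an apex/base taper of the cross-section, a
simply connected CZ core obtained by shrinking the gland outline and shifting
it anteriorly — which makes the PZ rim posterior-weighted, as in real
anatomy — per-class mean intensities (PZ brightest, as on T2), a smooth
random intra-gland heterogeneity field, additive Gaussian noise, and optional
motion blur (normalised line kernel, intensity-conserving) plus TURP-cavity /
bladder toggles for qualitative failure modes. Background occupies ≥ 90% of
voxels, reproducing the class imbalance that makes the PZ the hardest
structure. Everything is a pure function of `(params, seed)`; cohort seeds
are derived deterministically from a master seed.

What the phantoms deliberately do **not** model: MR physics (bias fields,
k-space artifacts), true tissue texture, lesions, and anatomical neighbours
other than the optional bladder. Tests passing on phantoms therefore
demonstrate that the pipeline's machinery — optimisation, geometry, metrics,
protocol — is correct, not that the networks reach patient-data accuracy;
cohort-scale Dice values on real T2 data require the external dataset and
GPU-scale training and are explicitly out of scope here.

## Evaluation metrics

* **Dice**: $2|A\cap B|/(|A|+|B|)$; both-empty pairs score 1 and
  empty-vs-nonempty 0, so per-structure scoring never produces NaN.
* **RAVD**: $(|B|/|A|-1)\times 100$ with $A$ the ground truth; cohort
  aggregation uses the absolute value (MRAVD).
* **Hausdorff distance**: computed on boundary voxels (face-neighbour
  erosion difference; singleton axes use in-plane connectivity) with an exact
  anisotropic squared Euclidean distance transform, so distances are in mm
  for any voxel spacing. The default reported direction is prediction →
  ground truth, with a symmetric mode available.
* **Mean surface distance**: nearest-surface distances pooled over both
  boundaries and averaged; by construction MSD ≤ symmetric Hausdorff. (No
  single canonical formula exists for MSD; the pooled symmetric mean is the
  convention adopted and documented here.)
* **Sensitivity/specificity**: voxel-wise from the confusion counts.
* **Regional scoring**: the prostate-containing slice range is split
  25/50/25 with boundaries `floor(0.25 n)` / `floor(0.75 n)`; the first-index
  block is called the apex. With 20 gland slices this yields 5/10/5.
* **Cohort summaries**: mean Dice with a normal-approximation 95% CI
  (`1.96·sd/√n`), SD, median, MRAVD, mean HD/MSD, mean Sen/Spc — the column
  layout of the per-structure results tables.
* **Significance**: a two-sided paired t-test on per-case scores (cases are
  matched across model variants). Zero-variance differences are handled
  explicitly: p = 1 for identical vectors, p = 0 for a constant nonzero
  shift.

Hausdorff and MSD are verified against an exhaustive all-pairs brute-force
oracle on random mask pairs to $10^{-9}$ mm.

## Training protocol and the cross-validation harness

`train()` pools all axial slices of the training cases, shuffles them each
epoch under the config seed, and optimises with Adam (batch size 5 by
default) while logging the loss at every iteration; a non-finite loss raises
a divergence error. `make_folds()` produces seeded round-robin k-fold splits
— 188 cases at k = 4 give the 141-train / 47-test geometry — and
`run_experiment()` ties generation, training, prediction and evaluation
together, writing per-fold case metrics, pooled per-variant summaries and
pairwise paired t-tests (per fold and pooled) as CSV.

Numerical/config choices: the package default learning rate is 1e-4, a
conservative U-net default; full-scale iteration budgets (35,760 / 36,952)
are meaningful only with the external cohort and are provided as config
values, not defaults. Checkpoints are plain `.rds` files written at a
configurable cadence.

## Desk-scale problem sizes

The test suite and the worked examples run everything at reduced,
CPU-friendly sizes, chosen once as the package's own desk-scale conditions:
phantoms at 64×64 pixels (2 mm pixels, preserving the 128 mm field of view)
with 10–14 slices; a reduced Dense-2 network with four stages, base width 8
and growth 4 (the auto growth convention degenerates to one map at width 8);
200 Adam iterations at learning rate 1e-3 — the canonical Adam default,
appropriate for so short a budget — with batch 5 and cross-entropy. Under
these conditions the trained network reaches mean whole-prostate Dice ≥ 0.85
on held-out phantoms, which the acceptance test asserts; the experiment
harness is exercised at even smaller sizes (32×32, two folds) to keep the
suite fast.

## Known limitations

* Slice-wise 2D inference: no access to 3D context, by design.
* The conv engine is single-threaded CPU code built for correctness and
  desk-scale training; full-scale training is out of its intended range.
* `predict_volume()` on the full-scale networks keeps all intermediate
  activations of a slice in memory; use reduced specs for bulk phantom work.
* NIfTI headers store spacing as float32, so spacing round-trips to ~7
  significant digits (MetaImage headers keep full precision).
* The phantom generator's realism limits are listed above; conclusions about
  patient-data accuracy cannot be drawn from phantom scores.
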