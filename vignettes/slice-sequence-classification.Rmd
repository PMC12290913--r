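---
title: "Classifying brain MRI volumes as ordered slice sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying brain MRI volumes as ordered slice sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sliceformer)
```

## The model

sliceformer classifies a 3D structural brain MRI into one of three diagnostic
groups — normal control (NC), mild cognitive impairment (MCI), Alzheimer's
disease (AD) — by treating the volume as an *ordered sequence of 2D slices*.
The pipeline has two stages:

1. **Per-slice features.** The volume (already skull-stripped and registered
   to MNI space upstream) is sectioned along one anatomical plane, the
   central 50 slices are kept, each is resized to 224 × 224 pixels, and a
   patch-based encoder maps each slice to a feature vector. The patch
   geometry is the standard patch-16 layout: a 224-pixel slice becomes a
   14 × 14 grid of 16 × 16-pixel patches (196 patches). The encoder is a
   pluggable backend: a pretrained vision-transformer encoder can be supplied
   externally through `encoder_backend("pretrained_vit", encode_fun = ...)`,
   while the default `stub_projection` backend — a seeded random linear map
   of the 196 per-patch mean intensities — keeps the pipeline deterministic,
   dependency-free, and testable offline. Grayscale slices are replicated to
   three channels before encoding, matching what natural-image-pretrained
   encoders expect.

2. **Sequence classification.** The resulting `50 × feature_dim` matrix is
   classified by a transformer encoder: sinusoidal positional encoding added
   to the inputs, `n_blocks` pre-layer-norm blocks of multi-head scaled
   dot-product self-attention
   (per head, $\mathrm{softmax}(QK^\top/\sqrt{d_h})V$ with learned
   projections) plus a position-wise two-layer ReLU feed-forward map, pooling
   over the sequence axis, and a dense softmax head trained with categorical
   cross-entropy. Self-attention lets the classifier use relationships
   between anatomically distant slices; the positional encoding is what
   makes slice *order* visible to it.

Evaluation uses stratified 10-fold cross-validation at the subject level:
per class, subjects are shuffled once with the seed and dealt round-robin
into ten disjoint test buckets; each fold's remaining subjects are split
80/20 into training and validation. Per-fold confusion matrices yield
accuracy, balanced accuracy (mean per-class recall) and macro-averaged
precision/recall/F1, which are averaged across folds with a sample standard
deviation.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `k` (central slices) | 50 | slices kept around the stack midpoint; window start is `floor((N - 50)/2)` |
| `side` | 224 px | slice resolution after bilinear resize |
| `patch_side` | 16 px | patch edge for the encoder geometry |
| `feature_dim` | 64 | encoder output width (a configuration, not a fixed constant of the method) |
| `n_blocks`, `n_heads`, `head_dim`, `ff_dim` | 2, 4, 32, 128 | transformer capacity; small enough for a single CPU, standard for length-50 sequences |
| `dropout` | 0.1 | on both residual branches during training |
| `learning_rate`, `batch_size` | 1e-3, 16 | Adam optimiser settings |
| `max_epochs`, `patience`, `min_delta` | 100, 10, 1e-4 | early stopping on validation loss; improvements smaller than `min_delta` consume patience, so training stops soon after the loss plateaus |
| `n_folds`, `val_frac` | 10, 0.2 | cross-validation protocol |

Design choices where the method itself leaves the decision open:

* **Positional encoding is sinusoidal, not learned** — deterministic,
  parameter-free, and directly testable against its closed form
  (`positional_encoding()`).
* **Pre-layer-norm block placement** — more stable than post-norm at small
  scale; with all projection weights zero the block is exactly the identity,
  a property the tests exploit.
* **Pooling** is global average by default; attention pooling (a learned
  scoring vector, softmax over slices) is available via
  `model_config(pooling = "attention")`.
* **No input projection when `d_model = feature_dim`** (the default): the
  slice features enter the blocks at their own width. Setting `d_model`
  inserts a single linear map.
* **Argmax ties** break toward the lower class index (NC < MCI < AD), so
  evaluation is deterministic.
* **Label encoding** is fixed: NC = 0, MCI = 1, AD = 2.
* **Central-window tie-break**: when `N - k` is odd the extra discarded
  slice comes from the top of the stack (floor convention).
* **PNG intensity mapping** is per-slice min-max to 8-bit; a constant slice
  maps to mid-gray. Filenames carry the zero-padded source index so
  lexicographic order is anatomical order.
* **Plane-to-axis mapping** comes from the NIfTI orientation codes; volumes
  without usable orientation metadata are assumed RAS with a warning.

## What the synthetic generators emulate

Real cohort data cannot ship with a package, so two seeded generators stand
in for it; both are first-class, tested code.

**Phantom volumes** (`make_phantom_volume()`) are concentric ellipsoids: a
"brain" of elevated intensity (0.8) with an internal low-intensity cavity
(0.1) standing in for the ventricular system, plus Gaussian voxel noise,
clipped to [0, 1]. The cavity-to-brain radius ratio grows with stage —
NC 0.15, MCI 0.25, AD 0.35 — mimicking the direction of ventricular
enlargement with atrophy. This geometry is analytically checkable (cavity
voxel counts order as NC < MCI < AD under a half-maximum threshold) and
exercises slicing, central-window selection, resizing and encoding, but it
is *not* anatomy: no cortex, no bias field, no Rician noise, no
registration error.

**Feature sequences** (`make_feature_dataset()`) emulate what the encoder
produces: class `c` rows are
$\mu_c + a\,\sin(2\pi p/50)\,\mathbf{u} + \varepsilon$, with class means
offset by `separation` noise-sd units along orthogonal coordinate
directions, a slice-position-dependent component of amplitude
`positional_signal` along the normalised all-ones direction, and unit
Gaussian noise. `separation` controls how recoverable the classes are;
`positional_signal` makes slice order informative, which the
order-sensitivity checks rely on. One global seed expands to per-subject
sub-seeds (`seed + subject index`), so any single subject is reproducible
in isolation.

The standard demonstration cohort is 20 subjects per class (balanced — no
cohort proportions are being reproduced, this is a choice), 50 × 64
sequences, separation 6, positional signal 1. At separation 6 the classes
are trivially separable by construction (a nearest-centroid rule on sequence
means is already perfect), so the cross-validated demo measures whether the
*pipeline* — folds, training loop, early stopping, evaluation — recovers
structure that is present, and stays at chance (1/3) when `separation = 0`
removes it. Passing these checks says nothing about accuracy on clinical
MRI, where class overlap, scanner effects and registration error dominate;
clinical-scale performance additionally requires real pretrained encoder
weights, which are deliberately out of scope.

## Numerical choices

* Training is full backpropagation through the attention blocks, hand-derived
  and verified against central-difference numerical gradients (tolerance
  1e-5 elementwise) in the test suite.
* Layer norm uses $\epsilon = 10^{-5}$; softmax rows are max-shifted before
  exponentiation; the cross-entropy loss clamps probabilities at 1e-12.
* Early stopping restores the best-validation parameters; `max_epochs = 0`
  returns the seeded initial model untouched.
* One config seed governs initialisation (drawn under `seed`) and the
  training loop's shuffling and dropout (drawn under `seed + 1`); reruns on
  equal data reproduce histories exactly on a deterministic BLAS, and the
  tests assert equality within 1e-3.
* Bilinear resizing is center-aligned and clamped to the input range; an
  input already at the target size is returned unchanged, and a 2× downsample
  of a 2 × 2 block pattern equals the block means exactly.
* Metric ratios of the form 0/0 (e.g. precision of a never-predicted class)
  are defined as 0 with a warning, so degenerate folds aggregate
  deterministically.
* Matrices persist as full-precision text (17 significant digits), which
  round-trips IEEE doubles exactly.

## Problem sizes

The package's own demonstrations and tests run at deliberately modest sizes:
the cross-validated demo uses 60 subjects with 50 × 64 feature sequences and
completes in a couple of minutes on one CPU; phantom-based image-path tests
use 16³–32³ voxel volumes and 6–8 slice windows. Larger inputs are generated
at run time by the same seeded code, never stored.

## The demo's two modes

`run_demo()` runs the whole workflow and returns an `eval_report`. Its
default `"features"` mode generates feature sequences directly — these are
the conditions under which the recovery properties above are stated, since
the separation knob lives in the feature generator. The `"phantom"` mode
runs the full image path (phantom NIfTI → plane slicing → central window →
resize → PNG folders → stub encoding) before the same fold/train/evaluate
steps; its class signal comes from the stage-dependent cavity size. The
stage runner `run_stage()` exposes the same workflow as five restartable
steps with hashed-input manifests, mirroring script-by-script use.

## Known limitations

* The stub encoder is a fixed random projection: good for determinism and
  order sensitivity, blind to texture. Clinical use requires an external
  pretrained encoder via `encode_fun`.
* Phantoms are geometric, not anatomical; results on them do not transfer
  to real T1 volumes.
* Training is single-threaded R; the defaults target length-50 sequences
  and cohorts of tens to hundreds of subjects, not thousands.
* Registration, bias correction and skull-stripping are assumed done
  upstream and are out of scope.
* No nested or repeated cross-validation; no model-comparison statistics.
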