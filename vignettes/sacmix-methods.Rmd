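---
title: "Spatial-attention ConvMixer: model, pipeline and design notes"
author: "sacmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial-attention ConvMixer: model, pipeline and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sacmix)
```

## The problem and the model

Gastrointestinal endoscopy produces large volumes of frames that must be
sorted into findings (polyps, esophagitis, ulcerative colitis, dye-marked
lesions and resection margins) and normal anatomy. `sacmix` implements a
compact classifier for this task: a **ConvMixer** backbone whose patch
embedding is gated by a **spatial-attention** map.

The network, for an $n \times n \times 3$ input with patch size $p$,
hidden width $h$, depth $d$ and depthwise kernel $k$:

1. **Patch embedding (stem).** A convolution with $h$ filters of size
   $p \times p$ and stride $p$ turns the image into an
   $(n/p) \times (n/p) \times h$ grid of patch tokens, followed by GELU
   and BatchNorm. With the defaults ($n = 128$, $p = 2$, $h = 256$) the
   grid is $64 \times 64 \times 256$, and every later stage preserves
   that extent.
2. **Spatial attention.** A $1 \times 1$ convolution projects each
   location's $h$-vector to a single scalar; a sigmoid maps it to a gate
   $a(x, y) \in (0, 1)$; the feature map is multiplied by the gate,
   broadcast across channels. The gate costs exactly $h + 1$ trainable
   parameters ($256 + 1 = 257$ at the default width) and is applied once,
   between the stem and the first mixer block.
3. **$d$ ConvMixer blocks.** Each block mixes spatial positions with a
   per-channel (depthwise) $k \times k$ convolution inside a residual
   branch and mixes channels with a pointwise ($1 \times 1$) convolution,
   with GELU activations and BatchNorm. Same-padding keeps the spatial
   extent fixed.
4. **Head.** Global average pooling collapses the grid to an $h$-vector;
   a dense layer and softmax produce the class distribution (6 classes by
   default).

### Block ordering

Published descriptions of this architecture family differ in where the
second activation/normalization pair sits. `sacmix` ships both orderings
behind `model_config(block_order = ...)`:

* `"table1"` (default): depthwise → GELU → BN → residual add → GELU →
  BN → pointwise. This follows the layer-by-layer summary table of the
  architecture we implement.
* `"original_convmixer"`: residual(depthwise → GELU → BN) → pointwise →
  GELU → BN, the ordering of the original ConvMixer description.

The two orderings contain exactly the same parameter tensors, so all
parameter accounting is identical between them (a tested invariant); only
the arrangement of the nonlinearities differs. Which one the original
authors trained cannot be determined from the text alone, so the explicit
table was taken as authoritative and the alternative kept one switch away.

Similarly, whether the attention gate multiplies the raw stem convolution
output or the normalized activations is not settled by the source
figures; `sacmix` gates the post-GELU/BatchNorm activations (the gate then
reweights normalized features, which keeps its sigmoid input
well-scaled). Parameter counts are unaffected.

### Parameter accounting

`count_trainable_params()` evaluates the closed form

* stem: $p^2 \cdot 3h + h$ (conv weights + biases) $+\,2h$ (BN scale/shift),
* gate: $h + 1$ (or 0 when disabled),
* per block: $(k^2 h + h) + 2h + (h^2 + h) + 2h$,
* head: $hC + C$,

and `n_trainable_params()` independently counts the allocated arrays of a
built model. With defaults: 593,415 with the gate, 593,158 without,
difference 257. BatchNorm running means/variances are state, not
parameters, and are excluded. All convolutions and the dense layer carry
biases and every BatchNorm has trainable scale and shift — dropping any
of these would break the totals above, which pins the convention.

## Why the network is implemented in base R

The model, its backward pass, the AdamW optimizer and the Grad-CAM
gradients are implemented directly on base-R matrices and arrays. Feature
maps are stored as an $(H \cdot W \cdot B) \times C$ matrix, which makes
the pointwise convolution one BLAS matrix multiply, BatchNorm a column
operation, and the attention gate a row operation; the depthwise
convolution is evaluated as $k^2$ shifted, channel-weighted additions of
the zero-padded tensor. Gradients are hand-derived per layer and verified
against central finite differences in the test suite (relative error
$\sim 10^{-5}$ on every parameter group, both block orderings), and the
depthwise/pointwise layers are checked entrywise against deliberately
naive nested-loop oracles.

Numerical conventions: exact (erf-based) GELU $x\,\Phi(x)$; BatchNorm
$\varepsilon = 10^{-5}$ with population batch statistics and running
statistics updated with momentum 0.9 (exponential average retaining 90%
of the previous value — at the few-hundred-step scale of the runs in this
package a slower average would leave inference statistics badly stale);
Glorot-uniform weight initialization with zero biases, seeded; softmax
computed with row-max subtraction; argmax ties broken toward the first
class for determinism.

## Data pipeline

The raw layout is one folder per class, eight classes: five findings
plus three anatomical "normal" landmark folders.

* `merge_normal_classes()` collapses the three normal folders into one
  `normal` label (conserving records), after which `normal` holds three
  times the images of any other class.
* `balance_with_augmentation()` restores balance by adding a horizontally
  mirrored and a 180°-rotated copy of every record of the five non-normal
  classes. Both transforms are pixel-exact involutions and are applied
  lazily at load time; provenance (`original` / `mirrored` /
  `rotated180`) and the parent image are recorded in the manifest.
  The mirror axis is not specified by the recipe we follow; horizontal
  was chosen. Geometric augmentation of `normal` is refused (with a
  warning) in paper-faithful mode.
* Random brightness — one scalar shift per image, uniform in ±0.2 on the
  [0, 1] scale, clipped — is applied on the fly to training batches of
  all six classes. Treating brightness as dynamic and the geometric
  balancing as static is the only reading that both balances the class
  counts and leaves the printed per-class supports reproducible.
* `split_manifest()` stratifies 70/15/15 per class. Two modes:
  `paper_faithful` splits after balancing, which with 3,000 records per
  class yields the published 2,100/450/450 per-class partition;
  `leakage_safe` splits the originals first and keeps derived copies only
  in the training partition, so no mirrored/rotated twin of a test image
  can be trained on. The faithful mode reproduces the published
  arithmetic; the safe mode is what we would recommend for new work, and
  `audit_leakage()` verifies the property exhaustively.

Class order is fixed alphabetically everywhere so confusion matrices are
reproducible. Grayscale inputs are replicated to three channels rather
than rejected; images are resized bilinearly to the network input size.

## Training recipe

`train_config()` defaults: AdamW (β₁ = 0.9, β₂ = 0.999, ε = 1e-8),
learning rate 0.001, decoupled weight decay 0.0001 (not applied to
BatchNorm parameters), batch size 32, 25 epochs, categorical
cross-entropy, no label smoothing. After each epoch the model is
evaluated on the validation split; weights are checkpointed on strict
validation-accuracy improvement, and the learning rate is multiplied by
0.5 after 3 epochs without validation-loss improvement (floor 1e-6,
waiting counter restarting after each reduction). The plateau
factor/patience and floor are not stated in the recipe we follow; these
are declared defaults, not inferences. `plateau_step()` exposes the rule
as a pure function of the loss history, and a test replays it against
the recorded schedule of a real run.

## Evaluation

`confusion_matrix()` uses truth-rows/prediction-columns. Accuracy is
$100 \cdot \mathrm{trace}/\mathrm{total}$ — the only multi-class reading
of the binary TP/TN form consistent with the published report, where
overall accuracy equals macro recall under equal supports (both 93.37 on
the published matrix). Precision is column-based, recall row-based, F1
their harmonic mean; zero denominators yield flagged zeros. Macro
averages are unweighted means, weighted averages support-weighted means.
Printed reports round to 2 decimals; serialized JSON keeps raw floats.
The arithmetic is cross-checked in tests against an independent reference
implementation (caret) on random label vectors to 1e-10.

## Grad-CAM

`compute_cam()` differentiates the pre-softmax class score with respect
to the final convolutional feature map (the pointwise output feeding
GAP). For a GAP + linear head this gradient is constant over space —
`head_W[, class] / (H·W)` — so the channel weights reduce to the head
weights of the target class; the general gradient-weighted formulation is
kept because it is the definition being implemented, and an analytic
closed form on a toy linear-head model serves as the test oracle. The
raw map is the ReLU of the weighted channel sum, normalized by its
maximum (an all-zero map stays zero), then bilinearly upsampled to input
resolution. Overlays blend a blue-to-red colormap with per-pixel opacity
`alpha × heat` (default alpha 0.4), so zero-activation regions show the
untouched image — which also makes repeated zero-overlay idempotent.
The published overlay renderings cannot be matched pixel-for-pixel (the
trained weights are not public); only the mechanism is reproducible.

## Synthetic fixtures

`generate_fixture_dataset()` writes an eight-folder tree shaped like the
real collection, with one procedural motif per class over correlated
noise: bright ellipse (polyp-like), green-blue tint with an ellipse or a
dark ring (dye-like), periodic bright streaks (esophagitis-like), bright
speckles on a red base (colitis-like), and three smooth mucosa variants
for the normal folders. Optional burned-in white glyph blocks and a dark
frame border mirror two artifacts of real endoscopy frames. Generation is
a pure function of the `fixture_spec()` — identical specs give
byte-identical PNG trees — and the caller's RNG stream is left untouched.

The motifs are deliberately easy: distinct in hue and structure, so that
a nearest-centroid rule on raw pixel statistics already separates the
classes and a small network can overfit quickly. Passing tests on these
fixtures therefore demonstrate that the pipeline, optimizer and gradients
work — not that the model reaches any particular accuracy on real
endoscopy data, which is far harder (fine texture distinctions,
illumination variation, class overlap) and out of scope here.

## Problem sizes used by the tests

The full-size model (593k parameters on a 64×64×256 grid) is built and
introspected in tests, but trained models use reduced widths: the
overfit-sanity check trains a patch-8 / width-32 / depth-2 / kernel-3 SAC
on the fixed 60-image, 128-px benchmark (batch 8, 30 epochs, brightness
augmentation off, since the sanity property being checked is that the
optimizer can drive training accuracy to 100%, not robustness to
photometric jitter), and the end-to-end pipeline test runs a width-8
model on 32-px fixtures for two epochs. These sizes are the package's own
choice of desk-scale problems: training the full model to its published
93.37% accuracy requires the real dataset and GPU-scale compute, and is
explicitly not attempted.

## Known limitations

* No burned-in-text removal: real endoscopy frames often carry overlay
  text; the fixtures can reproduce the artifact, but the pipeline does
  not mask it.
* `paper_faithful` splitting lets augmented twins of an image straddle
  the train/test boundary; that is faithful to the arithmetic being
  reproduced but optimistic as an evaluation protocol. Use
  `leakage_safe` for anything beyond reproduction.
* The training engine is single-threaded CPU R; it is intended for
  fixture-scale experiments, not for the real dataset.
* No segmentation, bounding boxes, video, ROC/AUC or calibration — the
  surface mirrors what the implemented report provides.
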