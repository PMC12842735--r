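---
title: "Masked deep embedding pre-training and two-stage implant detection: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Masked deep embedding pre-training and two-stage implant detection: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mdeimplant)
```

## The problem

Identifying the commercial system of a dental implant from a panoramic or
periapical radiograph is a recurring clinical need when treatment records
are unavailable. The approach implemented here combines two ideas:

1. **Self-pre-training with masked image modeling.** A vision transformer
   (ViT) is pre-trained on the task's *own* training images — no external
   corpus — by hiding a random subset of image patches and training the
   network to predict their content from the visible context. This removes
   any domain gap between pre-training and fine-tuning data, which matters
   when the target domain (dental radiographs) looks nothing like natural
   images.
2. **Two-stage detection with part grouping.** Rather than detecting whole
   implants directly, stage 1 detects the three *design parts* of an
   implant — the coronal (platform), middle (threaded body) and apical
   (tip) thirds — and stage 2 groups part detections into implants
   geometrically and infers a single bounding box per implant.

## The MDE objective

Classic masked autoencoders (MAE) reconstruct the raw pixels of masked
patches under a mean-squared-error loss. The *masked deep embedding* (MDE)
objective implemented here replaces the pixel target with the **deep patch
embedding** of the original (uncorrupted) patch: if `E = tok(X)` is the
patch-embedding map applied to the patch matrix `X`, the decoder must
predict `E[masked, ]` and the loss is the mean absolute (L1) difference
over all masked-position embedding coordinates,

```
L = mean_{k in masked, d} | pred[k, d] - E[k, d] |.
```

Both objectives share all machinery except the prediction head and the
loss: `run_pretraining(images, cfg, objective = "mde")` vs `"mae"`.

Routing follows standard MAE practice: the encoder processes **visible
tokens only** (with fixed 2-D sine-cosine positional encodings added); the
decoder receives the full-length sequence in which every masked slot holds
one shared learnable mask token plus its positional encoding, and a linear
head reads out predictions at masked positions. A configuration switch
(`simmim_routing = TRUE`) implements the alternative routing in which the
corrupted full-length sequence is fed to the encoder itself, for
comparison.

**Target branch and collapse.** The embedding targets come from the
model's *own, current* tokenizer applied to the original patches, with
gradient flow into the target branch severed (`detach_target = TRUE`, the
default). The stop-gradient is the minimal anti-collapse device: without
it, the tokenizer receives a direct incentive to shrink all embeddings
toward a constant. The non-detached mode is implemented for ablation. No
per-patch target normalization is applied by default.

**Loss reduction** is the mean over (masked patches x embedding
dimensions), which makes loss values comparable across mask ratios.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `image_size` | 416 px | square input side (full-scale recipe) |
| `patch_size` | 16 px | ViT patch side; `image_size` must be divisible |
| `mask_ratio` | 0.25 | fraction of patches hidden; count is `round(r*N)` (half-up) |
| `base_lr` | 1.5e-4 | AdamW base learning rate (pre-training) |
| `weight_decay` | 0.05 | decoupled decay, weight matrices only |
| `beta1`, `beta2` | 0.9, 0.95 | AdamW moments |
| `warmup_epochs` | 10 | linear ramp 0 to `base_lr` |
| `total_epochs` | 100 | cosine decay to 0 after warmup |

The learning rate at (fractional) epoch `e` is `lr_at(e, cfg)`: linear
warmup then `base_lr * 0.5 * (1 + cos(pi*(e - warmup)/(total - warmup)))`.
The training loop evaluates the schedule at epoch midpoints, so neither the
first nor the last epoch trains at a degenerate rate of exactly zero.

The fine-tuning recipe uses starting learning rate 1e-4 and weight decay
0.05 at full scale. `run_config_tiny()` provides the CPU-scale preset used
throughout the tests (64x64 images, 8x8 patches, 2-layer 64-dim encoder,
1-layer 48-dim decoder) with raised learning rates (1e-3 pre-training,
2.5e-3 fine-tuning as used in the test harnesses): tiny models trained with
4-16-image batches need, and tolerate, larger steps.

**Batching.** The full-scale recipe treats one epoch as one effective
batch over the whole training set. The implementation trains with
mini-batches (`batch_size`, gradients averaged within a batch, one AdamW
step per batch) and holds the learning rate constant within an epoch; for
the convex-combination gradients involved this is the standard
approximation to full-batch epochs and is what the epoch-level schedule
assumes.

Epoch budgets default to 100: longer masked pre-training has been observed
to *hurt* downstream detection in this domain, and the mask-ratio/epoch
sweep driver (`run_mask_ratio_sweep()`) exists to reproduce that kind of
study at synthetic scale. No claim is made that synthetic-scale trends
match full-scale radiograph results.

## The synthetic radiograph generator

Real dental radiograph datasets with design-part annotations are not
redistributable, so `generate_dataset()` emulates their *structure*:
vertically oriented, bright (radiopaque-like) screw silhouettes over a
smoothed-noise background, each composed of a wide coronal platform, a
threaded middle body (alternating intensity bands), and a tapering apical
tip with an optional darker hole. Three synthetic system classes with
distinct geometry priors (height, body aspect, platform widening) stand in
for commercial systems; design attributes are drawn per part level from
weights matching a realistic class imbalance (coronal
bone:tissue:microthread:no-threads = 1240:870:410:208, middle
parallel:tapered:v-shaped = 1935:621:382, apical
hole-round:hole-oblong:apex-cone:apex-flat = 1710:545:364:188). Only a
representative subset of design subclasses is rendered *distinguishably*;
the remaining taxonomy entries would be label-only aliases, since their
visual realization cannot be validated against any reference.

Annotations are exact by construction: each part box is the bounding box of
the rendered part's pixel support and each implant box is the tight union
of its three part boxes. Patients are assigned in configurable group sizes
(the number of images a real patient contributes is unknown, so it is a
parameter, not an assumption).

What the generator does **not** emulate: anatomy (bone, teeth, sinuses),
projective distortion, exposure variation, metal artifacts, overlapping
implants and prosthetics. Tests passing on synthetic data therefore
demonstrate that the *pipeline machinery* (losses, masking, training
dynamics, grouping geometry, evaluation) is correct — not that the trained
tiny models would transfer to clinical images.

## Stage-1 detector

The pre-trained encoder initializes a detection backbone; its stride-`P`
token map is the native feature map (for the full-scale 416/16 geometry
this is the stride-16 map), from which a simple feature pyramid at strides
4/8/16/32 is built by lateral projection plus nearest-neighbor upsampling
and average pooling. A full Mask R-CNN reimplementation is deliberately out
of scope: the detector is a pluggable contract — anything that emits scored
part boxes can feed stage 2 — and the minimal head keeps every moving part
verifiable. The dense anchor-free head predicts per cell: softmax class
logits (background + part classes) trained with a class-weighted focal
loss (inverse-frequency weights computed from the training split), box
offsets `(dx, dy, log w, log h)` in stride units under an L1 loss, and an
implant-system hint (softmax over systems) used later for assembly voting.

Design choices made where the design was genuinely open:

- **Cell assignment**: a cell is positive when its center lies inside a
  ground-truth box, ties to the smallest box. A center-cell-only variant is
  implemented (`scheme = "center"`) but starves tiny models of positives.
- **Box/system heads are 2-layer MLPs** (hidden width `2*d_enc`): purely
  linear heads plateau around 2 px per-coordinate error, which is fatal at
  IoU 0.5 for parts ~10 px across.
- **Box voting**: after greedy per-category suppression, each kept box is
  replaced by the score-weighted average of all pooled candidates
  overlapping it (pool floor 0.05). Adjacent-cell predictions are
  independent noisy estimates of the same box, so averaging reduces
  localization noise roughly like a square root.
- **Suppression criterion**: a same-class candidate is suppressed when it
  overlaps a kept box above IoU 0.35 *or* its center lies within 0.7 part
  diagonals of the kept center. Noisy duplicates of one part often overlap
  their rival by less than any workable IoU threshold, while two genuine
  same-class parts belong to different implants and are never that close;
  `dist_factor = 0` restores pure IoU NMS.
- **Flip TTA** (`predict_parts_tta()`): candidates pooled from the image
  and its two flips before the same merge; used by the evaluation
  harnesses.
- **Box calibration**: after training, per-class median center offsets and
  size ratios of matched predictions are fitted on the training images and
  applied at inference — a train-data-only correction of systematic
  regression bias.

## Stage-2 assembly

Given scored part detections for one image:

1. **Implant count**: the number of coronal detections when at least one
   exists (each complete implant has exactly one), otherwise
   `ceiling(n/3)`. Taking the cluster count equal to the number of part
   detections would yield singleton clusters, so the count is tied to
   implants; the literal rule remains available (`literal_k = TRUE`).
2. **Grouping**: k-means on box centers, k-means++ seeding, at most 300
   Lloyd iterations, best of 10 restarts. Centers are rescaled before
   clustering (vertical coordinate x 0.25 by default): one implant's parts
   spread vertically much farther than neighboring implants are separated
   horizontally, and isotropic k-means groups height bands instead of
   implants. Isotropic mode: `axis_scale = 1`.
3. **Refinement**: within each group at most one member per part level
   survives (highest score); members farther from the group median center
   than an adaptive cap are discarded with a logged reason. Groups reduced
   below two part levels by such discards are dropped; untouched
   single-part groups are kept.
4. **Missing parts**: a missing middle with both neighbors present is
   interpolated linearly along the implant axis between them; a missing end
   part is extrapolated from the middle using the default
   coronal:middle:apical height ratio 0.25:0.5:0.25, oriented by the
   observed part order along the axis (so 90-degree-rotated implants are
   handled).
5. **Implant box**: tight union of member and inferred boxes; score = mean
   member score; system class by highest total hint score (ties to the
   highest single score).

## Evaluation

`average_precision()` implements COCO-style AP: greedy one-to-one matching
in descending score order at an IoU threshold, 101-point interpolated
precision-recall integration, reported x100. `evaluate_detections()`
always emits both AP50 and the 0.50:0.05:0.95 average; published
"APbox" figures in this literature are usually AP50, so AP50 is the
headline column, but both are reported. Crowd/ignore regions are not
supported. `crossval_evaluate()` splits at patient level with one fixed
test set (greedy bin-packing of patients by descending image count into
capacity-targeted sets; the remainder goes to the designated test set, so
5,572 singleton patients yield four sets of 1,114 and a 1,116-image test
set) and reports per-iteration AP plus mean and standard deviation.

## Numerical choices and degenerate inputs

- Mask count rounding is half-up; masks of 0 or N patches are errors.
- Layer norm uses eps 1e-6; attention scales by `1/sqrt(d_head)`; GELU is
  the exact `x * pnorm(x)` form.
- AdamW decays weight matrices only (not biases, layer-norm parameters or
  the mask token), eps 1e-8.
- Depth-0 encoder/decoder stacks are exact identities (used by contract
  tests).
- The embedding-head reconstruction preview inverts the affine tokenizer by
  SVD pseudo-inverse; it is qualitative only and never feeds any loss.
- k-means++ seeds receive 1e-9 jitter to guard against duplicate seed
  points; `k = n` and `k = 1` bypass clustering entirely.
- All randomness derives from one root seed through named substreams
  (`substream_seed`), so any stage is independently reproducible.

## Problem sizes used by the test and acceptance harnesses

Pre-training convergence runs use 64 synthetic 64x64 images and a tiny
2-layer/64-dim model for 200 optimizer steps; the detection experiment
trains on 100 easy synthetic images (one implant each, low noise) for 150
epochs and evaluates part-level AP50 on 60 held-out images; assembly is
exercised at the full 416x416 geometry with jittered oracle parts
(truncated-normal jitter, sd 0.5 px, clipped at +-2 px — an upper-bound
stand-in for a perfect stage-1 detector). These sizes keep every run inside
a few CPU-minutes while remaining large enough for the reported quantities
to be stable.

## Known limitations

- The backbone is a tiny ViT trained by hand-written backprop on CPU;
  full-scale (ViT-B, 416x416, thousands of images) training is out of reach
  here, and published full-scale AP values are not reproducible by this
  package's harnesses.
- The synthetic generator's realism limits are listed above; absolute AP
  values on synthetic data say nothing about clinical performance.
- The assembly stage assumes near-vertical implants by default; heavily
  tilted implants need `axis_scale = 1` and looser consistency thresholds.
- Only boxes are modeled (no masks), and crowd annotations are unsupported.
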