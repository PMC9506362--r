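---
title: "Skeleton-sequence gait representation learning: models and methods"
author: "gaitseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Skeleton-sequence gait representation learning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitseq)
```

## The problem

Gait — the way a person walks — is a biometric that needs no subject
cooperation and survives changes of clothing and appearance. Working from
2D pose-tracker output (18 keypoints with confidences per frame, grouped
into tracklets by an upstream tracker) rather than silhouettes keeps only
movement information, which is both more privacy-preserving and more
transferable. This package implements the full chain: cleaning and
normalizing raw tracklets into a corpus, self-supervised pretraining of a
transformer encoder where *each tracklet is its own identity*, and the
evaluation protocols for recognition, gender and pedestrian-attribute
estimation.

Because real surveillance-derived corpora are large, credentialized and
unnecessary for verifying the machinery, the package ships a kinematic
walker simulator that generates tracker-style data with known identity
and attribute structure. Every claim the test suite makes is computed on
that synthetic population.

## Corpus construction

The cleaning pipeline (`build_dataset()`) applies, in order:

1. **Frame confidence filter** — frames whose mean confidence over the 18
   joints is below 0.5 are removed; "below" is strict, so a frame at
   exactly the threshold is kept. The same rule with threshold 0.4
   applies to the mean ankle confidence, because leg movement carries
   most of the gait signal.
2. **Duration filter** — tracklets shorter than `T * fps / 24` source
   frames are dropped (`T = 48`; at 24 fps that is roughly two full gait
   cycles). The filter runs in source-fps units *before* resampling, and
   after frame removal (the stricter of the two possible orders).
3. **Pace unification** — linear interpolation of every coordinate and
   confidence channel resamples each stream to the 24 fps reference pace,
   preserving wall-clock duration.
4. **Normalization** — each frame is centered at the pelvis (defined as
   the hip midpoint; the 18-joint layout has no explicit pelvis joint)
   and scaled per axis: x by the absolute shoulder span, y by the
   absolute neck–pelvis distance. Absolute values keep image-style
   y-down data from flipping sign. A guard `eps = 1e-6` protects against
   degenerate frames (for example a frontal collapse of the shoulder
   span); such frames are flagged rather than dropped — removal is a
   filtering decision, not a normalization one.
5. **Leg-speed band** — sequences whose mean per-frame leg-joint
   displacement (knees and ankles, in normalized units at the reference
   pace) falls below 0.0015 (standing) or above 0.09 (erratic pose
   estimates) are removed. The band is applied after normalization and
   resampling because the thresholds are scale- and pace-dependent.

Frame removal leaves gaps the original papers on such pipelines are
silent about. Here interior gaps of at most 12 frames (half a second at
the reference pace) are refilled by linear interpolation; longer gaps
split the tracklet into independent tracklets. The rationale: pace-aware
training assumes temporal continuity, and splicing across a long gap
would fabricate a motion that never happened.

## Attribute annotation

A pluggable ensemble of pedestrian-attribute predictors (one per source
vocabulary) annotates pedestrian crops sampled every `T` frames. Each
crop is predicted on `k = 4` randomly augmented copies (flip, small
rotation, mild color jitter) and averaged; crop-level predictions are
pooled over the sequence with weights proportional to bounding-box area,
since nearer pedestrians are more legible. Source vocabularies are
coalesced onto 42 target attributes in 8 groups through a shipped,
user-overridable YAML map in which every source label either maps to a
target (combined by `average` for same-concept labels or `max` for
union-style merges) or is explicitly dropped as unrecoverable from
movement. Labels remain soft probabilities throughout — training against
them is a distillation of the annotating ensemble, and rounding would
discard exactly the calibration that makes noisy labels usable.

The 42-name membership and the per-label merge modes are a reconstruction:
the available sources document the groups, the source vocabularies and
example merges, not the full table. Shipping the map as data rather than
code makes that reconstruction auditable and replaceable.

## Model

Each skeleton frame flattens to a 54-d token — 18 joints × (x, y,
confidence); the confidence channel is deliberately kept, as 18 × 3 = 54,
and gives the encoder a per-joint reliability signal. Tokens are linearly
projected to `d_model`, a learnable positional embedding is *added* (not
concatenated, to keep dimensionality), and a standard post-norm
transformer encoder processes the sequence. Token representations are
mean-pooled over time, making output shapes independent of sequence
length. Three linear heads follow: the identity embedding (256-d in the
stock sizes), a 128-d projection on which the contrastive loss operates
(applying the loss on a lower-dimensional projection is standard
practice), and a 42-d sigmoid appearance head.

The stock sizes are 4/8/12 encoder layers with `d_model = 256` and 8
heads, totalling 2,244,266 / 4,352,682 / 6,461,098 trainable parameters
(2.24M / 4.35M / 6.46M). A note on the feed-forward width: a width of 256
would give ~0.395M parameters per layer, inconsistent with those totals;
`ff_dim = 512` reproduces all three at ~0.527M per layer and is the
default, with the width configurable. Similarly, the printed totals pin
down post-norm layers, biases everywhere and no final stack
normalization; all are the defaults here. The test suite asserts the
totals against a closed-form component sum, so any architectural drift
breaks loudly.

There is no dropout; evaluation-mode inference is bit-deterministic. The
encoder, backpropagation and Adam are implemented in base R — the model
is the package's core and no installed package provides it — and the
backward pass is verified against central-difference numerical gradients
to ~1e-9 relative error in the tests.

## Training

Pretraining draws two independently augmented views of each sampled
tracklet (the two-view sampler guarantees every sample a positive). The
augmentations, in order: random pace change (uniform factor in
[0.75, 1.5], applied first because it changes length), random 48-frame
crop, horizontal flip with probability 0.5 (swapping left/right joint
triplets including confidences — a mirrored left joint *is* the right
joint's measurement), and Gaussian coordinate jitter (σ = 0.005
normalized units). The pace-factor range and jitter magnitude are
package defaults, declared rather than inherited from any source.

The supervised contrastive loss over l2-normalized projections uses
temperature τ = 0.001; at that sharpness similarities are scaled by
1000, so the log-sum-exp is computed with max subtraction
unconditionally, and the training loop clips the global gradient norm at
1.0 (configurable) — without clipping, updates at the configured
learning rates diverge on small batches. The loss is averaged over
anchors. In multi-task mode the soft-label binary cross-entropy of the
appearance head (computed on both views against the same tracklet-level
labels) is added with weight λ = 0.5, chosen so the two terms have
similar magnitude. "Batch size 1024" counts view-samples: 512 tracklets
× two views.

The learning rate follows a triangular cycle between 1e-4 and 1e-3 with
a 20-epoch period. Fine-tuning (`gait_finetune()`) uses layer-wise
learning-rate decay — heads at `lr0`, encoder layer depth `k` from the
top at `lr0 · 0.9^k`, input projection and positional table smallest —
with a linear `lr0 → 0` schedule over 200 epochs. The decay factor 0.9
is a package default; the scheme, not the constant, is the specified
part. The optimizer is Adam in both phases.

## Evaluation

Embeddings are extracted with a deterministic center crop of 48 frames,
no test-time augmentation, and l2 normalization. Rank-1 uses cosine
similarity (equivalently Euclidean ranking on the unit sphere — the
metric choice left open by l2 normalization), ties broken toward the
first gallery index. The cross-view protocol evaluates each view with a
gallery of all *other* views; probes whose subject has no cross-view
gallery entry are skipped with a warning and reported in a coverage
statistic rather than silently matched to themselves. Gender metrics
threshold at 0.5 and macro-average over the two classes so the minority
class weighs equally (the averaging convention is not standardized in
this literature; macro is reported and labelled as such). Attribute
agreement is per-attribute R² about the target mean, with zero-variance
targets reported as missing, never as 0.

## The synthetic walker population

`sample_walker()` draws identity parameters — gait frequency 0.7–1.3 Hz,
normalized stride amplitude, arm-swing/stride ratio, torso and shoulder
scale, hip/shoulder width ratio, phase, azimuth in [0, π], joint noise —
and `render_tracklet()` produces tracker-style output: coupled sinusoid
limb kinematics (legs in anti-phase, arms counter-phased, pelvis bob at
twice the stride rate), Beta-distributed confidences concentrated near
0.92, face-joint confidences dropping for back views, and bounding boxes
from joint extents. The stride amplitudes are calibrated so the nominal
population's mean leg speed sits comfortably inside the [0.0015, 0.09]
keep-band (empirically ~0.01–0.06 across the parameter ranges).

Soft attribute labels derive from a fixed monotone map: every coded
label is a logistic threshold on a latent that is itself monotone in the
driving parameters (ordinal cumulative coding for the ordered groups).
Two design points matter:

- **Only pace-invariant features carry attributes.** The training
  augmentations include random pace changes, so any learned
  representation is cadence-invariant *by construction of the method*;
  a label coded purely in gait frequency would be unlearnable no matter
  how good the model. Age-group scores therefore ride on stride
  amplitude and arm-swing ratio (both plausible ageing correlates),
  body type on the hip/shoulder ratio (which survives the
  normalization), viewpoint on the lateral-amplitude inflation, head
  lead and face confidences, and gender on a hip-ratio + arm-swing
  combination.
- **The remaining 30 attributes are deliberately noise-dominated**:
  clothing, carrying and action labels get weak identity-specific noise,
  mirroring the empirical finding on real corpora that some appearance
  labels are simply not recoverable from movement. Passing tests
  therefore demonstrate recovery of movement-coded structure, not of
  arbitrary appearance.

What the simulator does *not* model: realistic biomechanics, walking
direction changes within a tracklet, occlusions and identity switches,
multi-person interactions, and the long-tailed duration distribution of
real tracklets. Results on it bound what the machinery can do on clean
periodic data; they do not predict absolute accuracy on surveillance
footage.

## Desk-scale studies

Two packaged experiments (`experiment_identity_recovery()`,
`experiment_multitask_benefit()`) fix the study conditions used by the
tests and the acceptance script:

- **Identity recovery** — 50 walkers, 144 frames each; a 2-layer,
  `d_model = 64` encoder pretrained contrastively for 60 full-corpus
  epochs; rank-1 scored with gallery crops from the first half of each
  tracklet and probe crops from the second half. Chance is 2%.
- **Multi-task benefit** — 96 training walkers, multi-task pretraining
  for 220 epochs at batch 64 (more optimizer steps per epoch at this
  corpus size), appearance-head R² computed on 48 freshly sampled
  walkers. The contrastive-only reference is trained for 30 epochs: its
  appearance head receives no gradient in that mode (verified bit-exact
  in the tests), so its R² is that of a frozen random readout regardless
  of training length.

The problem sizes were chosen as the smallest at which the phenomena are
stable: identity recovery saturates near-perfect well before 50
identities, while the held-out attribute R² of the multi-task head needs
both the longer schedule (the ordinal labels underfit at ~300 optimizer
steps) and the larger held-out sample (R² over a few dozen walkers is a
noisy statistic) before the seed-to-seed spread settles.

## Numerical choices and degenerate inputs

- Denominator guards: `eps = 1e-6` in normalization; l2 normalization
  guards at 1e-12; BCE probabilities clamp to [1e-7, 1 − 1e-7].
- Boundary semantics: all removal thresholds are strict ("less than"),
  so equality survives; the duration filter keeps equality; crop
  intervals are half-open with 0-based frame indexing.
- Resampling uses the frame-count duration convention (`n` frames at
  `fps` span `n/fps` seconds), which keeps the duration filter and the
  resampled length consistent at every source rate; the trailing
  samples hold the last frame where the grids do not align exactly.
- Ties in rank-1 break toward the first gallery index
  (`which.max` semantics), making evaluation deterministic.
- Single-positive contrastive batches (one tracklet, two views) have
  loss exactly 0; a sample with no positive is a sampler-contract error,
  not a skip.

## Known limitations

- The appearance head is linear on the embedding; non-monotone label
  codes (e.g. a "middle band" class coded as a bump) are poorly
  representable — one reason the label map uses ordinal cumulative
  coding.
- Training is full-batch Adam at desk scale; no mini-batch sampling
  schedule, mixed precision or distributed execution.
- The pose-stream reader covers the common flat-JSON tracker dialect
  with an fps sidecar, not every tracker's output format.
- The CLI's `annotate` command ships a deterministic mock ensemble;
  plugging in a real predictor means supplying a callable to
  `annotate_tracklet()`.
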