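# gaitseq

Skeleton-sequence gait analysis in R: corpus construction from 2D
pose-tracker output, self-supervised representation learning with a plain
transformer encoder, and the standard recognition / demographics
evaluation protocols — plus a kinematic walker simulator so the whole
pipeline runs and is testable at desk scale, on synthetic data, with no
external downloads.

## Who this is for

Researchers working on gait biometrics from pose data: person
re-identification from walking patterns, gait-based gender and
pedestrian-attribute estimation, and the data engineering in between
(tracklet filtering, normalization, pace unification). Everything is
plain R with no deep-learning framework dependency; the transformer,
its backpropagation and the Adam optimizer are implemented in the
package and verified against numerical gradients in the test suite.

## The method

**Corpus construction.** Pose trackers emit per-frame 18-keypoint
skeletons `(x, y, c)` with track ids. The pipeline removes frames with
mean joint confidence `< 0.5` or mean ankle confidence `< 0.4`, drops
tracklets shorter than `T·fps/24` frames (with `T = 48`, about two gait
cycles), resamples every stream to 24 fps by linear interpolation, and
normalizes each skeleton by centering at the pelvis and scaling axes by
the shoulder span and neck–pelvis distance:

    x' = (x − x_pelvis) / |x_R.shoulder − x_L.shoulder|
    y' = (y − y_pelvis) / |y_neck − y_pelvis|

Finally, sequences whose mean leg-joint speed falls outside
`[0.0015, 0.09]` normalized units/frame (standing people, erratic pose
output) are removed. Each surviving tracklet is treated as a unique
identity.

**Model.** Each skeleton flattens to a 54-d token (18 × (x, y, c)); a
linear projection to `d_model = 256` plus a learnable additive
positional embedding feeds a standard post-norm transformer encoder (4,
8 or 12 layers; 8 heads), token outputs are mean-pooled, and three
linear heads produce a 256-d identity embedding, a 128-d contrastive
projection and 42 sigmoid attribute scores. The stock sizes have 2.24M,
4.35M and 6.46M trainable parameters.

**Training.** Two augmented views of every tracklet (random pace, crop
to 48 frames, horizontal flip, Gaussian joint jitter) are pulled
together by a supervised contrastive loss over the l2-normalized
projections with temperature `τ = 0.001`; in multi-task mode a
soft-label binary cross-entropy on the attribute head is added with
weight `λ = 0.5`:

    L = L_supcon + λ · L_appearance

Optimization is Adam under a triangular cyclical learning rate
(1e-4 → 1e-3, 20-epoch cycles). Fine-tuning uses layer-wise
learning-rate decay and a linear 1e-4 → 0 schedule.

**Evaluation.** Deterministic center crops, l2-normalized embeddings,
cosine nearest-neighbour rank-1 with gallery/probe splits (including
the cross-view protocol where the gallery excludes the probe's view),
macro precision/recall/F1 for gender, and per-attribute R² against the
annotating ensemble's soft labels.

## Worked example

```r
library(gaitseq)

# a synthetic corpus of 20 walking identities, tracker-style
corpus <- make_pretraining_corpus(n_ids = 20, seed = 7)
ds <- corpus_dataset(corpus)
ds
#> <gait_dataset: 20 sequences, 42 attributes>
#>   removals: low_conf=0 low_feet_conf=0 short=0 speed=0

# contrastive pretraining of a small encoder
model <- gait_pretrain(
  ds,
  model = model_config(n_layers = 2, d_model = 64, n_heads = 4,
                       ff_dim = 128, emb_dim = 64, proj_dim = 32),
  training = training_config(epochs = 40, batch_size = 40, seed = 7),
  mode = "contrastive")
model
#> Pose-token transformer (2 layers, d_model 64, 82,506 parameters)
#>   trained: contrastive, 40 epochs, final loss 0.1832

# rank-1 recognition: gallery from the first half of each tracklet,
# probes from the second half
half <- lapply(ds$sequences, function(s) gait_sequence(s$data[1:72, , ], 24))
rest <- lapply(ds$sequences, function(s) gait_sequence(s$data[73:144, , ], 24))
rank1_accuracy(extract_embeddings(model, half), ds$ids,
               extract_embeddings(model, rest), ds$ids)
#> [1] 95
```

Rank-1 of 95% against a 5% chance level means the embedding separates
19 of the 20 synthetic identities from three seconds of held-out
walking after a forty-epoch training run. The
per-epoch loss curve lives in `model$history` (`plot(model)`).

The same surface is scriptable from a shell via the thin CLI wrapper:

```sh
Rscript inst/cli/gaitseq.R simulate --ids 50 --seed 7 --out stream.json
Rscript inst/cli/gaitseq.R build-dataset --in stream.json --out ds/
Rscript inst/cli/gaitseq.R pretrain --data ds/ --out model.rds --epochs 60
```

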