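---
title: "Hierarchical cost-sensitive classification of horse-human interaction behavior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical cost-sensitive classification of horse-human interaction behavior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(equibehave)
```

## The classification problem

The package classifies the behavioral state of a horse-human dyad, frame by
frame, from three computer-vision modalities: object detections for both
subjects (bounding boxes with confidences), human pose landmarks, and equine
keypoints. Labels live in a two-level taxonomy: three parent valence
categories (affiliative, neutral, avoidant) each split into two leaves
(active/subtle engagement; horse/human-initiated neutrality; horse/human
withdrawal). The taxonomy is the consolidation of a 13-behavior ethogram;
`default_ethogram()` ships the mapping, and `consolidate()` applies it, with
"Move Away" the single actor-dependent code (it maps to `avoidant_horse` or
`avoidant_human` depending on who withdraws).

Naturalistic annotation makes the label distribution extremely skewed. The
reference dataset's printed counts (`paper_class_counts()`) give a 166.6:1
leaf-level and 18.3:1 parent-level imbalance, so plain accuracy is nearly
meaningless — a majority-class predictor scores 69.4% accuracy but 33.3%
balanced accuracy. Balanced accuracy (mean per-class recall) is therefore the
primary metric everywhere in the package.

## Model and assumptions

`equiboost()` fits a two-stage hierarchy of gradient-boosted tree classifiers:

* **Stage 1** — a three-way model over parent categories, on all samples.
* **Stage 2** — one binary model per parent, trained *only* on samples whose
  ground-truth parent matches, over that parent's two leaves.

Every stage is cost-sensitive: samples are weighted by
$w_c = N / (k \cdot n_c)$ computed on the stage's own label alphabet
($k = 3$ for Stage 1, $k = 2$ per Stage 2 model). The weights conserve the
total effective sample size ($\sum_c n_c w_c = N$) while equalizing each
class's contribution to the loss, so a rare avoidant sample costs roughly the
imbalance ratio times a majority sample. Alternative imbalance treatments —
random over/undersampling and SMOTE interpolation
(`smote_interpolate()`, `undersample_plan()`) — are shipped as explicit
comparators only and are never used by the default pipeline: interpolated
samples represent hypothetical rather than observed behavior, and
undersampling to the minority count would discard 88.6% of the reference
dataset's training signal.

Two prediction modes matter:

* **oracle routing** (`predict(..., routing = "oracle", true_parent = ...)`)
  sends each sample to the Stage 2 model of its *true* parent. It isolates
  within-parent discrimination and makes the leaf confusion matrix
  block-diagonal by construction.
* **cascaded routing** (the default) routes by Stage 1's *predicted* parent —
  the deployed mode, in which Stage 1 errors propagate and cross-parent leaf
  errors appear. Whenever a cascaded prediction is correct, the oracle
  prediction is identical (correct leaf implies correct routing), so cascaded
  accuracy can never exceed oracle accuracy; the gap measures the Stage 1
  bottleneck.

A flat six-way model (`architecture = "flat"`) is the non-hierarchical
baseline, and `architecture = "parent"` fits Stage 1 alone.

The base learner is a contract, not a vendor: anything that accepts per-sample
weights and returns class probabilities plugs in. The shipped default is
xgboost (gradient-boosted trees, histogram method); `learner_rpart()` is a
dependency-light single-tree fallback used widely in the test suite because
it is fast and consistent on separable data.

## Tunable parameters

`stage_config()` carries the stage hyperparameters. Defaults follow the
reference pipeline: Stage 1 — 400 boosting rounds, depth 10; Stage 2 — 300
rounds, depth 8; learning rate 0.03; L2 regularization 3.0; random strength
1.0; 254 histogram borders; early stopping with 50-round patience on a 20%
stratified holdout of the training data. `border_count` maps to xgboost's
`max_bin`; `random_strength` has no xgboost analogue and is carried for
learners that support it. Iteration counts and depths are the main
speed/accuracy dials; on the synthetic benchmark the pipeline saturates well
below the default budgets, so the tests and the acceptance script use smaller
configurations (see "Problem sizes" below).

The feature extractor has no tunable parameters, but two constants deserve
mention: the alertness composite is
$0.5\,\sigma(\theta_{head}/45^\circ) + 0.5\,\sigma(\theta_{ear}/30^\circ)$
with $\sigma$ the logistic function — the denominators are chosen so the
composite saturates near the behaviorally meaningful thresholds (head fully
raised ~45°; ears forward-pricked beyond +30°). The ear-angle regimes
(+30° forward/interest, −20° pinned/stress) follow the equine ethology
literature and are exposed via `ear_regime()`.

## What the simulator emulates — and what it does not

`simulate_dyads()` generates labeled per-frame observation streams standing in
for video-derived data. It reproduces the statistical structure the
classifier relies on:

* **class-conditional proximity**: normalized center-to-center distance drawn
  from per-class bands — affiliative (0, 0.3), neutral (0.3, 0.6), avoidant
  (0.6, 1.0) in frame-diagonal units; `default_scenarios(overlap = TRUE)`
  widens the bands so neighboring parents overlap, which is the benchmark
  condition for all directional performance comparisons;
* **ear-angle regimes** (Gaussian around class means: > +30° for affiliative
  leaves, −30° for avoidant-horse) and **head elevation** (e.g. −40° grazing
  for neutral-horse);
* **movement-speed differences** (active engagement and human withdrawal move
  faster than passive observation);
* **episode structure**: frames come in contiguous episodes of geometric mean
  length 30 frames with an episode-level random effect on distance and
  angles, so frames within an episode are temporally correlated and
  grouped/leave-one-video-out validation is meaningfully harder than
  frame-level validation;
* **occlusion**: per-frame Bernoulli dropout of an entire modality; the
  spatial dropout removes the horse detection, mirroring a horse moving out
  of frame. Default rates are 5% (8% for avoidant classes, where subjects
  more often leave the frame).

Geometry is synthesized so the features *recover* the scenario parameters:
eye and ear-base keypoints are placed with offsets that cancel around the
head anchor (the extracted head centroid equals the anchor), ear tips realize
the sampled ear angle exactly in the extractor's own convention, and the
human's per-frame step length is scaled so the extracted speed matches the
configured value. At very large separations (the avoidant band extends to
1.0 diagonal units) box centers are clamped to keep boxes inside the frame;
distances then sample the intersection of the class band with the
geometrically feasible range, and class means remain inside their bands
(asserted by the parameter-recovery tests).

The simulator does **not** emulate: image appearance (no rendering), realistic
pose-estimator error structure (only Gaussian jitter and dropout, provided by
`perturb_keypoints()` / `dropout_landmarks()`), multi-subject scenes, camera
motion, or behavioral transition dynamics beyond episode blocks. Passing
tests on synthetic data therefore demonstrate that the pipeline's mechanics
are correct and that its orderings (hierarchical vs. flat, oracle vs.
cascaded, weighted vs. unweighted, frame-level vs. video-level) behave as the
method predicts — they do not certify performance on real video, which
depends on detector quality and behavioral ambiguity the simulator cannot
represent.

## Numerical conventions

* **Coordinates**: pixel origin top-left, y increases downward, 0-based frame
  indices. Positions and offsets are normalized by frame width/height, the
  center distance by the frame diagonal, areas by the frame area — all
  invariant to uniform rescaling.
* **Angles**: computed in pixel space; elevation is the signed angle of the
  head-centroid-to-nose axis against the horizontal with raised head
  positive; the ear angle is measured from the upward perpendicular of the
  head axis, positive toward the nose; the head centroid needs at least two
  visible eye/ear-base keypoints, elevation additionally needs the nose.
* **Speed**: frame-to-frame displacement of the normalized body center
  (shoulder midpoint), computed within videos only; 0 on a video's first
  frame and after gaps where the previous center was unobserved.
* **Quantiles**: linear interpolation between order statistics (type 7), the
  most common convention. Columns with zero IQR are centered but not divided.
  Missing entries are excluded from scaler statistics and imputed with 0
  after scaling (the robust center).
* **Ties**: argmax ties break by the canonical class order
  (`behavior_leaves()` / `behavior_parents()`); majority-vote ties break
  toward the original unsmoothed label, which makes window 1 the identity.
* **Degenerate inputs**: zero-area boxes compute area 0 with a warning;
  McNemar with no discordant pairs returns statistic 0 with a warning (no
  continuity correction by default, since the reference analysis reports the
  uncorrected statistic; the corrected variant sits behind a flag); paired
  fold tests with zero-variance differences are flagged degenerate; kappa
  with both raters constant and identical returns 1 by convention.
* **Sampling**: behavior episodes are expanded at 3 fps over the half-open
  interval `[start, end)` so adjoining episodes never double-count a boundary
  instant; point events yield exactly one sample. Overlapping episodes each
  emit their own samples — concurrent annotations are legal.
* **Seeds**: one master seed per fit/simulation; child seeds for stages,
  holdout splits and fold models are derived by fixed offsets, so every
  artifact is reproducible from its config and seed.

## Design decisions taken where the method left choices open

* *Grouped-fold stratification key*: each video's majority parent class —
  video-level stratification needs a single label per video and the parent
  level is the one whose fold balance matters most for rare-class coverage.
* *Early-stopping data*: a 20% stratified holdout of the stage's training
  data, refit fraction 80% — stages with classes too small to split safely
  skip early stopping rather than risk a holdout without both classes.
* *Missing-modality flags*: the 35-column vector is kept fixed; missingness
  is carried by the in-vector both-detected flag plus a per-modality missing
  mask attribute rather than extra indicator columns.
* *Equine keypoint schema*: a 17-point set including ear bases and tips
  (nose, eyes, ears, withers, shoulders, hips, hooves, tail base), so ear
  orientation is computable from keypoints alone. Public animal-pose schemas
  of the same size omit ear points; this schema is a declared convention of
  the package, as are the ear-spread definition (inter-tip distance over
  nose-to-centroid distance) and the alertness composite.
* *Landmark dropout scope*: applied to both species' points by default (the
  robustness functions accept `species = "horse"` or `"human"` for one-sided
  ablations), since the underlying description of the dropout experiment does
  not pin down the scope.
* *Stage 2 training set*: ground-truth parent subsets (oracle protocol), with
  cascaded evaluation provided separately — training on predicted parents
  would entangle the two stages' errors.

## Problem sizes used by the tests and acceptance script

The shipped benchmark uses the reference class proportions scaled down
tenfold (5,027 samples: 2599/890/872/475/175/16 across the six leaves) over
12 videos, with overlapping bands, and reduced boosting budgets (Stage 1: 150
rounds, depth 6; Stage 2: 100 rounds, depth 4; no early stopping). These
sizes keep the full suite and the acceptance script to a few minutes on one
CPU while leaving all the directional effects of interest — hierarchy
benefit, cascade gap, weighting benefit, video-level penalty — clearly
visible. Unit tests use single constructed frames and a 6 x 30-sample
perfectly separable toy problem on which any consistent learner must be
exact.

## Known limitations

* Single dyad per scene; no identity tracking or multi-subject support.
* Frame-by-frame classification; the only temporal component is post-hoc
  majority-vote smoothing (`temporal_majority_vote()`), not a sequence model.
* The simulator's feature distributions beyond distance, ear angle, head
  elevation and speed are fixed conventions, not fitted to real data; absolute
  synthetic-benchmark scores say nothing about real-video performance.
* Wilson intervals, McNemar and paired fold tests assume the usual
  independence approximations; at 3 fps, frame-level samples within an
  episode are correlated, which is precisely why the grouped and
  leave-one-video-out protocols exist and should be preferred for honest
  generalization estimates.
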