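---
title: "Tracking migrating neutrophils by detection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking migrating neutrophils by detection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neutrack)
```

## The problem

Neutrophils recruited to a wound migrate fast, change shape constantly, and
drift in and out of the imaged field. In a two-hour confocal time-lapse
(512 x 512 frames at 1-minute intervals, roughly 10--40 cells per frame),
a tracker must survive four awkward behaviors besides plain migration:
cells **appearing** at the border, **disappearing** out of view, two cells
**merging** into a single connected detection during a collision or
occlusion, and **splitting** apart again afterwards. neutrack implements a
tracking-by-detection pipeline built around these events: segment every
frame, score the plausibility of every (cell at *t*, cell at *t + 1*)
pair, and link detections into trajectories globally.

## Pipeline overview

1. **Pre-processing** (`max_intensity_project()`, `preprocess_frame()`):
   z-stacks are collapsed by per-pixel maximum; each frame then gets a
   percentile contrast stretch, a median filter, and a Gaussian blur, in
   that order. The stretch makes dim cells segmentable, the median removes
   the noise the stretch amplifies, and the blur smooths cell boundaries
   so thresholding yields compact components.
2. **Segmentation** (`segment_reference()`): intensities are min-max
   normalized and thresholded at `t` (default 0.1); 8-connected components
   below `min_area` (5 px) are discarded. This deterministic classical
   segmenter is the package's reference detector; any external instance
   segmentation (for example a learned model) can be substituted by
   supplying its labeled masks, since downstream stages consume masks
   only.
3. **Scoring** (`proxy_predict()`, `score_sequence()`): for every cell at
   frame *t*, a prediction of where it may be at *t + 1* is formed by
   dilating its pixel set by `search_radius`. The overlap of each
   prediction with each detection at *t + 1*, normalized by the predicted
   area (configurable: target area or union/IoU), fills the score matrix
   `S_t` with rows the cells of frame *t* and columns those of *t + 1*; a
   sequence of *n* frames gives *n - 1* matrices. The dilation prior is a
   deliberate, fully deterministic stand-in for a learned motion
   predictor; `prune_prediction()` adapts externally supplied multi-blob
   predictions by keeping the component with the highest mean intensity.
4. **Linkage** (`link_tracks()`): four algorithms over the same matrices —
   greedy frame-to-frame argmax, Hungarian assignment, basic Viterbi, and
   the extended Viterbi linker described next.
5. **Evaluation and measurement** (`compute_metrics()`,
   `migration_stats()`): identification-based tracking quality against
   ground truth, and per-track migration statistics.

## The extended Viterbi linker

A trajectory's quality is the **product** of its per-step scores, so the
best continuation of a track depends on the whole chain, not the next
frame only. The basic algorithm treats each first-frame cell as a seed and
runs the classic two phases: a forward *routing* pass propagating, in log
space, the best accumulated score to every detection of every later frame,
and a backward *retrieval* pass recovering the argmax path. This is optimal
per seed but blind to other tracks: after two cells merge they share the
same rows of every later matrix, and independent retrievals collapse onto
one path that never splits.

The extended algorithm routes tracks **sequentially** (first-frame cells in
ascending label order, then every detection left uncovered, in frame order)
and maintains an occupancy table mapping each detection to the tracks that
own it and their accumulated scores there. A transition into an occupied
detection is allowed only if

* **Condition 1** — the routing track's accumulated score at that layer is
  at least the discounted merge threshold, or
* **Condition 2** — every occupant's accumulated score at that node is
  below its own discounted threshold.

Because accumulated scores decay geometrically along a track, a fixed
threshold `T_merge` would become unreachable after a few frames; the
comparable quantity at the *k*-th frame of a track (its birth frame being
1) is `discount_threshold(T_merge, k) = T_merge^(k - 1)`. The discount
counts from the track's birth, consistent with the accumulated product it
is compared against.

Three further rules complete the linker:

* **Disappearance** — transitions scoring below `T_truncated` are
  unavailable; a track whose only nonzero continuations are below the
  floor terminates with status `truncated_disappeared` (read: the cell
  left the field of view). Zero rows terminate with
  `ended_zero_scores`, and occupancy blockades with
  `ended_no_available_cell`, so the three end conditions are
  distinguishable downstream.
* **Appearance** — after routing, every detection covered by no trajectory
  seeds a new one starting at its frame.
* **Reroute** — when a later-routed track reaches a contested detection
  with a strictly better accumulated score (by factor `reroute_factor`,
  default 1) than an occupant had there, the occupant is reset at the
  previous layer and re-routed with the contested node forbidden. One
  sweep only, and re-routed tracks cannot trigger further reroutes, which
  guarantees termination. This quantifies the otherwise loose notion of a
  "much better later match" and makes the routing order mostly harmless.

Merging needs no extra machinery: trajectories satisfying the conditions
simply share nodes. Splitting is emergent — sharing ends at the first
layer where the merged tracks' own best continuations diverge or the
conditions fail.

### Why the crossing fixture carries engineered score matrices

`scripted_scenario("two_cells_cross_merge_split")` reproduces the hard
case: two cells approach head-on, share one detection for three frames,
then separate, each continuing in its original direction. Detection-level
overlap scores cannot express that case's resolution: during the merge both
tracks sit on the *same* score-matrix row, so any scoring that looks only
at the shared detection gives both tracks identical continuations. A
learned motion model avoids this because it predicts per cell *history*,
not per detection. The fixture therefore ships score matrices emulating
such a history-aware predictor: the first track's steps are slightly
stronger than the second's, and the exit toward the first track's true
side scores slightly higher. The values are chosen so that both tracks
satisfy Condition 1 at the shared detection (entry and merge layers) while
the later-routed track falls below the discounted threshold exactly at the
first track's exit — it is blocked there and takes its own, correct exit.
The same matrices are the documented failure modes of the baselines: the
greedy linker strands the second cell at the collision (the node is
claimed), and basic Viterbi collapses both retrievals onto the
higher-scoring exit.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `T_truncated` | 0.001 | score | disappearance floor |
| `T_merge` | 0.875 | score | merge admission threshold (discounted per frame) |
| `reroute_factor` | 1 | -- | how much better a later track must be to displace an occupant |
| `end_threshold` | 0.001 | score | Hungarian link cut |
| `t` (segmentation) | 0.1 | normalized intensity | foreground threshold |
| `min_area` | 5 | px | speck suppression |
| `search_radius` | 10 | px | motion prior radius; should exceed the largest per-frame displacement |
| `match_radius` | 10 | px | identification radius for evaluation |
| `pixel_size` | 0.9 | um/px | physical calibration |
| `frame_interval` | 1 | min | temporal calibration |
| `distant_threshold` | 2.4 | um | distant-cell classification on mean step displacement |

## Evaluation metrics

`match_identities()` says a predicted node *identifies* a ground-truth
object when it is the nearest object within `match_radius` at that frame;
each track is matched to the object it identifies in the majority of its
frames (ties toward the smaller object id). On top of that:

* **track purity (TP)** — fraction of a track's frames identifying its
  matched object, averaged over tracks;
* **object purity (OP)** — fraction of an object's frames identified by a
  track matched to it, averaged over objects;
* **FIT** — (frame, object) identifications by a wrongly-matched track;
* **FIO** — (frame, track) events where a track follows an object other
  than its match;

FIT and FIO are normalized per frame per cell: raw counts divided by
`n_frames x mean cells per frame` (purities are already ratios). The
frame-level identification rule and the majority matching are the package's
own completion of the metric family — the metrics' absolute values depend
on them, which is why they are stated here prominently and exposed as
parameters. Cross-method comparisons use the Kruskal--Wallis omnibus test
followed, when significant, by Dunn's rank-based post-hoc z-tests with
Benjamini--Hochberg correction (`compare_methods()`); migration properties
between two biological groups use the independent-samples t-test
(`group_compare()`, pooled variance by default).

## The synthetic time-lapse generator

`simulate_sequence()` emulates the acquisition regime the pipeline
targets: 512 x 512 frames, 120 frames per sequence at 1-minute intervals,
10--40 cells per frame. Cells are isotropic Gaussian-profile discs
(`sigma = radius / sqrt(2 log 5)`, so the 20%-of-peak contour sits at the
nominal radius; the ground-truth mask extends to the 10%-of-peak contour,
about 1.2 radii — deliberately the same contour the reference segmenter
extracts at its default threshold, so simulated masks and segmentations
agree at the operating point) moving under a persistent random walk — the new heading is a convex blend of the old
heading and a uniformly random direction, with weight `persistence`.
Appearance and disappearance happen at image borders (probabilistically or
scripted); scripted merge events let two or more tracks share one
connected region until a scripted split. Noise is additive Gaussian on a
constant background. An optional `min_separation` constraint re-draws
headings that would bring two cells too close, which is how the
"clean separated" study condition is constructed by design rather than by
luck.

Simulator defaults are the package's own choices where no measured values
exist: `speed_mean = 3` px/frame (~2.7 um/min at 0.9 um/px — brisk
interstitial migration), `persistence = 0.7` (visibly directional but
wandering paths), `noise_sigma = 0.02` on a zero (background-subtracted) baseline with unit
peak — high-SNR fluorescence, under which the reference segmenter at
`t = 0.1` stays above 0.9 IoU on raw frames (asserted in the suite). A
nonzero `background_level` shifts the min-max normalization and fattens
segmented regions relative to ground truth; the contrast-stretch step
compensates partially, which is the realistic regime rather than the
calibrated one. The generator does **not** emulate irregular neutrophil
morphology (an optional eccentricity is a crude surrogate), intensity
texture, photobleaching, or empirically calibrated motility statistics.
Tests passing on simulated data therefore certify the *algorithms* —
linkage correctness, event handling, metric arithmetic — not segmentation
robustness on real morphologies.

## Numerical and design choices

* Accumulated scores are products of per-step scores; the DP works in log
  space, and all threshold comparisons use a 1e-12 slack.
* All argmax ties break toward the lower cell label (forward pass,
  retrieval end-node choice, and the greedy linker's first-candidate
  rule), making every linker fully deterministic.
* Image filters use reflective (symmetric) padding; results are
  bit-reproducible across platforms.
* Connected-component labeling is 8-connective; labels are assigned in
  column-major order of first pixels.
* Segmentation object matching uses the mutual-maximal-overlap rule — a
  (truth, prediction) pair is a true positive when each is the other's
  largest overlap — because it is order-independent and makes the
  under-/over-segmentation counts well-defined.
* Train/test splitting of *n* annotated images at ratio 8:2 puts
  `ceiling(0.2 n)` images in the held-out side (240 -> 192/48,
  192 -> 153/39).
* The basic-Viterbi truncation post-processing (cut a trajectory at the
  first step whose score drops below its predecessor's, once the
  trajectory has entered a node shared with another trajectory) is one
  reading of a loosely specified rule; it is isolated behind
  `link_viterbi_basic(truncate =)` and marked with its own status so it
  never contaminates comparisons of the DP core.
* Degenerate inputs are defined behaviors: empty frames yield 0-row/column
  score matrices; all-zero chains yield length-1 trajectories for every
  seed; an empty prediction set reports zero purities with a warning.

## Problem sizes used by the test suite

The suite verifies the Viterbi core against exhaustive path enumeration on
200 random chains of up to 5 frames and 4 cells plus 20 contention-free
permutation chains; parameter recovery runs a 20-cell, 60-frame, 512 x 512
noise-free simulation with enforced separation, on which the extended
linker must reproduce the ground truth exactly (TP = OP = 1, FIT = FIO =
0); counting identities use a full 120-frame simulated sequence. These
sizes are the package's chosen verification conditions; the algorithms
themselves have no built-in limits.

## Known limitations

* The dilation-based motion prior carries no velocity information; fast
  cells need a generous `search_radius`, which in dense fields inflates
  off-diagonal scores. Plugging in a learned predictor through the
  external-prediction adapter is the intended remedy.
* Occupancy decisions depend on routing order; the reroute sweep mitigates
  but does not provably eliminate order effects.
* Tracking is 2D; z-stacks are only projected.
* FIT/FIO/TP/OP values depend on the identification radius and majority
  matching; compare values across methods under identical settings, not
  across publications.
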