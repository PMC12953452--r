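---
title: "Counting seedlings in a row: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting seedlings in a row: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rowcountr)
```

## The problem

Plant breeders score seedling emergence — for rapeseed and similar drilled
row crops — by counting the plants in each planted row. Walking a
smartphone along the row and filming it obliquely turns the task into
tracking-by-detection: an object detector emits one
bounding box per visible seedling per frame, and a multi-object tracker
links those boxes into identities, so the number of identities is the row
count ŷ. Two things make this harder than generic object counting:

* **Perspective distortion.** A camera 0.5 m above the ground tilted 45°
  sees the row stretching to the horizon: distant plants are a few pixels
  tall and visually crowded, foreground plants tens of pixels and sparse
  ("small in distance, large in foreground"). No single spatial scale
  describes the frame.
* **Non-target detections.** The detector also fires on seedlings in
  neighbouring rows beyond the drainage ditches, and on ditch-edge soil
  texture. Counted naively these inflate ŷ.

rowcountr implements the full pipeline — detection ingestion,
density-adaptive clustering to eliminate non-target detections, SORT
tracking with permanent-ID counting, the evaluation metric suite — plus a
pinhole-camera scene simulator so the whole chain can be exercised and
tested without videos or a trained detector.

## Adaptive clustering

Each frame's detection centres form a point set whose density varies
systematically with image height. The clustering stage assigns every point
a local neighbourhood radius

$$\varepsilon_x \;=\; \min\!\Big(\varepsilon_{\max},\;
  \max\!\big(1, \Delta v/\alpha\big)\times \mathrm{median}(D_{filtered})\Big)$$

and a density threshold
$min\_samples = \max\!\big(2, \lceil \bar\rho\,\delta\rceil\big)$,
where:

* $D_{filtered}$ are the gaps between adjacent members of the point's
  k-nearest-neighbour set, projected on the neighbourhood's principal axis
  (the local row direction), after discarding upper outliers by the
  $Q_3 + 1.5\,\mathrm{IQR}$ rule. Along a horizontal row of evenly spaced
  plants this is exactly the plant spacing. We use the principal-axis
  projection rather than raw horizontal differences because under an
  oblique view the row runs *vertically* through the image, and horizontal
  gaps then measure only lateral scatter.
* $\Delta v$ is a vertical span mapped through the normalisation constant
  $\alpha$ into a dimensionless scale factor. Its support is configurable:
  the default is the frame-global span, which makes the scale factor shared
  by all points so that adaptivity comes entirely from the local spacing
  median (dense regions → small radius, sparse regions → large radius). The
  per-neighbourhood ("local") support is also implemented; it makes the
  radius grow with the *square* of the local spacing, which on strongly
  perspective-compressed frames either starves the dense band or saturates
  sparse regions at the ceiling, so it is not the default.
* $\bar\rho$ is the mean neighbourhood occupancy over the point's k-NN set
  and $\delta$ a decay factor: denser regions demand more neighbours before
  a point counts as core.

A point is **core** if its radius contains at least `min_samples` points
(itself included). Core points connect under *mutual* reachability — their
distance must lie within **both** radii. This matters: detected
neighbour-row plants are sparse (most are too small for the detector), so
the formula hands them inflated radii, and with one-directional reach those
radii would bridge the perspective-narrowed ditch at the image top and pull
the side row into the target cluster. Non-core points within a core's
radius join its cluster as border points; the rest are noise — the
candidate elimination set of non-target detections. A second guard is the
**dual-threshold constraint**: the radius never exceeds 250 px, which at
the 800 px/m central-band calibration is 0.3125 m, wider than the 0.3 m
ditch, so in the well-resolved central band no radius can reach across the
ditch regardless of local statistics.

Per frame, the largest cluster (ties broken toward the frame's vertical
midline) is the target row; everything else is eliminated.

### Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `alpha` | 80 | px | span-to-scale normalisation; with the global span of a full frame, radius ≈ 10 × local gap median (projected-gap medians are dragged down by near-duplicate projections) |
| `delta` | 0.5 | — | density decay in the `min_samples` model |
| `k_neighbors` | 5 | — | local-statistics neighbourhood |
| `eps_max` | 250 | px | dual-threshold ceiling (≈ 0.3125 m) |
| `eps_floor` | 1 | px | radius floor |
| `min_samples_floor` | 2 | — | a cluster needs two members |
| `spacing_outlier_multiplier` | 1.5 | — | IQR rule for gap outliers |

None of `alpha`, `delta`, `k_neighbors` have a canonical value; the
defaults were calibrated once on the simulator's default scene so that the
dense band stays clustered, side rows are eliminated, and the retained
radii span the tens-of-pixels (dense) to 150–250 px (sparse foreground)
range. All are exposed in configuration.

## Tracking and counting

The tracker is SORT: a constant-velocity Kalman filter per track on the
state $(u, v, s, r, \dot u, \dot v, \dot s)$ (box centre, area, aspect
ratio), Hungarian assignment on an IoU cost with gate 0.3, a
tentative-confirmed lifecycle (`min_hits = 3`, `max_age = 3`), and the
counting rule: when a track's centre crosses the lower frame edge
($v \ge$ frame height) it is retired and its id permanently blacklisted,
so a seedling that leaves the frame can never be re-counted. Three
adaptations to the walking-camera geometry, all config-exposed:

* **Process noise ×10.** A camera 0.5 m above ground induces strong
  apparent acceleration near the lower frame edge; the original SORT noise
  magnitudes make the constant-velocity filter lag there until the IoU gate
  rejects its own object and the identity fragments.
* **Ego-motion spawn prior.** New tracks start with the median velocity of
  currently matched tracks rather than zero. Image motion is dominated by
  the camera walk; with apparent motion comparable to the plant spacing, a
  zero-velocity prediction sits closer to the *neighbouring* plant's next
  detection than to its own, and the resulting chain mis-association mints
  ids without bound.
* **Rescue pass** (`rescue_iou`, default half the gate): still-unmatched
  detections are re-associated to coasting tracks at a relaxed gate before
  any new id is spawned, so a single strict-gate miss cannot split an
  identity into two counted ids.

### Where the elimination acts

The clustering verdicts can be applied in two places. Removing eliminated
detections *before association* (`clustering_apply = "association"`) means
clutter never forms tracks — but a few frames of labeling flicker on a
genuine plant starve its track, and the respawned track double-counts it;
we measured this inflating counts by half or more. The default
(`clustering_apply = "counting"`) therefore feeds the tracker every
detection and treats the per-frame verdicts as votes: a finalised track is
counted only if it was confirmed and the majority of its matched detections
were retained. Flicker averages out over a track's life; a neighbour-row
track, stably eliminated frame after frame, fails the vote. Because tracks
enter the count at finalisation (deletion, retirement, or end of video) the
running count is monotone.

The count is the number of finalised, confirmed, majority-retained ids
(`count_mode = "confirmed"`); `count_mode = "retired"` restricts it to ids
that crossed the lower edge, which misses plants still visible when the
video ends.

## Evaluation metrics

The metric suite follows the field's conventions: precision
$P = TP/(TP+FP)$ and recall $R = TP/(TP+FN)$ from greedy
confidence-ordered box matching at an IoU threshold; average precision as
the raw all-point sum $AP = \sum_i P_i\,\Delta R_i$ (no interpolation);
counting accuracy $Acc = (1 - |\hat y - y|/y)\times 100\%$ (which is 100
only for an exact count and negative for a gross over-count); and
$R^2 = 1 - \sum_i(y_i-\hat y_i)^2 / \sum_i(y_i-\bar y)^2$ over per-video
counts. Tracking quality uses centre-distance matching of track output to
ground-truth identities: $Q_{sh}$ is the number of identities that suffer
at least one id switch, $S$ the tracker's count, $T_{mat}$ the identities
matched at least once, $M_{mat}$ those whose dominant track id covers at
least half their matched frames, and
$W_{ID} = Q_{sh}/S$, $P_{tr} = M_{mat}/S$, $P_{mt} = M_{mat}/T_{mat}$.
The operational definitions of $Q_{sh}$, $M_{mat}$ and $T_{mat}$ (gate,
coverage threshold, switch counting) are conventions chosen here and
documented in `?tracking_eval`, including a detectability floor
(`min_box_px`) because identities smaller than the detector's resolving
limit cannot meaningfully be tracked.

## The scene simulator

The simulator exists so that every stage — and the pipeline end to end —
is testable against known ground truth. It emulates the acquisition
protocol the package targets: a 14.4 m × 1.2 m plot, plants on a
0.05 m-spaced jittered grid with lateral scatter (s.d. 0.08 m — drilled
seed spreads over a band, not a line), 0.3 m ditches, sparse clutter rows
beyond them, a camera at 0.5 m height tilted 45° or 90° walking at
0.8 m/s, 30 fps, 1920×1080 frames. The focal length is derived so the
central-band ground scale is 800 px/m at either tilt. Plants render as
view-dependent boxes: a late-stage rosette's top-down footprint (0.13 m)
is far wider than its side profile (0.05 m), which is why boxes overlap
more in the vertical view than in the oblique view at the same ground
scale — the geometric seed of the oblique view's counting advantage.

Detector noise is deliberately *correlated*, because a real detector
re-seeing the same plant makes correlated errors:

* misses follow a logistic size curve (midpoint 10 px, slope 2 px),
  realised through a per-plant detectability threshold drawn from that
  logistic — marginally identical to the curve, but a plant near the
  threshold stays missed until it grows, rather than flickering;
* sustained occlusion: a plant is missed while the fraction of its box
  covered by another box, scaled by `occlusion_coef`, exceeds its own
  susceptibility — the mechanism that penalises the vertical view;
* confidence and localisation are a per-plant bias plus a small per-frame
  wiggle; spurious detections arrive as a Poisson stream biased toward the
  projected ditch edges.

With every noise source per-frame-independent instead, all pipeline modes
over-counted two- to three-fold through identity churn — a failure mode no
real detection stream exhibits. This is the main caveat when reading test
results: the simulator shows the pipeline behaves correctly *given a
detector whose errors are object-correlated*; it cannot certify behaviour
under pathologies it does not model (rolling-shutter distortion, path
offsets, camera shake, appearance-dependent detector failures).

## Numerical and degenerate-input choices

* Quantiles use the type-7 (linear interpolation) rule.
* Frames with fewer than `k_neighbors + 1` points have no meaningful local
  statistics: the whole frame is labelled noise (degenerate frame); the
  pipeline passes frames with fewer than 2 detections straight to the
  tracker.
* A spacing median of zero (duplicate points) clamps the radius to
  `eps_floor`.
* Predicted box area is clamped positive; aspect ratio is modelled
  constant.
* Ties in target-cluster selection break toward the frame's vertical
  midline; border points attach to their nearest qualifying core.
* Confidence values outside [0, 1] are clamped with a warning; boxes fully
  outside the frame are flagged degenerate rather than silently dropped.

## Problem sizes used in the tests

The test suite and the acceptance script simulate 7.2 m scenes (half the
default plot, ~140 target plants, ~340 frames) for the paired
adaptive-versus-fixed and 45°-versus-90° experiments over ten seeds, and
the full 14.4 m default scene (~280 plants, ~560 frames) for the
noise-free conservation check. These sizes are the package's choice of a
thorough-but-quick experimental battery; nothing in the method depends on
them.

## Known limitations

* The elimination's majority vote needs a track to spend most of its
  matched life inside the retained cluster; plants at the extreme lateral
  edge of the drill band can sit permanently outside it and be missed
  (the dominant error is a mild under-count).
* Conservation of identities is exact on the oblique default scene; in the
  vertical view a box entering clipped at the top edge can occasionally
  steal a young track's match and cost one extra id.
* The 250 px ceiling is calibrated for the central band; at the image top
  the ditch is narrower than 250 px and side-row exclusion rests on the
  mutual-reachability rule instead.
* Camera yaw is fixed along the row; path offset and shake are not
  modelled.
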