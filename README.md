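# rowcountr

Row-based seedling counting from object-detection streams of oblique-view
walking videos.

Plant breeders score seedling emergence — for rapeseed (*Brassica napus*)
and similar row crops — by counting the plants in each planted row.
Filming the row with a smartphone carried at walking speed and running an
object detector on the frames turns that chore into
tracking-by-detection — but two obstacles stand between detector output and
a usable row count. First, perspective distortion: a camera half a metre
above the ground sees distant plants as a few crowded pixels and foreground
plants as large sparse boxes, so no single spatial scale describes a frame.
Second, non-target detections: the detector also fires on seedlings in
neighbouring rows beyond the drainage ditches and on ditch-edge soil
texture, inflating the count.

rowcountr implements the full counting pipeline in R:

* **Density-adaptive DBSCAN.** Every detection centre gets a local
  neighbourhood radius `eps = min(250, max(1, Δv/α) × median(D_filtered))`,
  where `D_filtered` is the outlier-filtered local adjacent-plant spacing,
  and a local density threshold `min_samples = max(2, ⌈ρ̄·δ⌉)`. Dense
  distant regions get small radii, sparse foreground regions large ones;
  the 250 px ceiling (0.3125 m at the 800 px/m central-band calibration)
  together with the filtered spacing median forms a dual-threshold
  constraint that keeps the radius from expanding across the 0.3 m ditch.
  Noise points form the elimination set of non-target detections; classic
  fixed-parameter DBSCAN is included as the conventional baseline.
* **SORT tracking with permanent-ID counting.** Constant-velocity Kalman
  filtering per track, Hungarian assignment on IoU, a tentative/confirmed
  lifecycle, and the counting rule: a track whose box centre crosses the
  lower frame edge is retired and its id blacklisted forever, so a plant
  leaving the frame is counted exactly once. The count ŷ is the number of
  finalised confirmed tracks whose detections were majority-retained by
  the clustering stage.
* **The evaluation metric suite**: precision, recall, all-point average
  precision; counting accuracy `Acc = (1 − |ŷ − y|/y) × 100%` and the
  per-video count regression `R²`; ID-switch rate `W_ID = Q_sh/S`,
  tracking accuracy `P_tr = M_mat/S` and precision `P_mt = M_mat/T_mat`.
* **A scene simulator** that renders a walked plot (14.4 m × 1.2 m,
  0.05 m plant spacing, 0.3 m ditches, 45° or 90° camera tilt, 30 fps,
  1920×1080) through a pinhole camera and corrupts the ground-truth boxes
  with a realistic, object-correlated detector-noise model — so the whole
  pipeline is testable without videos or trained weights.

Detections travel as plain tibbles (`frame, id, x, y, w, h, conf`), read
and written in the MOT-challenge CSV dialect and the YOLO normalised label
format; every stage returns tidy objects with `tidy()`, `glance()` and
`autoplot()` methods.

## A worked example

Simulate an oblique walk along a 7.2 m row with clutter rows beyond the
ditches and detector noise, then count it:

```r
library(rowcountr)

scene <- scene_config(plot_length = 7.2)       # 45° tilt by default
sim <- simulate_video(scene, noise_config(), seed = 42)
sim
#> Simulated walking video
#>   tilt 45 deg, 287 frames, 197 plants (target row y = 139)
#>   30789 truth boxes -> 21305 detections (seed 42)

res <- run_pipeline(sim$detections, pipeline_config("adaptive"),
                    frame_size = scene$frame_size)
res
#> Row counting result
#>   predicted count: 125
#>   frames: 287   clustering: adaptive   view: 45deg

count_accuracy(sim$y, res$count)
#> [1] 89.92806
```

The scene holds 197 plants, but only the 139 in the target row are the
ground truth `y`; the pipeline eliminated 6,039 of 21,210 detections as
neighbour-row or ditch clutter and counted 125 seedlings — an accuracy of
89.9%. Comparing clustering modes on the same video shows what the
adaptive stage buys:

```r
compare_methods(sim$detections,
                list(adaptive = pipeline_config("adaptive"),
                     fixed = pipeline_config("fixed", fixed_eps = 100,
                                             fixed_min_samples = 6),
                     off = pipeline_config("off")),
                truth = sim$y, frame_size = scene$frame_size)
#>   method   clustering_mode count truth      acc
#> 1 adaptive        adaptive   125   139 89.92806
#> 2 fixed              fixed   108   139 77.69784
#> 3 off                  off   186   139 66.18705
```

With clustering off, every clutter track is counted (186 ≫ 139); the
fixed-radius baseline over-eliminates (108); the adaptive radii land
closest. `autoplot(res)` draws the cumulative count and per-frame
elimination; `plot_scene_frame(sim, 120)` shows a rendered frame.

A thin command-line wrapper over these functions lives at
`inst/cli/rowcountr.R` (`count`, `compare`, `simulate`, `evaluate`,
`print-config` subcommands; YAML configuration via
`read_pipeline_config()`).

## Vignette

`vignettes/row-counting-methods.Rmd` documents the models and their
assumptions, every tunable parameter with units and defaults, what the
simulator does and does not emulate, the numerical and degenerate-input
choices, and known limitations.
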