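#' Scene geometry configuration
#'
#' Geometry of the simulated acquisition: a smartphone carried at walking
#' speed along a planted row, looking down at the ground either obliquely
#' (45 degrees) or vertically (90 degrees). World coordinates are metres:
#' X along the walking direction, Y lateral (left negative), Z up; the
#' camera is centred over the target row.
#'
#' Defaults reproduce the field layout and acquisition protocol the package
#' targets: 14.4 m plots, 1.2 m wide, 0.05 m plant spacing, 0.3 m drainage
#' ditches on both sides, camera at 0.5 m height moving at 0.8 m/s, 30 fps,
#' 1920x1080 frames. The focal length (in pixels) is derived so that the
#' ground scale in the central image band equals `pixels_per_meter`
#' (`focal = pixels_per_meter * camera_height / sin(tilt)`), matching the
#' 800 px/m calibration the clustering stage assumes.
#'
#' @param plot_length,plot_width plot size in metres.
#' @param plant_spacing along-row plant spacing in metres.
#' @param ditch_width drainage-ditch width in metres.
#' @param camera_height camera height above ground, metres.
#' @param tilt_deg camera tilt below the horizontal: 45 (oblique) or 90
#'   (vertical); any value in (0, 90] is accepted.
#' @param walk_speed walking speed, m/s.
#' @param fps frame rate, Hz.
#' @param frame_size `c(width, height)` in pixels.
#' @param pixels_per_meter central-band ground calibration used to derive
#'   the focal length (default 800).
#' @param focal_px focal length in pixels; `NULL` (default) derives it from
#'   the calibration.
#' @param plant_diameter apparent plant diameter seen in side profile,
#'   metres (default 0.05, late-seedling scale).
#' @param plant_diameter_top rosette footprint diameter seen from directly
#'   above, metres (default 0.13: the leaves of a late-stage rosette splay
#'   far wider than its side profile, to the point of interlocking with
#'   neighbours at 0.05 m drill spacing). The rendered size blends the two
#'   by view angle, which is what makes boxes overlap more in the vertical
#'   view than in the oblique view at the same ground scale.
#' @param emergence_rate probability a grid site holds a plant (default
#'   0.97).
#' @param n_side_rows clutter rows on each side beyond the ditch (default 1).
#' @param side_row_sparsity occupancy of side-row grid sites relative to
#'   `emergence_rate` (default 0.15: sparse clutter).
#' @param position_jitter s.d. of along-row plant position jitter, metres.
#' @param lateral_sd s.d. of the lateral scatter of plants about the row
#'   centreline, metres (default 0.08: drilled seed spreads over a band a
#'   few tens of centimetres wide rather than a geometric line).
#' @param start_margin,end_margin camera start/end positions relative to the
#'   plot ends, metres (the walk must pass the last plant so every seedling
#'   crosses the lower frame edge).
#' @return A list of class `scene_config`.
#' @export
scene_config <- function(plot_length = 14.4, plot_width = 1.2,
                         plant_spacing = 0.05, ditch_width = 0.3,
                         camera_height = 0.5, tilt_deg = 45,
                         walk_speed = 0.8, fps = 30,
                         frame_size = c(1920, 1080),
                         pixels_per_meter = 800, focal_px = NULL,
                         plant_diameter = 0.05, plant_diameter_top = 0.13,
                         emergence_rate = 0.97,
                         n_side_rows = 1, side_row_sparsity = 0.15,
                         position_jitter = 0.01, lateral_sd = 0.08,
                         start_margin = 0.5, end_margin = 0.7) {
  stopifnot(tilt_deg > 0, tilt_deg <= 90, camera_height > 0, walk_speed > 0,
            fps > 0, plant_spacing > 0, emergence_rate >= 0,
            emergence_rate <= 1, side_row_sparsity >= 0,
            side_row_sparsity <= 1)
  if (is.null(focal_px)) {
    focal_px <- pixels_per_meter * camera_height / sin(tilt_deg * pi / 180)
  }
  phi <- (90 - tilt_deg) * pi / 180   # view angle from the vertical
  diameter_eff <- plant_diameter_top * cos(phi)^2 +
    plant_diameter * sin(phi)^2
  structure(list(plot_length = plot_length, plot_width = plot_width,
                 plant_spacing = plant_spacing, ditch_width = ditch_width,
                 camera_height = camera_height, tilt_deg = tilt_deg,
                 walk_speed = walk_speed, fps = fps, frame_size = frame_size,
                 pixels_per_meter = pixels_per_meter, focal_px = focal_px,
                 plant_diameter = plant_diameter,
                 plant_diameter_top = plant_diameter_top,
                 diameter_eff = diameter_eff,
                 emergence_rate = emergence_rate,
                 n_side_rows = n_side_rows,
                 side_row_sparsity = side_row_sparsity,
                 position_jitter = position_jitter, lateral_sd = lateral_sd,
                 start_margin = start_margin, end_margin = end_margin),
            class = "scene_config")
}

#' Detector-noise configuration
#'
#' Noise applied to rendered ground-truth boxes to emulate detector output:
#' size-dependent misses (small distant plants are frequently undetected),
#' centre and size jitter, a size-dependent confidence model, and spurious
#' false-positive boxes biased toward the ditch edges where a real detector
#' misfires on soil texture.
#'
#' The miss curve is logistic in box height: near 1 below ~4 px, near 0
#' above ~20 px. It is realised through a per-plant detectability threshold
#' drawn from the logistic distribution with the same midpoint and slope
#' (a plant is detected once its box height exceeds its own threshold), so
#' the marginal miss probability at height h is exactly
#' `plogis((midpoint - h) / slope)` while misses stay correlated across
#' frames, as they are for a real detector re-seeing the same plant.
#' Independent per-frame dropouts (motion blur) are added on top, and an
#' occlusion term makes plants whose boxes are substantially covered by
#' other plants' boxes go undetected for as long as the cover persists —
#' the mechanism that penalises the vertical view, where canopy overlap is
#' highest. Confidence is likewise mostly a property of the plant: a
#' height-dependent mean (small targets score low, so the pipeline's
#' confidence gate removes them) plus a per-plant bias, with only a small
#' per-frame wiggle. Localisation error follows the same split: a constant
#' per-plant offset (anchor quantisation, asymmetric canopy) plus a smaller
#' per-frame jitter.
#'
#' @param center_jitter_sigma s.d. of the per-frame box-centre jitter,
#'   pixels.
#' @param center_bias_sigma s.d. of the constant per-plant centre offset,
#'   pixels.
#' @param size_jitter_frac s.d. of the per-frame multiplicative box-size
#'   jitter.
#' @param size_bias_frac s.d. of the constant per-plant size bias.
#' @param miss_midpoint_px,miss_slope_px logistic miss-curve midpoint and
#'   slope (pixels): `P(miss at height h) = plogis((midpoint - h) / slope)`.
#' @param dropout_rate probability an otherwise-detectable box is dropped in
#'   a single frame (independent across frames; motion blur).
#' @param occlusion_coef scales the occlusion miss rule: a plant is missed
#'   while `occlusion_coef` times the fraction of its box covered by
#'   another box exceeds its own (uniformly drawn) susceptibility.
#' @param fp_rate expected false detections per frame (Poisson).
#' @param fp_edge_bias fraction of false positives placed near the projected
#'   ditch edges rather than uniformly.
#' @param conf_midpoint_px,conf_slope_px logistic confidence-model midpoint
#'   and slope; mean confidence is `0.1 + 0.75 * plogis((h - midpoint) /
#'   slope)`.
#' @param conf_sigma s.d. of the per-plant confidence bias.
#' @param conf_wiggle s.d. of the per-frame confidence noise.
#' @return A list of class `noise_config`.
#' @export
noise_config <- function(center_jitter_sigma = 0.5, center_bias_sigma = 1.0,
                         size_jitter_frac = 0.04, size_bias_frac = 0.08,
                         miss_midpoint_px = 10, miss_slope_px = 2,
                         dropout_rate = 0.02, occlusion_coef = 0.7,
                         fp_rate = 0.5, fp_edge_bias = 0.5,
                         conf_midpoint_px = 12, conf_slope_px = 4,
                         conf_sigma = 0.06, conf_wiggle = 0.015) {
  stopifnot(center_jitter_sigma >= 0, center_bias_sigma >= 0,
            size_jitter_frac >= 0, size_bias_frac >= 0, fp_rate >= 0,
            fp_edge_bias >= 0, fp_edge_bias <= 1, occlusion_coef >= 0,
            dropout_rate >= 0, dropout_rate < 1)
  structure(list(center_jitter_sigma = center_jitter_sigma,
                 center_bias_sigma = center_bias_sigma,
                 size_jitter_frac = size_jitter_frac,
                 size_bias_frac = size_bias_frac,
                 miss_midpoint_px = miss_midpoint_px,
                 miss_slope_px = miss_slope_px,
                 dropout_rate = dropout_rate,
                 occlusion_coef = occlusion_coef,
                 fp_rate = fp_rate,
                 fp_edge_bias = fp_edge_bias,
                 conf_midpoint_px = conf_midpoint_px,
                 conf_slope_px = conf_slope_px, conf_sigma = conf_sigma,
                 conf_wiggle = conf_wiggle),
            class = "noise_config")
}

#' Zero-noise configuration (detections identical to ground truth)
#' @return A `noise_config` with every noise source disabled.
#' @export
no_noise <- function() {
  noise_config(center_jitter_sigma = 0, center_bias_sigma = 0,
               size_jitter_frac = 0, size_bias_frac = 0,
               miss_midpoint_px = -Inf, dropout_rate = 0,
               occlusion_coef = 0, fp_rate = 0,
               conf_sigma = 0, conf_wiggle = 0)
}

#' Lay out plants in the world
#'
#' Places target-row plants on a jittered grid at `plant_spacing` along the
#' plot, each site occupied with probability `emergence_rate`; side rows sit
#' beyond the ditch on each side with occupancy scaled by
#' `side_row_sparsity`. The true row count `y` is the number of target-row
#' plants (conservation: every identity in the output belongs to exactly one
#' plant).
#'
#' @param scene a [scene_config()].
#' @return A list of class `scene_truth`: `plants` (tibble: `id`, `x_m`,
#'   `lat_m`, `row` in `"target"` / `"side_left"` / `"side_right"`) and `y`
#'   (true target-row count).
#' @export
layout_plants <- function(scene = scene_config()) {
  sites_x <- seq(scene$plant_spacing / 2, scene$plot_length,
                 by = scene$plant_spacing)
  place_row <- function(lat_center, occupancy, row_name) {
    occupied <- stats::runif(length(sites_x)) < occupancy
    n <- sum(occupied)
    if (n == 0) {
      return(tibble::tibble(x_m = double(), lat_m = double(),
                            row = character()))
    }
    tibble::tibble(
      x_m = sites_x[occupied] + stats::rnorm(n, 0, scene$position_jitter),
      lat_m = lat_center + stats::rnorm(n, 0, scene$lateral_sd),
      row = row_name)
  }
  rows <- list(place_row(0, scene$emergence_rate, "target"))
  if (scene$n_side_rows > 0) {
    side_occ <- scene$emergence_rate * scene$side_row_sparsity
    for (k in seq_len(scene$n_side_rows)) {
      lat <- scene$plot_width / 2 + scene$ditch_width +
        (k - 0.5) * scene$plant_spacing * 4
      rows <- c(rows, list(place_row(-lat, side_occ, "side_left"),
                           place_row(lat, side_occ, "side_right")))
    }
  }
  plants <- dplyr::bind_rows(rows)
  plants <- dplyr::mutate(plants, id = dplyr::row_number(),
                          .before = "x_m")
  structure(list(plants = plants, y = sum(plants$row == "target"),
                 scene = scene),
            class = "scene_truth")
}

# camera basis vectors for a camera pitched tilt degrees below horizontal,
# facing +X. forward f, right r, image-down d (world directions).
camera_basis <- function(tilt_deg) {
  th <- tilt_deg * pi / 180
  list(forward = c(cos(th), 0, -sin(th)),
       right = c(0, 1, 0),
       down = c(-sin(th), 0, -cos(th)))
}

#' Project world points through the walking pinhole camera
#'
#' Pinhole projection for the camera at along-row position `cam_x`, height
#' `camera_height`, pitched `tilt_deg` below the horizontal. Image origin is
#' the top-left corner; y grows downward, so approaching ground points move
#' toward the lower edge as the camera advances.
#'
#' @param points tibble/data frame with `x_m`, `lat_m` (and optionally
#'   `z_m`, default 0) world coordinates in metres.
#' @param cam_x camera along-row position, metres.
#' @param scene a [scene_config()].
#' @return A tibble with `u`, `v` (pixels), `depth` (metres, camera-frame)
#'   and `visible` (positive depth and inside the frame).
#' @export
project_points <- function(points, cam_x, scene = scene_config()) {
  z_m <- if ("z_m" %in% names(points)) points$z_m else 0
  basis <- camera_basis(scene$tilt_deg)
  px <- points$x_m - cam_x
  py <- points$lat_m
  pz <- z_m - scene$camera_height
  depth <- px * basis$forward[1] + py * basis$forward[2] +
    pz * basis$forward[3]
  rightc <- px * basis$right[1] + py * basis$right[2] + pz * basis$right[3]
  downc <- px * basis$down[1] + py * basis$down[2] + pz * basis$down[3]
  u <- scene$frame_size[1] / 2 + scene$focal_px * rightc / depth
  v <- scene$frame_size[2] / 2 + scene$focal_px * downc / depth
  visible <- depth > 0.05 & u >= 0 & u <= scene$frame_size[1] &
    v >= 0 & v <= scene$frame_size[2]
  tibble::tibble(u = u, v = v, depth = depth, visible = visible)
}

#' Render ground-truth boxes for every frame of the walk
#'
#' The camera advances `walk_speed / fps` metres per frame from
#' `-start_margin` to `plot_length + end_margin`. Each visible plant becomes
#' a box centred on its projection with pixel size `plant_diameter *
#' focal_px / depth`, clipped to the frame; a plant is rendered only while
#' its centre is inside the frame, so once it passes the lower edge its
#' identity never reappears.
#'
#' @param truth a [layout_plants()] result.
#' @param scene a [scene_config()] (defaults to the one stored in `truth`).
#' @return A detection tibble with identities (`id` = plant id, `conf` = 1)
#'   plus a `row` column naming the source row.
#' @export
render_truth <- function(truth, scene = truth$scene) {
  step <- scene$walk_speed / scene$fps
  cam_xs <- seq(-scene$start_margin,
                scene$plot_length + scene$end_margin, by = step)
  plants <- truth$plants
  frames <- purrr::map(seq_along(cam_xs), function(f) {
    pr <- project_points(plants, cam_xs[f], scene)
    size <- scene$diameter_eff * scene$focal_px / pr$depth
    vis <- pr$visible
    if (!any(vis)) return(NULL)
    tibble::tibble(frame = f, id = plants$id[vis],
                   x = pr$u[vis] - size[vis] / 2,
                   y = pr$v[vis] - size[vis] / 2,
                   w = size[vis], h = size[vis], conf = 1,
                   row = plants$row[vis])
  })
  out <- dplyr::bind_rows(frames)
  clipped <- clip_boxes(out, scene$frame_size)
  clipped[!clipped$degenerate, setdiff(names(clipped), "degenerate")]
}

#' Corrupt ground-truth boxes into detector-like output
#'
#' Applies the [noise_config()] model: each truth box is dropped with the
#' height-dependent miss probability; survivors get centre and size jitter
#' and a size-dependent confidence; Poisson-many spurious boxes per frame
#' are added, biased toward the projected ditch edges.
#'
#' @param truth_det rendered truth detections ([render_truth()]).
#' @param noise a [noise_config()].
#' @param scene a [scene_config()] (frame size and ditch geometry for the
#'   false-positive placement).
#' @param seed optional integer seed for reproducibility.
#' @return A detection tibble (ids set to -1).
#' @export
corrupt_detections <- function(truth_det, noise = noise_config(),
                               scene = scene_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(truth_det)
  # per-plant detectability threshold ~ Logistic(midpoint, slope): marginal
  # P(miss | h) = plogis((midpoint - h)/slope), correlated across frames
  ids <- sort(unique(truth_det$id))
  thr <- if (is.finite(noise$miss_midpoint_px)) {
    stats::qlogis(stats::runif(length(ids)), noise$miss_midpoint_px,
                  noise$miss_slope_px)
  } else {
    rep(-Inf, length(ids))
  }
  names(thr) <- as.character(ids)
  conf_bias <- stats::rnorm(length(ids), 0, noise$conf_sigma)
  names(conf_bias) <- as.character(ids)
  # sustained occlusion: susceptibility drawn once per plant, cover fraction
  # recomputed per frame, so a covered plant stays missed while the cover
  # lasts rather than flickering
  occ_u <- stats::runif(length(ids))
  names(occ_u) <- as.character(ids)
  occluded <- rep(FALSE, n)
  if (noise$occlusion_coef > 0) {
    for (f in unique(truth_det$frame)) {
      rows <- which(truth_det$frame == f)
      if (length(rows) < 2) next
      cov <- cover_fraction(truth_det[rows, ])
      occluded[rows] <- noise$occlusion_coef * cov >
        occ_u[as.character(truth_det$id[rows])]
    }
  }
  keep <- truth_det$h >= thr[as.character(truth_det$id)] &
    stats::runif(n) >= noise$dropout_rate & !occluded
  det <- truth_det[keep, c("frame", "id", "x", "y", "w", "h")]
  m <- nrow(det)
  if (m > 0) {
    key <- as.character(det$id)
    bias_x <- stats::rnorm(length(ids), 0, noise$center_bias_sigma)
    bias_y <- stats::rnorm(length(ids), 0, noise$center_bias_sigma)
    sbias_w <- stats::rnorm(length(ids), 0, noise$size_bias_frac)
    sbias_h <- stats::rnorm(length(ids), 0, noise$size_bias_frac)
    names(bias_x) <- names(bias_y) <- names(sbias_w) <- names(sbias_h) <-
      as.character(ids)
    det$x <- det$x + unname(bias_x[key]) +
      stats::rnorm(m, 0, noise$center_jitter_sigma)
    det$y <- det$y + unname(bias_y[key]) +
      stats::rnorm(m, 0, noise$center_jitter_sigma)
    scale_w <- pmax(0.2, 1 + unname(sbias_w[key]) +
                      stats::rnorm(m, 0, noise$size_jitter_frac))
    scale_h <- pmax(0.2, 1 + unname(sbias_h[key]) +
                      stats::rnorm(m, 0, noise$size_jitter_frac))
    det$w <- det$w * scale_w
    det$h <- det$h * scale_h
    mean_conf <- 0.1 + 0.75 * stats::plogis((det$h - noise$conf_midpoint_px) /
                                              noise$conf_slope_px)
    det$conf <- pmin(1, pmax(0.01,
      mean_conf + unname(conf_bias[as.character(det$id)]) +
        stats::rnorm(m, 0, noise$conf_wiggle)))
    det$id <- NULL
  } else {
    det$id <- NULL
    det$conf <- double(0)
  }
  # spurious detections, biased toward the ditch edges
  frames <- sort(unique(truth_det$frame))
  n_fp <- stats::rpois(length(frames), noise$fp_rate)
  fp <- NULL
  if (sum(n_fp) > 0) {
    fp_frames <- rep(frames, n_fp)
    k <- length(fp_frames)
    at_edge <- stats::runif(k) < noise$fp_edge_bias
    # ditch edge world lines at +/- plot_width/2 .. + ditch; sample a world
    # point on either ditch and project it for the frame's camera position
    step <- scene$walk_speed / scene$fps
    cam_xs <- -scene$start_margin + (fp_frames - 1) * step
    lat <- (scene$plot_width / 2 +
              stats::runif(k, 0, scene$ditch_width)) * sample(c(-1, 1), k,
                                                              replace = TRUE)
    ahead <- stats::runif(k, 0.2, 6)
    pr <- project_points(tibble::tibble(x_m = cam_xs + ahead, lat_m = lat),
                         cam_x = cam_xs, scene = scene)
    size <- scene$diameter_eff * scene$focal_px / pr$depth
    u <- ifelse(at_edge & pr$visible, pr$u,
                stats::runif(k, 0, scene$frame_size[1]))
    v <- ifelse(at_edge & pr$visible, pr$v,
                stats::runif(k, 0, scene$frame_size[2]))
    sz <- ifelse(at_edge & pr$visible, size, stats::runif(k, 4, 30))
    fp <- tibble::tibble(frame = fp_frames, x = u - sz / 2, y = v - sz / 2,
                         w = sz, h = sz,
                         conf = stats::runif(k, 0.25, 0.7))
  }
  det <- dplyr::bind_rows(det, fp)
  det$id <- -1L
  det <- clip_boxes(detections(det), scene$frame_size)
  det <- det[!det$degenerate & det$w > 0.5 & det$h > 0.5, ]
  detections(det[setdiff(names(det), "degenerate")])
}

#' Generate a full simulated video bundle
#'
#' Runs layout → render → corrupt and optionally writes the bundle to disk
#' in the package's interchange formats: `det.txt` and `gt.txt` (MOT
#' dialect), `scene.yaml` (configuration echo) and `truth.json` (true row
#' count). Deterministic for a given seed.
#'
#' @param scene a [scene_config()].
#' @param noise a [noise_config()].
#' @param seed integer seed.
#' @param dir optional output directory (created if needed).
#' @return An object of class `simulated_video`: `detections`, `truth`
#'   (rendered boxes with identities), `scene_truth` ([layout_plants()]
#'   output), `y` (true row count), `scene`, `noise`, `seed`.
#' @export
simulate_video <- function(scene = scene_config(), noise = noise_config(),
                           seed = 1, dir = NULL) {
  set.seed(seed)
  truth <- layout_plants(scene)
  truth_det <- render_truth(truth, scene)
  det <- corrupt_detections(truth_det, noise, scene)
  out <- structure(list(detections = det, truth = truth_det,
                        scene_truth = truth, y = truth$y, scene = scene,
                        noise = noise, seed = seed),
                   class = "simulated_video")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_mot(det, file.path(dir, "det.txt"))
    write_mot(truth_det[setdiff(names(truth_det), "row")],
              file.path(dir, "gt.txt"))
    yaml::write_yaml(list(scene = unclass(scene), noise = unclass(noise),
                          seed = seed), file.path(dir, "scene.yaml"))
    jsonlite::write_json(list(y = truth$y), file.path(dir, "truth.json"),
                         auto_unbox = TRUE)
  }
  out
}

#' @export
print.simulated_video <- function(x, ...) {
  cat("Simulated walking video\n")
  cat(sprintf("  tilt %g deg, %d frames, %d plants (target row y = %d)\n",
              x$scene$tilt_deg, max(x$truth$frame),
              nrow(x$scene_truth$plants), x$y))
  cat(sprintf("  %d truth boxes -> %d detections (seed %d)\n",
              nrow(x$truth), nrow(x$detections), x$seed))
  invisible(x)
}

# fraction of each box's area covered by the most-overlapping other box in
# the same frame
cover_fraction <- function(boxes) {
  n <- nrow(boxes)
  if (n < 2) return(rep(0, n))
  x1 <- boxes$x; y1 <- boxes$y
  x2 <- boxes$x + boxes$w; y2 <- boxes$y + boxes$h
  iw <- pmin(outer(x2, rep(1, n)), outer(rep(1, n), x2)) -
    pmax(outer(x1, rep(1, n)), outer(rep(1, n), x1))
  ih <- pmin(outer(y2, rep(1, n)), outer(rep(1, n), y2)) -
    pmax(outer(y1, rep(1, n)), outer(rep(1, n), y1))
  inter <- pmax(iw, 0) * pmax(ih, 0)
  diag(inter) <- 0
  apply(inter, 1, max) / (boxes$w * boxes$h)
}
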