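test_that("plant layout follows grid arithmetic and emergence probability", {
  full <- layout_plants(scene_config(emergence_rate = 1, n_side_rows = 0,
                                     position_jitter = 0, lateral_sd = 0))
  expect_equal(full$y, floor(14.4 / 0.05))
  none <- layout_plants(scene_config(emergence_rate = 0, n_side_rows = 0))
  expect_equal(none$y, 0)
})

test_that("occupancy matches the binomial expectation over seeds", {
  n_sites <- floor(14.4 / 0.05)
  p <- 0.5
  counts <- sapply(1:10, function(s) {
    set.seed(s)
    layout_plants(scene_config(emergence_rate = p, n_side_rows = 0))$y
  })
  expect_lt(abs(mean(counts) - n_sites * p),
            3 * sqrt(n_sites * p * (1 - p) / 10))
})

test_that("points on the optical axis project to the principal point", {
  scene <- scene_config(tilt_deg = 45)
  # the optical axis leaves the camera at 45 deg down and hits the ground
  # at distance camera_height ahead of the camera
  pr <- project_points(tibble::tibble(x_m = 0.5, lat_m = 0), cam_x = 0, scene)
  expect_equal(pr$u, scene$frame_size[1] / 2, tolerance = 1e-9)
  expect_equal(pr$v, scene$frame_size[2] / 2, tolerance = 1e-9)
})

test_that("pinhole similarity: double the depth, half the pixel size", {
  scene <- scene_config(tilt_deg = 90)
  # straight-down camera: depth equals height above the point
  pr <- project_points(tibble::tibble(x_m = c(0, 0), lat_m = c(0.1, 0.1),
                                      z_m = c(0, -0.5)),
                       cam_x = 0, scene)
  expect_equal(pr$depth[2], 2 * pr$depth[1])
  size <- scene$diameter_eff * scene$focal_px / pr$depth
  expect_equal(size[1] / size[2], 2)
})

test_that("projected ground density increases toward the image top at 45°", {
  scene <- scene_config(tilt_deg = 45)
  grid <- expand.grid(x_m = seq(0.5, 12, 0.1), lat_m = seq(-0.5, 0.5, 0.1))
  pr <- project_points(tibble::as_tibble(grid), cam_x = 0, scene)
  vis <- pr[pr$visible, ]
  bands <- table(cut(vis$v, seq(0, 1080, 270)))
  expect_true(bands[1] > bands[4])  # most points compressed into the top
})

test_that("truth boxes shrink monotonically from bottom to top at 45°", {
  scene <- quick_scene(plot_length = 14.4)
  sim <- simulate_video(scene, no_noise(), seed = 1)
  tr <- sim$truth[sim$truth$frame == 20, ]
  med <- tapply(tr$h, cut(tr$y, seq(0, 1080, 216)), median, na.rm = TRUE)
  med <- med[!is.na(med)]
  expect_true(all(diff(med) > 0))
  # foreground tens of pixels, top band single digits
  expect_gt(max(med), 30)
  expect_lt(min(med), 10)
})

test_that("at 90° box size barely varies across the frame", {
  scene <- quick_scene(tilt_deg = 90)
  sim <- simulate_video(scene, no_noise(), seed = 1)
  tr <- sim$truth
  full <- tr[tr$h == max(tr$h) | tr$h > 0.9 * max(tr$h), ]
  expect_lt(stats::sd(full$h) / mean(full$h), 0.1)
})

test_that("central-band ground scale is within 20% of 800 px/m", {
  for (tilt in c(45, 90)) {
    scene <- scene_config(tilt_deg = tilt)
    # two points 10 cm apart laterally, both on the optical axis depth
    d0 <- scene$camera_height / sin(tilt * pi / 180)
    x_axis <- scene$camera_height / tan(tilt * pi / 180)
    pts <- tibble::tibble(x_m = x_axis, lat_m = c(0, 0.1))
    pr <- project_points(pts, cam_x = 0, scene)
    scale <- abs(diff(pr$u)) / 0.1
    expect_lt(abs(scale - 800) / 800, 0.2)
  }
})

test_that("a plant's identity ends at the bottom edge and never returns", {
  scene <- quick_scene()
  sim <- simulate_video(scene, no_noise(), seed = 2)
  tr <- sim$truth
  for (pid in unique(tr$id)[1:10]) {
    frames <- tr$frame[tr$id == pid]
    expect_equal(frames, seq(min(frames), max(frames)))
  }
})

test_that("zero noise returns the truth boxes minus identities", {
  scene <- quick_scene()
  sim <- simulate_video(scene, no_noise(), seed = 3)
  expect_equal(nrow(sim$detections), nrow(sim$truth))
  expect_true(all(sim$detections$id == -1))
  a <- dplyr::arrange(sim$detections, frame, x)
  b <- dplyr::arrange(sim$truth, frame, x)
  expect_equal(a$x, b$x)
  expect_equal(a$h, b$h)
})

test_that("total misses follow the marginal miss curve", {
  scene <- quick_scene(plot_length = 4.8)
  noise <- noise_config(fp_rate = 0, dropout_rate = 0, occlusion_coef = 0,
                        center_jitter_sigma = 0, center_bias_sigma = 0,
                        size_jitter_frac = 0, size_bias_frac = 0)
  # boxes near a fixed height band: miss fraction approx plogis((10 - h)/2)
  sims <- lapply(1:6, function(s) simulate_video(scene, noise, seed = s))
  tr <- dplyr::bind_rows(lapply(sims, `[[`, "truth"), .id = "rep")
  de <- dplyr::bind_rows(lapply(sims, `[[`, "detections"), .id = "rep")
  band <- tr[tr$h >= 11 & tr$h <= 14, ]
  expect_gt(nrow(band), 200)
  # count how many of those boxes survived into the detections (match by
  # frame + position since ids are dropped)
  key_t <- paste(band$rep, band$frame, round(band$x, 2))
  key_d <- paste(de$rep, de$frame, round(de$x, 2))
  surv <- mean(key_t %in% key_d)
  expected_miss <- mean(plogis((10 - band$h) / 2))
  expect_lt(abs((1 - surv) - expected_miss), 0.15)
})

test_that("false positives per frame are Poisson with the configured mean", {
  scene <- quick_scene(plot_length = 4.8)
  noise <- noise_config(fp_rate = 1.2, miss_midpoint_px = -Inf,
                        dropout_rate = 0, occlusion_coef = 0,
                        center_jitter_sigma = 0, center_bias_sigma = 0,
                        size_jitter_frac = 0, size_bias_frac = 0)
  sim <- simulate_video(scene, noise, seed = 5)
  n_frames <- max(sim$truth$frame)
  n_fp <- nrow(sim$detections) - nrow(sim$truth)
  lambda <- 1.2 * n_frames
  expect_lt(abs(n_fp - lambda), 3 * sqrt(lambda))
})

test_that("simulation output is deterministic per seed", {
  scene <- quick_scene()
  a <- simulate_video(scene, noise_config(), seed = 9)
  b <- simulate_video(scene, noise_config(), seed = 9)
  expect_identical(a$detections, b$detections)
  expect_identical(a$truth, b$truth)
  c <- simulate_video(scene, noise_config(), seed = 10)
  expect_false(identical(a$detections, c$detections))
})

test_that("bundle files on disk round-trip through the readers", {
  dir <- withr::local_tempdir()
  scene <- quick_scene()
  sim <- simulate_video(scene, noise_config(), seed = 1, dir = dir)
  expect_true(all(file.exists(file.path(dir, c("det.txt", "gt.txt",
                                               "scene.yaml", "truth.json")))))
  det <- read_mot(file.path(dir, "det.txt"))
  expect_equal(nrow(det), nrow(sim$detections))
  gt <- read_mot(file.path(dir, "gt.txt"), kind = "ground_truth")
  expect_setequal(unique(gt$id), unique(sim$truth$id))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$y, sim$y)
})

test_that("same-frame truth-box overlap is higher at 90° than at 45°", {
  # measured in the central image band, where both views share the 800 px/m
  # ground calibration; outside it the oblique view's far-field compression
  # (boxes of a few pixels with near-zero gaps) dominates the average and
  # reflects image-plane geometry rather than canopy overlap
  mean_overlap <- function(tilt, seed) {
    scene <- scene_config(plot_length = 3.6, tilt_deg = tilt,
                          n_side_rows = 0)
    sim <- simulate_video(scene, no_noise(), seed = seed)
    tr <- sim$truth
    cy <- tr$y + tr$h / 2
    tr <- tr[cy >= 340 & cy <= 740, ]
    frames <- unique(tr$frame)
    frames <- frames[seq(1, length(frames), 10)]
    mean(sapply(frames, function(f) {
      b <- tr[tr$frame == f, ]
      if (nrow(b) < 2) return(NA)
      iou <- box_iou(b, b)
      diag(iou) <- 0
      mean(apply(iou, 1, max))
    }), na.rm = TRUE)
  }
  ov45 <- mean(sapply(1:3, function(s) mean_overlap(45, s)))
  ov90 <- mean(sapply(1:3, function(s) mean_overlap(90, s)))
  expect_gt(ov90, ov45)
})
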