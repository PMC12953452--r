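test_that("Hungarian assignment equals exhaustive enumeration", {
  withr::with_seed(99, {
    for (i in 1:60) {
      n <- sample(1:6, 1); m <- sample(1:6, 1)
      cost <- matrix(runif(n * m), n, m)
      asg <- hungarian_assign(cost)
      ok <- !is.na(asg)
      expect_equal(sum(ok), min(n, m))
      expect_equal(sum(cost[cbind(which(ok), asg[ok])]),
                   brute_force_assignment(cost), tolerance = 1e-10)
    }
  })
})

test_that("association maximises total IoU and respects the threshold", {
  # two tracks over two swapped detections: optimal assignment keeps each
  # on its own box, verified against both permutations by hand
  tracks <- data.frame(x = c(0, 100), y = 0, w = 50, h = 50)
  dets <- data.frame(x = c(10, 90), y = 0, w = 50, h = 50)
  out <- associate_detections(tracks, dets, threshold = 0.3)
  expect_equal(out$matches[order(out$matches[, 1]), 2], c(1L, 2L))
  iou <- box_iou(tracks, dets)
  expect_gte(iou[1, 1] + iou[2, 2], iou[1, 2] + iou[2, 1])

  # IoU below threshold is rejected into both unmatched sets
  far <- data.frame(x = 40, y = 40, w = 50, h = 50)  # IoU ~ 0.03
  out2 <- associate_detections(data.frame(x = 0, y = 0, w = 50, h = 50),
                               far, threshold = 0.3)
  expect_equal(nrow(out2$matches), 0)
  expect_equal(out2$unmatched_tracks, 1L)
  expect_equal(out2$unmatched_detections, 1L)
})

test_that("association on random instances attains the exhaustive optimum", {
  withr::with_seed(17, {
    for (i in 1:20) {
      nt <- sample(1:5, 1); nd <- sample(1:5, 1)
      tracks <- data.frame(x = runif(nt, 0, 150), y = runif(nt, 0, 150),
                           w = 60, h = 60)
      dets <- data.frame(x = runif(nd, 0, 150), y = runif(nd, 0, 150),
                         w = 60, h = 60)
      thr <- 0.2
      out <- associate_detections(tracks, dets, thr)
      got <- if (nrow(out$matches) > 0) {
        iou <- box_iou(tracks, dets)
        sum(iou[out$matches])
      } else 0
      best <- brute_force_det_match(box_iou(tracks, dets), thr)
      expect_equal(nrow(out$matches), best$n)
      expect_equal(got, best$total, tolerance = 1e-9)
    }
  })
})

test_that("zero-noise prediction is exact linear extrapolation", {
  trk <- sort_tracker(tracker_config(min_hits = 1, rescue_iou = 0,
                                     max_age = 10),
                      c(1920, 1080))
  # feed two frames of constant motion, then let it coast
  for (f in 1:2) {
    tracker_step(trk, det_row(f, 100 + 10 * (f - 1), 200 + 5 * (f - 1),
                              40, 40), f)
  }
  x2 <- trk$X[, 1]
  for (f in 3:7) tracker_step(trk, det_row(f, 0, 0, 1, 1, conf = 0)[0, ], f)
  # 5 coasting steps: closed-form linear extrapolation of (u, v)
  expect_equal(trk$X[1, 1], x2[1] + 5 * x2[5], tolerance = 1e-9)
  expect_equal(trk$X[2, 1], x2[2] + 5 * x2[6], tolerance = 1e-9)
})

test_that("zero velocity leaves the predicted box unchanged", {
  trk <- sort_tracker(tracker_config(min_hits = 1), c(1920, 1080))
  tracker_step(trk, det_row(1, 500, 500, 40, 40), 1)
  before <- trk$X[1:4, 1]
  tracker_step(trk, det_row(2, 0, 0, 1, 1)[0, ], 2)   # empty frame
  expect_equal(trk$X[1:4, 1], before, tolerance = 1e-9)
})

test_that("track lifecycle: confirmation, deletion, id reassignment", {
  cfg <- tracker_config(min_hits = 3, max_age = 2)
  trk <- sort_tracker(cfg, c(1920, 1080))
  # object present frames 1..5
  for (f in 1:5) tracker_step(trk, det_row(f, 100, 100 + 5 * f, 40, 40), f)
  expect_equal(trk$status, "CONFIRMED")
  expect_equal(trk$hits, 5L)
  first_id <- trk$id
  # gone for > max_age
  for (f in 6:9) tracker_step(trk, det_row(f, 0, 0, 1, 1)[0, ], f)
  expect_length(trk$id, 0)
  # reappears: a new id must be issued, never the old one
  tracker_step(trk, det_row(10, 100, 150, 40, 40), 10)
  expect_gt(trk$id, first_id)
})

test_that("single noiseless object yields one confirmed track and count 1", {
  cfg <- tracker_config(min_hits = 3)
  trk <- sort_tracker(cfg, c(1920, 1080))
  for (f in 1:10) tracker_step(trk, det_row(f, 100, 10 * f, 40, 40), f)
  expect_equal(length(unique(trk$confirmed_ids)), 1)
  tracker_finalize(trk)
  expect_equal(tracker_count(trk), 1)
})

test_that("empty video counts zero", {
  trk <- sort_tracker(tracker_config(), c(1920, 1080))
  for (f in 1:5) tracker_step(trk, det_row(f, 0, 0, 1, 1)[0, ], f)
  tracker_finalize(trk)
  expect_equal(tracker_count(trk), 0)
})

test_that("out-of-order frames are rejected", {
  trk <- sort_tracker(tracker_config(), c(1920, 1080))
  tracker_step(trk, det_row(3, 0, 0, 10, 10), 3)
  expect_error(tracker_step(trk, det_row(2, 0, 0, 10, 10), 2), "increasing")
})

test_that("lower-edge retirement uses the strict v >= height rule", {
  h <- 1080
  cfg <- tracker_config(min_hits = 1)
  trk <- sort_tracker(cfg, c(1920, h))
  # centre just above the edge: v = 1079 -> stays
  tracker_step(trk, det_row(1, 100, 1079 - 20, 40, 40), 1)
  expect_length(trk$id, 1)
  # centre clearly past the edge -> retired (the filtered state blends the
  # prediction with the measurement, so the boundary applies to the state)
  tracker_step(trk, det_row(2, 100, h, 40, 40), 2)
  expect_length(trk$id, 0)
  expect_equal(length(trk$retired_ids), 1)
  # the retired id can never be revived: same box reappearing gets a new id
  retired <- trk$retired_ids[1]
  tracker_step(trk, det_row(3, 100, 500, 40, 40), 3)
  expect_false(retired %in% trk$id)
})

test_that("a simulated plant crossing the bottom edge contributes exactly 1", {
  scene <- quick_scene()
  sim <- simulate_video(scene, no_noise(), seed = 4)
  cfg <- pipeline_config("off", confidence_threshold = 0,
                         tracker = tracker_config(min_hits = 1))
  res <- run_pipeline(sim$detections, cfg, scene$frame_size)
  log <- res$track_log
  # every id retired at most once, and ids never reappear after retirement
  trk_ids <- split(log$frame, log$id)
  for (frames in trk_ids) {
    expect_equal(frames, seq(min(frames), max(frames)))  # contiguous life
  }
  expect_equal(res$count, sim$y)
})

test_that("id uniqueness holds across a noisy simulation", {
  scene <- quick_scene(n_side_rows = 1)
  sim <- simulate_video(scene, noise_config(), seed = 8)
  res <- run_pipeline(sim$detections, pipeline_config("adaptive"),
                      scene$frame_size)
  log <- res$track_log
  # a track id's frame span must be contiguous: no id is ever respawned
  by_id <- split(log$frame, log$id)
  for (frames in by_id) {
    expect_equal(frames, seq(min(frames), max(frames)))
  }
})

test_that("counting vote excludes tracks whose detections were eliminated", {
  cfg <- tracker_config(min_hits = 2)
  trk <- sort_tracker(cfg, c(1920, 1080))
  for (f in 1:6) {
    fd <- dplyr::bind_rows(
      det_row(f, 100, 100 + 5 * f, 40, 40),    # retained object
      det_row(f, 900, 100 + 5 * f, 40, 40))    # eliminated object
    fd$retained <- c(TRUE, FALSE)
    tracker_step(trk, fd, f)
  }
  tracker_finalize(trk)
  expect_equal(tracker_count(trk), 1)
})
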