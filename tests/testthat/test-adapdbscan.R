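test_that("local spacings equal consecutive gaps of the kNN set", {
  pts <- cbind(x = c(0, 100, 200), y = c(0, 0, 0))
  sp <- horizontal_spacings(pts, k = 2)
  expect_equal(sp[[2]], c(100, 100))
  # duplicate points contribute zero spacings
  pts2 <- cbind(x = c(0, 0, 50), y = c(0, 0, 0))
  expect_true(0 %in% horizontal_spacings(pts2, k = 2)[[1]])
  expect_error(horizontal_spacings(pts[1, , drop = FALSE], 2), "at least 2")
})

test_that("local spacings agree with a brute-force all-pairs oracle", {
  withr::with_seed(7, {
    pts <- cbind(x = runif(50, 0, 800), y = runif(50, 0, 600))
  })
  sp <- horizontal_spacings(pts, k = 5)
  for (i in c(1, 13, 27, 50)) {
    expect_equal(sp[[i]], brute_force_spacings(pts, i, 5))
  }
})

test_that("spacing filter removes upper outliers by the IQR rule", {
  # Q3 of {10,10,10,10,500} (type 7) is 10, IQR 0, cutoff 10
  expect_equal(filter_spacings(c(10, 10, 10, 10, 500), 1.5), rep(10, 4))
  expect_equal(filter_spacings(rep(4, 6)), rep(4, 6))      # all equal kept
  expect_equal(filter_spacings(42), 42)                    # singleton kept
  expect_error(filter_spacings(numeric(0)), "empty")
  # minimum always survives
  withr::with_seed(1, {
    for (i in 1:20) {
      x <- rexp(sample(2:12, 1)) * 50
      expect_true(min(x) %in% filter_spacings(x))
    }
  })
})

test_that("adaptive radius honours floor, scale and ceiling", {
  cfg <- adap_config(alpha = 100)
  # span below alpha: scale clamps to 1
  expect_equal(adaptive_eps(50, 60, cfg), 60)
  # direct substitution: (200/100) * 60 = 120
  expect_equal(adaptive_eps(200, 60, cfg), 120)
  # ceiling binds at 250 px
  expect_equal(adaptive_eps(1e6, 200, cfg), 250)
  expect_error(adaptive_eps(10, 0, cfg), "positive")
})

test_that("adaptive min_samples follows the ceiling rule with floor 2", {
  expect_equal(adaptive_min_samples(c(4, 4, 4, 4), 0.5), 2)
  expect_equal(adaptive_min_samples(c(10, 10), 0.5), 5)
  expect_equal(adaptive_min_samples(c(9, 9, 9), 1e-9), 2)  # floor binds
  expect_error(adaptive_min_samples(numeric(0), 0.5), "empty")
})

test_that("uniform horizontal line yields eps equal to the spacing", {
  pts <- cbind(x = seq(0, 950, by = 50), y = rep(0, 20))
  ap <- compute_adaptive_params(pts, adap_config())
  expect_equal(ap$params$eps, rep(50, 20))
  expect_equal(ap$params$delta_v, rep(0, 20))
})

test_that("eps shrinks toward the compressed top of a perspective row", {
  # a single row seen obliquely: adjacent-plant image gaps shrink toward
  # the top of the frame; the adaptive radius must shrink with them
  gaps <- seq(2, 30, length.out = 60)      # fine at the top, coarse below
  y <- cumsum(gaps)
  withr::with_seed(2, {
    pts <- cbind(x = 960 + rnorm(60, 0, 2), y = y)
  })
  ap <- compute_adaptive_params(pts, adap_config())
  quart <- cut(ap$params$y, quantile(ap$params$y, 0:4 / 4),
               include.lowest = TRUE)
  med_eps <- tapply(ap$params$eps, quart, median)
  # non-decreasing with y: plateaus allowed where the 250 px ceiling binds
  expect_true(all(diff(med_eps) >= 0))
  expect_gt(max(med_eps), min(med_eps))
  expect_gt(stats::cor(ap$params$y, ap$params$median_spacing,
                       method = "spearman"), 0.9)
})

test_that("degenerate frames label everything noise", {
  pts <- cbind(x = c(0, 10), y = c(0, 0))
  lab <- adap_dbscan(pts[1:2, ], adap_config())
  expect_true(all(lab$role == "noise"))
  expect_equal(elimination_set(lab), 1:2)
  ap <- compute_adaptive_params(pts[1, , drop = FALSE], adap_config())
  expect_true(ap$degenerate)
})

test_that("adaptive eps always stays within [floor, 250] on random frames", {
  cfg <- adap_config()
  withr::with_seed(11, {
    for (i in 1:20) {
      n <- sample(10:120, 1)
      pts <- cbind(x = runif(n, 0, 1920), y = runif(n, 0, 1080))
      ap <- compute_adaptive_params(pts, cfg)
      expect_true(all(ap$params$eps >= cfg$eps_floor))
      expect_true(all(ap$params$eps <= cfg$eps_max))
      expect_true(all(ap$params$rho >= 1))
    }
  })
})

test_that("fixed DBSCAN reproduces a brute-force reference on random data", {
  withr::with_seed(23, {
    for (i in 1:30) {
      n <- sample(20:120, 1)
      pts <- cbind(x = runif(n, 0, 500), y = runif(n, 0, 500))
      eps <- runif(1, 20, 90)
      ms <- sample(2:5, 1)
      got <- fixed_dbscan(pts, eps, ms, border_points = FALSE)
      ref <- reference_dbscan(pts, eps, ms)
      core_ref <- ref$core
      expect_identical(got$role == "core", core_ref)
      # compare partitions over core points only (border assignment of the
      # reference follows discovery order, which is not part of the contract)
      expect_true(same_partition(got$label[core_ref], ref$label[core_ref]))
    }
  })
})

test_that("fixed DBSCAN limit cases: huge eps one cluster, tiny eps all noise", {
  withr::with_seed(3, {
    pts <- cbind(x = runif(40, 0, 100), y = runif(40, 0, 100))
  })
  all_in <- fixed_dbscan(pts, eps = 1e6, min_samples = 2)
  expect_equal(unique(all_in$label), 1L)
  d <- as.matrix(stats::dist(pts)); diag(d) <- Inf
  none <- fixed_dbscan(pts, eps = min(d) / 2, min_samples = 2)
  expect_true(all(none$role == "noise"))
})

test_that("groups split by more than eps_max are never merged", {
  withr::with_seed(5, {
    a <- cbind(x = runif(25, 0, 100), y = runif(25, 0, 100))
    b <- cbind(x = runif(25, 0, 100) + 600, y = runif(25, 0, 100))
  })
  lab <- adap_dbscan(rbind(a, b), adap_config())
  la <- lab$label[1:25]; lb <- lab$label[26:50]
  expect_equal(length(intersect(na.omit(la), na.omit(lb))), 0)
})

test_that("homogeneous frames make adaptive equal fixed DBSCAN (limit case)", {
  # uniform row: scale clamps to 1 so every eps equals the shared spacing;
  # adaptive must then agree with fixed DBSCAN at that eps and the
  # aggregated min_samples
  pts <- cbind(x = seq(0, 950, by = 50), y = rep(0, 20))
  cfg <- adap_config(alpha = 1e9)   # force scale = 1: eps = local median gap
  ada <- adap_dbscan(pts, cfg)
  eps_shared <- unique(round(attr(ada, "params")$eps, 9))
  expect_length(eps_shared, 1)
  expect_equal(eps_shared, 50)
  fix <- fixed_dbscan(pts, eps_shared, attr(ada, "min_samples"))
  expect_true(same_partition(ada$label, fix$label))
})

test_that("target selection keeps the biggest cluster and drops noise", {
  pts <- cluster_with_noise()
  lab <- fixed_dbscan(pts, eps = 15, min_samples = 3)
  keep <- select_target(lab, frame_size = c(1000, 1000))
  expect_setequal(keep, 1:25)
  # empty labeling
  empty <- fixed_dbscan(pts[26:27, ], eps = 5, min_samples = 2)
  expect_equal(select_target(empty, c(1000, 1000)), integer(0))
})

test_that("side cluster loses to a central cluster of equal-or-larger size", {
  center <- as.matrix(expand.grid(x = seq(460, 560, 20), y = seq(0, 140, 20)))
  side <- as.matrix(expand.grid(x = seq(0, 40, 20), y = seq(0, 40, 20)))
  pts <- rbind(center, side)
  colnames(pts) <- c("x", "y")
  lab <- fixed_dbscan(pts, eps = 25, min_samples = 3)
  keep <- select_target(lab, frame_size = c(1000, 1000))
  expect_true(all(keep <= nrow(center)))
})

test_that("eps ceiling conversion matches the field calibration", {
  expect_equal(px_to_meters(250, 800), 0.3125)
})
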