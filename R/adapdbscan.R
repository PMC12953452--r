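#' Configuration for density-adaptive DBSCAN
#'
#' Parameters of the adaptive clustering stage that separates target-row
#' seedling detections from neighbour-row and ditch clutter under perspective
#' distortion. The neighbourhood radius is set per point as
#'
#' \deqn{eps = \min(eps_{max},\; \max(1, \Delta v / \alpha) \times
#'       \mathrm{median}(D_{filtered}))}
#'
#' where \eqn{\Delta v} is the vertical pixel span of the point's
#' k-nearest-neighbour set, \eqn{\alpha} maps that span to a scale factor, and
#' \eqn{D_{filtered}} are the local horizontal plant spacings after removal of
#' outlying large gaps. The density threshold is
#' \eqn{min\_samples = \max(floor, \lceil \bar\rho\,\delta \rceil)} with
#' \eqn{\bar\rho} the mean neighbourhood density over a point's k-NN set and
#' \eqn{\delta} a density decay factor. The 250 px ceiling and the filtered
#' median form a dual-threshold constraint that stops the radius expanding
#' across the drainage ditch (250 px is about 0.3125 m at the 800 px/m
#' central-band calibration, wider than the 0.3 m ditch).
#'
#' @param alpha normalisation constant for the vertical span, pixels
#'   (default 80; with the default global span support on a full 1080 px
#'   frame this sets the radius to roughly ten times the local
#'   adjacent-plant gap median — the projected-gap median is dragged down
#'   by near-duplicate projections, so a large multiple is needed to keep a
#'   row connected through missed detections).
#' @param delta density decay factor in (0, 1].
#' @param k_neighbors neighbourhood size for local statistics (>= 2).
#' @param eps_max neighbourhood-radius ceiling, pixels (default 250).
#' @param eps_floor neighbourhood-radius floor, pixels (default 1).
#' @param spacing_outlier_multiplier IQR multiplier for spacing outlier
#'   removal (default 1.5).
#' @param min_samples_floor smallest admissible `min_samples` (default 2: a
#'   cluster needs at least two members).
#' @param pixels_per_meter central-band image calibration (default 800).
#' @param border_points if `TRUE` (default) non-core points within a core's
#'   radius join its cluster (classic DBSCAN border semantics); if `FALSE`
#'   points are strictly core or noise.
#' @param per_point_min_samples if `TRUE` each point is tested against its own
#'   locally aggregated `min_samples` instead of the frame-level value.
#' @param core_link connectivity rule between core points: `"mutual"`
#'   (default; cores connect when their distance is within both points'
#'   radii, so a sparse outlier's inflated radius cannot attach it to a
#'   dense cluster across the perspective-narrowed ditch) or `"either"`
#'   (within either radius; more permissive, keeps chains with abruptly
#'   growing radii connected).
#' @param delta_v_support support of the vertical span `delta_v`:
#'   `"global"` (default; the span of all points in the frame, so the scale
#'   factor is shared and adaptivity comes from the local spacing median) or
#'   `"local"` (the span of each point's k-NN set). The local reading makes
#'   eps grow with the square of the local point spacing, which on strongly
#'   perspective-compressed frames either starves the dense band or drives
#'   sparse regions straight to the ceiling; the global span keeps eps
#'   proportional to the local spacing.
#' @return A list of class `adap_config`.
#' @export
adap_config <- function(alpha = 80, delta = 0.5, k_neighbors = 5,
                        eps_max = 250, eps_floor = 1,
                        spacing_outlier_multiplier = 1.5,
                        min_samples_floor = 2, pixels_per_meter = 800,
                        border_points = TRUE,
                        per_point_min_samples = FALSE,
                        core_link = c("mutual", "either"),
                        delta_v_support = c("global", "local")) {
  delta_v_support <- match.arg(delta_v_support)
  core_link <- match.arg(core_link)
  stopifnot(eps_floor <= eps_max, delta > 0, k_neighbors >= 2,
            alpha > 0, min_samples_floor >= 1, pixels_per_meter > 0,
            spacing_outlier_multiplier >= 0)
  structure(list(alpha = alpha, delta = delta, k_neighbors = k_neighbors,
                 eps_max = eps_max, eps_floor = eps_floor,
                 spacing_outlier_multiplier = spacing_outlier_multiplier,
                 min_samples_floor = min_samples_floor,
                 pixels_per_meter = pixels_per_meter,
                 border_points = border_points,
                 per_point_min_samples = per_point_min_samples,
                 core_link = core_link,
                 delta_v_support = delta_v_support),
            class = "adap_config")
}

#' Convert a pixel distance to metres at the central-band calibration
#'
#' @param px distance in pixels.
#' @param pixels_per_meter calibration constant (default 800).
#' @return Distance in metres (e.g. the 250 px radius ceiling is 0.3125 m).
#' @export
px_to_meters <- function(px, pixels_per_meter = 800) px / pixels_per_meter

as_point_matrix <- function(points) {
  if (is.matrix(points)) {
    stopifnot(ncol(points) >= 2)
    return(points[, 1:2, drop = FALSE])
  }
  cbind(points$x, points$y)
}

# k smallest values' indices per row of a distance matrix, excluding self
knn_indices <- function(d, k) {
  n <- nrow(d)
  k <- min(k, n - 1)
  lapply(seq_len(n), function(i) {
    ord <- order(d[i, ])
    setdiff(ord, i)[seq_len(k)]
  })
}

#' Local horizontal plant spacings
#'
#' For each point, the horizontal gaps between x-adjacent members of the set
#' formed by the point and its k nearest neighbours (Euclidean). These gaps
#' estimate the local plant spacing; along a row of uniformly spaced plants
#' every gap equals the planting interval.
#'
#' @param points matrix or data frame of point coordinates (`x`, `y`, pixels).
#' @param k neighbourhood size.
#' @return A list of numeric vectors, one per point (length `min(k, n - 1)`).
#' @export
horizontal_spacings <- function(points, k) {
  pts <- as_point_matrix(points)
  n <- nrow(pts)
  if (n < 2) stop("need at least 2 points for spacing statistics",
                  call. = FALSE)
  d <- as.matrix(stats::dist(pts))
  nn <- knn_indices(d, k)
  lapply(seq_len(n), function(i) {
    xs <- sort(pts[c(i, nn[[i]]), 1])
    diff(xs)
  })
}

#' Remove outlying large spacings
#'
#' Drops values above `Q3 + multiplier * IQR` (type-7 quantiles). At least
#' one value always survives (the minimum is never an upper outlier).
#'
#' @param spacings numeric vector of spacings, pixels.
#' @param multiplier IQR multiplier (default 1.5).
#' @return The filtered vector.
#' @examples
#' filter_spacings(c(10, 10, 10, 10, 500))  # drops 500
#' @export
filter_spacings <- function(spacings, multiplier = 1.5) {
  if (length(spacings) == 0) stop("empty spacing list", call. = FALSE)
  q <- stats::quantile(spacings, c(0.25, 0.75), names = FALSE, type = 7)
  cutoff <- q[2] + multiplier * (q[2] - q[1])
  spacings[spacings <= cutoff]
}

#' Adaptive neighbourhood radius
#'
#' `eps = min(eps_max, max(1, delta_v / alpha) * median_spacing)`, then
#' floored at `eps_floor`. Compact (dense, distant) neighbourhoods with small
#' vertical span keep `eps` at the local median spacing; sparse foreground
#' neighbourhoods scale it up, capped by the dual-threshold ceiling.
#'
#' @param delta_v vertical pixel span of the local neighbourhood (>= 0);
#'   vectorised.
#' @param median_spacing median filtered local spacing, pixels (> 0);
#'   vectorised.
#' @param config an [adap_config()].
#' @return eps in pixels, within `[eps_floor, eps_max]`.
#' @export
adaptive_eps <- function(delta_v, median_spacing, config = adap_config()) {
  if (any(median_spacing <= 0)) stop("median spacing must be positive",
                                     call. = FALSE)
  if (any(delta_v < 0)) stop("vertical span must be non-negative",
                             call. = FALSE)
  eps <- pmax(1, delta_v / config$alpha) * median_spacing
  pmin(config$eps_max, pmax(config$eps_floor, eps))
}

#' Adaptive density threshold
#'
#' `min_samples = max(floor, ceiling(mean(rho) * delta))`: denser
#' neighbourhoods demand more members before a point counts as core.
#'
#' @param rho neighbourhood densities (counts, including the point itself)
#'   over a local point set.
#' @param delta density decay factor.
#' @param floor smallest admissible value (default 2).
#' @return An integer `min_samples`.
#' @examples
#' adaptive_min_samples(c(10, 10), 0.5)  # 5
#' @export
adaptive_min_samples <- function(rho, delta, floor = 2) {
  if (length(rho) == 0) stop("empty density list", call. = FALSE)
  max(as.integer(floor), as.integer(ceiling(mean(rho) * delta)))
}

#' Per-point adaptive clustering parameters
#'
#' Two-pass parameter determination. Pass 1, per point: find the k nearest
#' neighbours, take the vertical span `delta_v` and the filtered median
#' horizontal spacing over that set, derive `eps` via [adaptive_eps()], and
#' count the neighbourhood density `rho` (points within `eps`, self
#' included). Pass 2: aggregate `rho` over each point's neighbour set through
#' [adaptive_min_samples()]; the frame-level `min_samples` is the median of
#' the per-point values (rounded up).
#'
#' @param points matrix or data frame of detection centres (`x`, `y`).
#' @param config an [adap_config()].
#' @return A list with `params` (tibble: `x`, `y`, `eps`, `rho`, `delta_v`,
#'   `median_spacing`, `min_samples_local`), `min_samples` (frame-level
#'   integer) and `degenerate` (logical; `TRUE` when fewer than 2 points).
#' @export
compute_adaptive_params <- function(points, config = adap_config()) {
  pts <- as_point_matrix(points)
  n <- nrow(pts)
  if (n < config$k_neighbors + 1) {
    # too few points for meaningful local statistics: degenerate frame
    return(list(params = tibble::tibble(x = pts[, 1], y = pts[, 2],
                                        eps = rep(config$eps_floor, n),
                                        rho = rep(1L, n),
                                        delta_v = rep(0, n),
                                        median_spacing = rep(NA_real_, n),
                                        min_samples_local = rep(NA_integer_, n)),
                min_samples = NA_integer_, degenerate = TRUE))
  }
  d <- as.matrix(stats::dist(pts))
  nn <- knn_indices(d, config$k_neighbors)
  delta_v <- if (identical(config$delta_v_support, "global")) {
    rep(max(pts[, 2]) - min(pts[, 2]), n)
  } else {
    vapply(seq_len(n), function(i) {
      ys <- pts[c(i, nn[[i]]), 2]
      max(ys) - min(ys)
    }, numeric(1))
  }
  # local spacing reference: consecutive gaps between neighbourhood members
  # projected on the neighbourhood's principal axis (the local row
  # direction), outlier-filtered. Along a horizontal row this is exactly
  # the horizontal adjacent-plant gap; under an oblique view the row stacks
  # vertically in the image and pure x-gaps would collapse to the lateral
  # jitter, starving eps and shattering the row into fragments.
  med_sp <- vapply(seq_len(n), function(i) {
    S <- pts[c(i, nn[[i]]), , drop = FALSE]
    C <- sweep(S, 2, colMeans(S))
    axis <- eigen(crossprod(C), symmetric = TRUE)$vectors[, 1]
    gaps <- diff(sort(as.vector(C %*% axis)))
    stats::median(filter_spacings(gaps, config$spacing_outlier_multiplier))
  }, numeric(1))
  scale <- pmax(1, delta_v / config$alpha)
  eps <- pmin(config$eps_max, pmax(config$eps_floor, scale * med_sp))
  rho <- vapply(seq_len(n), function(i) sum(d[i, ] <= eps[i]), integer(1))
  ms_local <- vapply(seq_len(n), function(i) {
    adaptive_min_samples(rho[c(i, nn[[i]])], config$delta,
                         config$min_samples_floor)
  }, integer(1))
  list(params = tibble::tibble(x = pts[, 1], y = pts[, 2], eps = eps,
                               rho = rho, delta_v = delta_v,
                               median_spacing = med_sp,
                               min_samples_local = ms_local),
       min_samples = as.integer(ceiling(stats::median(ms_local))),
       degenerate = FALSE)
}

# DBSCAN-style expansion with a per-point radius. core test: rho_i >=
# min_samples_i. Cores p, q are connected under mutual reachability (their
# distance within BOTH radii): a sparse outlier's inflated radius alone
# cannot attach it to a dense cluster whose own radii are small, which is
# what keeps neighbour-row points from bridging the perspective-narrowed
# ditch. A non-core point within a core's radius becomes BORDER of that
# core's cluster (nearest qualifying core wins).
cluster_from_params <- function(pts, eps, min_samples_vec, border_points,
                                core_link = "either") {
  n <- nrow(pts)
  label <- rep(NA_integer_, n)
  role <- rep("noise", n)
  if (n == 0) {
    return(tibble::tibble(point = integer(), x = double(), y = double(),
                          eps = double(), label = integer(),
                          role = character()))
  }
  d <- as.matrix(stats::dist(pts))
  rho <- vapply(seq_len(n), function(i) sum(d[i, ] <= eps[i]), integer(1))
  core <- rho >= min_samples_vec
  role[core] <- "core"
  cluster_id <- 0L
  for (i in which(core)) {
    if (!is.na(label[i])) next
    cluster_id <- cluster_id + 1L
    queue <- i
    label[i] <- cluster_id
    while (length(queue) > 0) {
      p <- queue[[1]]
      queue <- queue[-1]
      reach <- if (identical(core_link, "mutual")) {
        which(core & is.na(label) & d[p, ] <= eps[p] & d[p, ] <= eps)
      } else {
        which(core & is.na(label) & (d[p, ] <= eps[p] | d[p, ] <= eps))
      }
      if (length(reach) > 0) {
        label[reach] <- cluster_id
        queue <- c(queue, reach)
      }
    }
  }
  if (border_points && any(core)) {
    core_idx <- which(core)
    for (i in which(!core)) {
      within <- core_idx[d[i, core_idx] <= eps[core_idx]]
      if (length(within) > 0) {
        nearest <- within[which.min(d[i, within])]
        label[i] <- label[nearest]
        role[i] <- "border"
      }
    }
  }
  tibble::tibble(point = seq_len(n), x = pts[, 1], y = pts[, 2], eps = eps,
                 label = label, role = role)
}

#' Adaptive DBSCAN clustering of detection centres
#'
#' Runs the full two-pass adaptive parameter determination
#' ([compute_adaptive_params()]) followed by DBSCAN-style expansion with the
#' per-point radius. Noise points form the candidate elimination set of
#' non-target detections.
#'
#' @param points matrix or data frame of detection centres (`x`, `y`).
#' @param config an [adap_config()].
#' @return A labeling tibble of class `rc_labeling` with columns `point`,
#'   `x`, `y`, `eps`, `label` (integer cluster id, `NA` for noise), `role`
#'   (`"core"`, `"border"` or `"noise"`); attributes `min_samples` and
#'   `params`. Fewer than 2 points: all noise (degenerate frame).
#' @seealso [fixed_dbscan()], [elimination_set()], [select_target()]
#' @export
adap_dbscan <- function(points, config = adap_config()) {
  pts <- as_point_matrix(points)
  n <- nrow(pts)
  ap <- compute_adaptive_params(pts, config)
  if (ap$degenerate) {
    lab <- tibble::tibble(point = seq_len(n), x = pts[, 1], y = pts[, 2],
                          eps = ap$params$eps, label = NA_integer_,
                          role = rep("noise", n))
  } else {
    ms <- if (config$per_point_min_samples) ap$params$min_samples_local
          else rep(ap$min_samples, n)
    lab <- cluster_from_params(pts, ap$params$eps, ms, config$border_points,
                               config$core_link)
  }
  structure(lab, class = c("rc_labeling", class(lab)),
            min_samples = ap$min_samples, params = ap$params)
}

#' Classic fixed-parameter DBSCAN
#'
#' The conventional baseline: one global radius and density threshold.
#'
#' @param points matrix or data frame of point coordinates (`x`, `y`).
#' @param eps neighbourhood radius, pixels (> 0).
#' @param min_samples density threshold (neighbourhood count including the
#'   point itself).
#' @param border_points classic border semantics if `TRUE` (default).
#' @return A labeling tibble as in [adap_dbscan()].
#' @export
fixed_dbscan <- function(points, eps, min_samples, border_points = TRUE) {
  stopifnot(eps > 0, min_samples >= 1)
  pts <- as_point_matrix(points)
  n <- nrow(pts)
  if (n == 0) {
    lab <- cluster_from_params(pts, numeric(0), integer(0), border_points)
  } else {
    lab <- cluster_from_params(pts, rep(eps, n), rep(min_samples, n),
                               border_points)
  }
  structure(lab, class = c("rc_labeling", class(lab)),
            min_samples = as.integer(min_samples), params = NULL)
}

#' Indices of the candidate elimination set
#'
#' @param labeling a labeling tibble from [adap_dbscan()] or
#'   [fixed_dbscan()].
#' @return Integer indices of the noise points.
#' @export
elimination_set <- function(labeling) {
  labeling$point[labeling$role == "noise"]
}

#' Retain the target-row cluster
#'
#' Drops all noise points, then keeps the largest cluster by member count;
#' ties are broken in favour of the cluster whose centroid is nearest the
#' frame's vertical midline.
#'
#' @param labeling a labeling tibble from [adap_dbscan()] or
#'   [fixed_dbscan()].
#' @param frame_size `c(width, height)` in pixels.
#' @return Integer indices of the retained points (empty if no clusters).
#' @export
select_target <- function(labeling, frame_size = c(1920, 1080)) {
  lab <- labeling[!is.na(labeling$label), ]
  if (nrow(lab) == 0) return(integer(0))
  summ <- lab |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(n = dplyr::n(),
                     midline_dist = abs(mean(.data$x) - frame_size[1] / 2),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n), .data$midline_dist)
  keep <- summ$label[1]
  sort(lab$point[lab$label == keep])
}

#' Fixed-DBSCAN baseline parameters from adaptive statistics
#'
#' The conventional-method baseline uses one global radius: the median of
#' the adaptive per-point radii over (a sample of) the video's frames, with
#' the matching aggregated density threshold. This is the fixed setting the
#' adaptive mode is compared against.
#'
#' @param det detection tibble.
#' @param config an [adap_config()].
#' @param confidence_threshold detections below this are ignored.
#' @param frame_stride compute statistics every this-many frames.
#' @return A list with `eps` (pixels) and `min_samples`.
#' @export
fixed_baseline_params <- function(det, config = adap_config(),
                                  confidence_threshold = 0.25,
                                  frame_stride = 25) {
  sub <- det[det$conf >= confidence_threshold, ]
  frames <- sort(unique(sub$frame))
  frames <- frames[seq(1, length(frames), by = frame_stride)]
  eps_all <- c()
  ms_all <- c()
  for (f in frames) {
    fd <- sub[sub$frame == f, ]
    if (nrow(fd) < config$k_neighbors + 1) next
    ctr <- box_centers(fd)
    ap <- compute_adaptive_params(cbind(x = ctr$cx, y = ctr$cy), config)
    eps_all <- c(eps_all, ap$params$eps)
    ms_all <- c(ms_all, ap$min_samples)
  }
  if (length(eps_all) == 0) {
    return(list(eps = config$eps_max / 2, min_samples = config$min_samples_floor))
  }
  list(eps = stats::median(eps_all),
       min_samples = max(config$min_samples_floor,
                         as.integer(round(stats::median(ms_all)))))
}
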