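#' Counting-pipeline configuration
#'
#' Root configuration for the detection → clustering → tracking → count
#' pipeline.
#'
#' @param clustering_mode `"adaptive"` (density-adaptive DBSCAN),
#'   `"fixed"` (classic DBSCAN with `fixed_eps` / `fixed_min_samples`,
#'   the conventional baseline) or `"off"`.
#' @param confidence_threshold detections below this confidence are dropped
#'   before clustering (default 0.25).
#' @param adapdbscan an [adap_config()].
#' @param fixed_eps,fixed_min_samples parameters for `clustering_mode =
#'   "fixed"`.
#' @param tracker a [tracker_config()].
#' @param clustering_apply where the elimination acts: `"counting"`
#'   (default) keeps every detection in the tracker and lets the per-frame
#'   cluster verdicts vote on whether each finalised track is counted —
#'   per-frame labeling flicker then averages out over a track's life;
#'   `"association"` removes eliminated detections before the tracker sees
#'   them, so clutter never forms tracks but a few frames of mislabeling
#'   can fragment a genuine identity.
#' @param view_label free-text camera-view tag carried into outputs
#'   (`"45deg"`, `"90deg"`, ...).
#' @param random_seed seed recorded in outputs (the counting path itself is
#'   deterministic).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(clustering_mode = c("adaptive", "fixed", "off"),
                            confidence_threshold = 0.25,
                            adapdbscan = adap_config(),
                            fixed_eps = 100, fixed_min_samples = 4,
                            tracker = tracker_config(),
                            clustering_apply = c("counting", "association"),
                            view_label = "45deg", random_seed = 1L) {
  clustering_mode <- match.arg(clustering_mode)
  clustering_apply <- match.arg(clustering_apply)
  stopifnot(confidence_threshold >= 0, confidence_threshold <= 1,
            fixed_eps > 0, fixed_min_samples >= 1)
  structure(list(clustering_mode = clustering_mode,
                 confidence_threshold = confidence_threshold,
                 adapdbscan = adapdbscan, fixed_eps = fixed_eps,
                 fixed_min_samples = fixed_min_samples, tracker = tracker,
                 clustering_apply = clustering_apply,
                 view_label = view_label,
                 random_seed = as.integer(random_seed)),
            class = "pipeline_config")
}

#' Run the row-counting pipeline on a detection stream
#'
#' Per frame: detections below the confidence threshold are dropped; the
#' configured clustering mode labels the box centres and flags members of
#' the retained target cluster (frames with fewer than 2 detections skip
#' clustering — the statistics are undefined there — and pass straight
#' through). Under the default `clustering_apply = "counting"` all
#' detections feed the SORT tracker and a finalised track is counted when
#' it was confirmed and the majority of its matched detections were
#' retained; under `"association"` eliminated detections never reach the
#' tracker and every confirmed track counts.
#'
#' @param det detection tibble (see [detections()]).
#' @param config a [pipeline_config()].
#' @param frame_size `c(width, height)` in pixels.
#' @param n_frames number of frames in the video; defaults to the largest
#'   frame index present. Frames with no detections are processed as empty.
#' @return An object of class `counting_result`: a list with `count` (the
#'   predicted row count), `per_frame` (tibble: `frame`, `n_detections`,
#'   `n_retained`, `n_eliminated`, `n_active_tracks`, `cumulative_count`),
#'   `track_log`, `config` and `frame_size`. Supports [tidy()] (per-frame
#'   log), [glance()] (one-row summary) and `autoplot()`.
#' @export
run_pipeline <- function(det, config = pipeline_config(),
                         frame_size = c(1920, 1080), n_frames = NULL) {
  det <- detections(det)
  if (nrow(det) == 0) {
    warning("empty video: count is 0", call. = FALSE)
  }
  if (is.null(n_frames)) {
    n_frames <- if (nrow(det) > 0) max(det$frame) else 0L
  }
  det <- det[det$conf >= config$confidence_threshold, ]
  trk <- sort_tracker(config$tracker, frame_size)
  by_frame <- split(det, factor(det$frame, levels = seq_len(n_frames)))
  per_frame <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    fd <- by_frame[[f]]
    n_in <- nrow(fd)
    n_kept <- n_in
    if (config$clustering_mode != "off" && n_in >= 2) {
      centers <- box_centers(fd)
      pts <- cbind(x = centers$cx, y = centers$cy)
      lab <- switch(config$clustering_mode,
        adaptive = adap_dbscan(pts, config$adapdbscan),
        fixed = fixed_dbscan(pts, config$fixed_eps, config$fixed_min_samples)
      )
      keep <- select_target(lab, frame_size)
      n_kept <- length(keep)
      if (config$clustering_apply == "association") {
        fd <- fd[keep, ]
      } else {
        fd$retained <- seq_len(n_in) %in% keep
      }
    }
    tracks <- tracker_step(trk, fd, f)
    per_frame[[f]] <- tibble::tibble(
      frame = f, n_detections = n_in, n_retained = n_kept,
      n_eliminated = n_in - n_kept, n_active_tracks = nrow(tracks),
      cumulative_count = tracker_count(trk))
  }
  tracker_finalize(trk)
  if (n_frames > 0) {
    per_frame[[n_frames]]$cumulative_count <- tracker_count(trk)
  }
  structure(list(count = tracker_count(trk),
                 per_frame = dplyr::bind_rows(per_frame),
                 track_log = tracker_log(trk),
                 config = config, frame_size = frame_size,
                 seed = config$random_seed),
            class = "counting_result")
}

#' @export
print.counting_result <- function(x, ...) {
  cat("Row counting result\n")
  cat("  predicted count:", x$count, "\n")
  cat("  frames:", nrow(x$per_frame), "  clustering:",
      x$config$clustering_mode, "  view:", x$config$view_label, "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a counting result
#'
#' @param x a `counting_result`.
#' @param ... unused.
#' @return The per-frame log tibble.
#' @export
tidy.counting_result <- function(x, ...) x$per_frame

#' One-row summary of a counting result
#'
#' @param x a `counting_result`.
#' @param ... unused.
#' @return A one-row tibble: `count`, `n_frames`, `n_detections`,
#'   `n_eliminated`, `clustering_mode`, `view_label`, `seed`.
#' @export
glance.counting_result <- function(x, ...) {
  tibble::tibble(count = x$count, n_frames = nrow(x$per_frame),
                 n_detections = sum(x$per_frame$n_detections),
                 n_eliminated = sum(x$per_frame$n_eliminated),
                 clustering_mode = x$config$clustering_mode,
                 view_label = x$config$view_label, seed = x$seed)
}

#' Compare pipeline configurations on one video
#'
#' Runs each configuration and tabulates the predicted count with counting
#' accuracy against the known row count.
#'
#' @param det detection tibble.
#' @param configs a named list of [pipeline_config()] objects.
#' @param truth true row count (y > 0).
#' @param frame_size `c(width, height)` in pixels.
#' @param n_frames see [run_pipeline()].
#' @return A tibble with one row per configuration: `method`,
#'   `clustering_mode`, `count`, `truth`, `acc` (percent).
#' @export
compare_methods <- function(det, configs, truth,
                            frame_size = c(1920, 1080), n_frames = NULL) {
  stopifnot(length(configs) >= 1)
  if (is.null(names(configs)) || any(!nzchar(names(configs)))) {
    names(configs) <- paste0("config_", seq_along(configs))
  }
  purrr::imap_dfr(configs, function(cfg, nm) {
    res <- run_pipeline(det, cfg, frame_size, n_frames)
    tibble::tibble(method = nm, clustering_mode = cfg$clustering_mode,
                   count = res$count, truth = truth,
                   acc = count_accuracy(truth, res$count))
  })
}

config_to_list <- function(config) {
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  strip(config)
}

#' Read / write a pipeline configuration as YAML
#'
#' The YAML schema mirrors [pipeline_config()]: top-level keys plus nested
#' `adapdbscan:` and `tracker:` blocks; absent keys take the package
#' defaults.
#'
#' @param path YAML file path.
#' @return `read_pipeline_config()`: a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  ad <- do.call(adap_config, raw$adapdbscan %||% list())
  tr <- do.call(tracker_config, raw$tracker %||% list())
  top <- raw[setdiff(names(raw), c("adapdbscan", "tracker"))]
  do.call(pipeline_config, c(top, list(adapdbscan = ad, tracker = tr)))
}

#' @param config a [pipeline_config()].
#' @rdname read_pipeline_config
#' @return `write_pipeline_config()`: `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(config_to_list(config), path)
  invisible(path)
}
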