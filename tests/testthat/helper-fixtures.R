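# Small deterministic fixtures built in code.

det_row <- function(frame, x, y, w, h, conf = 0.9, id = -1L) {
  tibble::tibble(frame = as.integer(frame), id = as.integer(id),
                 x = x, y = y, w = w, h = h, conf = conf)
}

# detections of n non-overlapping boxes drifting down a synthetic frame
drifting_video <- function(n_objects = 3, n_frames = 20, dy = 15,
                           frame_size = c(1920, 1080)) {
  purrr::map_dfr(seq_len(n_frames), function(f) {
    tibble::tibble(frame = f, id = seq_len(n_objects),
                   x = 200 * seq_len(n_objects),
                   y = 50 + dy * (f - 1) + 10 * seq_len(n_objects),
                   w = 40, h = 40, conf = 0.9)
  })
}

# random detection table across frames (for IO round trips)
random_detections <- function(n = 50, n_frames = 10, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    frame = sample.int(n_frames, n, replace = TRUE),
    id = -1L,
    x = runif(n, 0, 1800), y = runif(n, 0, 1000),
    w = runif(n, 2, 120), h = runif(n, 2, 80),
    conf = round(runif(n), 4)))
}

# a compact cluster plus distant stragglers
cluster_with_noise <- function() {
  grid <- expand.grid(x = seq(0, 40, 10), y = seq(0, 40, 10))
  pts <- rbind(as.matrix(grid), c(500, 500), c(900, 100))
  colnames(pts) <- c("x", "y")
  pts
}

quick_scene <- function(...) {
  args <- list(...)
  defaults <- list(plot_length = 2.4, n_side_rows = 0)
  do.call(scene_config, utils::modifyList(defaults, args))
}
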