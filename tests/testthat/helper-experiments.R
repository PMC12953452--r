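# Paired simulation experiments shared by several acceptance checks.
# Computed lazily once per test run and cached (they are the expensive part
# of the suite). Scenes are 7.2 m (half the default plot) to keep the run
# within a practical budget; geometry and noise are otherwise the defaults.

.experiment_cache <- new.env(parent = emptyenv())

paired_experiment <- function(n_seeds = 10) {
  key <- paste0("paired_", n_seeds)
  if (!is.null(.experiment_cache[[key]])) return(.experiment_cache[[key]])
  scene45 <- scene_config(plot_length = 7.2)
  scene90 <- scene_config(plot_length = 7.2, tilt_deg = 90)
  rows <- lapply(seq_len(n_seeds), function(s) {
    sim45 <- simulate_video(scene45, noise_config(), seed = s)
    fb <- fixed_baseline_params(sim45$detections)
    adaptive <- run_pipeline(sim45$detections, pipeline_config("adaptive"),
                             scene45$frame_size)
    fixed <- run_pipeline(
      sim45$detections,
      pipeline_config("fixed", fixed_eps = fb$eps,
                      fixed_min_samples = fb$min_samples),
      scene45$frame_size)
    sim90 <- simulate_video(scene90, noise_config(), seed = s)
    adaptive90 <- run_pipeline(sim90$detections,
                               pipeline_config("adaptive",
                                               view_label = "90deg"),
                               scene90$frame_size)
    tibble::tibble(seed = s, y45 = sim45$y, y90 = sim90$y,
                   count_adaptive = adaptive$count,
                   count_fixed = fixed$count,
                   count_90 = adaptive90$count,
                   fixed_eps = fb$eps, fixed_ms = fb$min_samples)
  })
  out <- dplyr::bind_rows(rows)
  .experiment_cache[[key]] <- out
  out
}
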