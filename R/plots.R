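#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a cluster labeling
#'
#' Detection centres coloured by cluster, with noise (the candidate
#' elimination set) drawn as grey crosses. The y axis is reversed to match
#' image coordinates (origin top-left).
#'
#' @param object a labeling from [adap_dbscan()] or [fixed_dbscan()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.rc_labeling <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$cluster <- ifelse(is.na(df$label), "noise", paste0("cluster ", df$label))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$cluster,
                                     shape = .data$role == "noise"),
                        show.legend = c(colour = TRUE, shape = FALSE)) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 4)) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "x (px)", y = "y (px)", colour = NULL,
                  title = "Cluster labeling of detection centres") +
    ggplot2::theme_minimal()
}

#' Plot a counting result
#'
#' Cumulative count and per-frame retained/eliminated detections over the
#' video.
#'
#' @param object a `counting_result` from [run_pipeline()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.counting_result <- function(object, ...) {
  pf <- object$per_frame |>
    tidyr::pivot_longer(c("cumulative_count", "n_retained", "n_eliminated"),
                        names_to = "series", values_to = "value")
  ggplot2::ggplot(pf, ggplot2::aes(x = .data$frame, y = .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frame", y = NULL, colour = NULL,
                  title = sprintf("Row count: %d (%s clustering)",
                                  object$count,
                                  object$config$clustering_mode)) +
    ggplot2::theme_minimal()
}

#' Plot a counting evaluation
#'
#' Predicted versus true per-video counts with the identity line.
#'
#' @param object a `counting_eval` from [counting_eval()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.counting_eval <- function(object, ...) {
  ggplot2::ggplot(object$per_video,
                  ggplot2::aes(x = .data$y, y = .data$yhat)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::labs(x = "true count y", y = "predicted count",
                  title = sprintf("Counting: mean Acc %.2f%%%s",
                                  object$mean_acc,
                                  if (is.na(object$r_squared)) "" else
                                    sprintf(", R² = %.3f",
                                            object$r_squared))) +
    ggplot2::theme_minimal()
}

#' Plot one frame of a simulated video
#'
#' Ground-truth boxes (by source row) and detector-like boxes for a chosen
#' frame, in image coordinates.
#'
#' @param sim a `simulated_video` from [simulate_video()].
#' @param frame frame index to draw.
#' @return A ggplot.
#' @export
plot_scene_frame <- function(sim, frame) {
  tr <- sim$truth[sim$truth$frame == frame, ]
  de <- sim$detections[sim$detections$frame == frame, ]
  ggplot2::ggplot() +
    ggplot2::geom_rect(data = tr,
                       ggplot2::aes(xmin = .data$x, xmax = .data$x + .data$w,
                                    ymin = .data$y, ymax = .data$y + .data$h,
                                    colour = .data$row),
                       fill = NA) +
    ggplot2::geom_rect(data = de,
                       ggplot2::aes(xmin = .data$x, xmax = .data$x + .data$w,
                                    ymin = .data$y, ymax = .data$y + .data$h),
                       colour = "black", linetype = 3, fill = NA) +
    ggplot2::scale_y_reverse(limits = c(sim$scene$frame_size[2], 0)) +
    ggplot2::xlim(0, sim$scene$frame_size[1]) +
    ggplot2::labs(x = "x (px)", y = "y (px)", colour = "truth row",
                  title = sprintf("Frame %d (tilt %g°)", frame,
                                  sim$scene$tilt_deg)) +
    ggplot2::theme_minimal()
}
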