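#' Match predicted and ground-truth boxes for detection evaluation
#'
#' Greedy one-to-one matching in descending prediction confidence: each
#' prediction claims the unused truth box of the same frame with the highest
#' IoU, provided it reaches the threshold. Matched predictions are true
#' positives, unmatched predictions false positives, unmatched truth boxes
#' false negatives.
#'
#' @param pred,truth detection tibbles sharing frame indices (`truth` ids are
#'   ignored here).
#' @param iou_thr IoU threshold (default 0.5).
#' @return A list with counts `TP`, `FP`, `FN` and `matched` (tibble of
#'   matched pairs: `frame`, `pred_row`, `truth_row`, `iou`, `conf`).
#' @export
match_detections <- function(pred, truth, iou_thr = 0.5) {
  frames <- sort(unique(c(pred$frame, truth$frame)))
  tp <- 0L; fp <- 0L; fn <- 0L
  matched <- list()
  for (f in frames) {
    p <- pred[pred$frame == f, ]
    g <- truth[truth$frame == f, ]
    if (nrow(p) == 0) { fn <- fn + nrow(g); next }
    if (nrow(g) == 0) { fp <- fp + nrow(p); next }
    ord <- order(-p$conf)
    iou <- box_iou(p, g)
    used <- rep(FALSE, nrow(g))
    hit <- rep(FALSE, nrow(p))
    for (i in ord) {
      cand <- which(!used & iou[i, ] >= iou_thr)
      if (length(cand) > 0) {
        j <- cand[which.max(iou[i, cand])]
        used[j] <- TRUE
        hit[i] <- TRUE
        matched[[length(matched) + 1L]] <-
          tibble::tibble(frame = f, pred_row = i, truth_row = j,
                         iou = iou[i, j], conf = p$conf[i])
      }
    }
    tp <- tp + sum(hit); fp <- fp + sum(!hit); fn <- fn + sum(!used)
  }
  list(TP = tp, FP = fp, FN = fn, matched = dplyr::bind_rows(matched))
}

#' Precision and recall from match counts
#'
#' `P = TP / (TP + FP)`, `R = TP / (TP + FN)`. With no predictions at all
#' (`TP + FP = 0`) precision is 1 by convention (no false alarms were
#' raised); a zero recall denominator means there is no ground truth and is
#' an error.
#'
#' @param TP,FP,FN non-negative counts.
#' @return A list with `P` and `R`.
#' @export
precision_recall <- function(TP, FP, FN) {
  stopifnot(TP >= 0, FP >= 0, FN >= 0)
  if (TP + FN == 0) stop("no ground-truth instances: recall undefined",
                         call. = FALSE)
  P <- if (TP + FP == 0) 1 else TP / (TP + FP)
  list(P = P, R = TP / (TP + FN))
}

#' Confidence-swept precision-recall curve
#'
#' Sorts predictions by descending confidence, matches them greedily against
#' ground truth ([match_detections()] semantics applied cumulatively), and
#' returns the running precision and recall after each prediction.
#'
#' @inheritParams match_detections
#' @return A tibble with columns `conf`, `P`, `R` (recall non-decreasing).
#' @export
detection_pr_curve <- function(pred, truth, iou_thr = 0.5) {
  n_truth <- nrow(truth)
  if (n_truth == 0) stop("no ground-truth instances", call. = FALSE)
  if (nrow(pred) == 0) {
    return(tibble::tibble(conf = double(), P = double(), R = double()))
  }
  m <- match_detections(pred, truth, iou_thr)
  # true-positive flags per prediction, in descending confidence
  flags <- tibble::tibble(conf = pred$conf,
                          tp = FALSE)
  if (nrow(m$matched) > 0) {
    # recover per-prediction hit flags by re-walking frames
    hit_key <- paste(m$matched$frame, m$matched$pred_row)
  } else {
    hit_key <- character(0)
  }
  by_frame_rows <- split(seq_len(nrow(pred)), pred$frame)
  for (f in names(by_frame_rows)) {
    rows <- by_frame_rows[[f]]
    local_hit <- paste(f, seq_along(rows)) %in% hit_key
    flags$tp[rows] <- local_hit
  }
  ord <- order(-flags$conf)
  tp_cum <- cumsum(flags$tp[ord])
  fp_cum <- cumsum(!flags$tp[ord])
  tibble::tibble(conf = flags$conf[ord],
                 P = tp_cum / (tp_cum + fp_cum),
                 R = tp_cum / n_truth)
}

#' Average precision by all-point summation
#'
#' `AP = sum(P_i * delta R_i)` over an ordered precision-recall curve, the
#' raw summation form with no interpolation or smoothing.
#'
#' @param pr tibble or data frame with columns `P` and `R`, recall
#'   non-decreasing.
#' @return AP in \[0, 1\]; 0 for an empty curve.
#' @examples
#' average_precision(data.frame(P = c(1, 0.5), R = c(0.5, 1)))  # 0.75
#' @export
average_precision <- function(pr) {
  if (nrow(pr) == 0) return(0)
  if (is.unsorted(pr$R)) stop("recall must be non-decreasing", call. = FALSE)
  dR <- diff(c(0, pr$R))
  sum(pr$P * dR)
}

#' Detection evaluation at one IoU threshold
#'
#' @inheritParams match_detections
#' @return An object of class `detection_eval`: counts `TP`, `FP`, `FN`,
#'   precision `P`, recall `R`, `AP` (confidence-swept all-point average
#'   precision) and `iou_thr`. Supports [tidy()] and [glance()].
#' @export
detection_eval <- function(pred, truth, iou_thr = 0.5) {
  m <- match_detections(pred, truth, iou_thr)
  pr <- precision_recall(m$TP, m$FP, m$FN)
  curve <- detection_pr_curve(pred, truth, iou_thr)
  structure(list(TP = m$TP, FP = m$FP, FN = m$FN, P = pr$P, R = pr$R,
                 AP = average_precision(curve), curve = curve,
                 iou_thr = iou_thr),
            class = "detection_eval")
}

#' @export
print.detection_eval <- function(x, ...) {
  cat(sprintf("Detection eval @ IoU %.2f: TP %d FP %d FN %d  P %.3f R %.3f AP %.3f\n",
              x$iou_thr, x$TP, x$FP, x$FN, x$P, x$R, x$AP))
  invisible(x)
}

#' @export
tidy.detection_eval <- function(x, ...) x$curve

#' @export
glance.detection_eval <- function(x, ...) {
  tibble::tibble(TP = x$TP, FP = x$FP, FN = x$FN, P = x$P, R = x$R,
                 AP = x$AP, iou_thr = x$iou_thr)
}

#' Tracking evaluation against ground-truth identities
#'
#' Matches tracker output to ground-truth tracks frame by frame on centre
#' distance (threshold: half the median truth box width, unless overridden),
#' then computes the tracking metric suite:
#' * `Q_sh` — the number of truth identities that suffer at least one ID
#'   switch (their matched track id changes between two of their matched
#'   frames);
#' * `S` — seedlings counted by the tracker (supplied count);
#' * `T_mat` — truth identities matched at least once;
#' * `M_mat` — correctly tracked identities: those whose dominant track id
#'   covers at least `coverage` of their matched frames;
#' * `W_ID = Q_sh / S`, `P_tr = M_mat / S`, `P_mt = M_mat / T_mat`.
#'
#' @param track_log tibble from [tracker_log()] (or any table with `frame`,
#'   `id`, `x`, `y`, `w`, `h`).
#' @param truth ground-truth detection tibble with identities (`id`).
#' @param count the tracker's final count `S`; defaults to the largest
#'   running `count` in the log, or the number of distinct track ids.
#' @param dist_threshold centre-distance gate in pixels (default: half the
#'   median truth box width).
#' @param coverage dominant-id coverage fraction defining "correctly
#'   tracked" (default 0.5).
#' @param min_box_px evaluate truth boxes only where their height reaches
#'   this size (default 0: no filter). Useful because identities smaller
#'   than the detector's resolving limit cannot meaningfully be tracked,
#'   and their near-coincident far-field boxes make centre-distance
#'   matching flap between neighbours.
#' @return An object of class `tracking_eval` with the fields above.
#' @export
tracking_eval <- function(track_log, truth, count = NULL,
                          dist_threshold = NULL, coverage = 0.5,
                          min_box_px = 0) {
  if (min_box_px > 0) truth <- truth[truth$h >= min_box_px, ]
  if (nrow(truth) == 0) stop("ground-truth tracks required", call. = FALSE)
  if (is.null(dist_threshold)) dist_threshold <- stats::median(truth$w) / 2
  if (is.null(count)) {
    count <- if ("count" %in% names(track_log) && nrow(track_log) > 0) {
      max(track_log$count)
    } else {
      length(unique(track_log$id))
    }
  }
  if (nrow(track_log) == 0) {
    warning("empty track log: all tracking metrics zero", call. = FALSE)
    return(structure(list(Q_sh = 0L, S = count, M_mat = 0L, T_mat = 0L,
                          W_ID = 0, P_tr = 0, P_mt = 0),
                     class = "tracking_eval"))
  }
  tl <- box_centers(track_log)
  gt <- box_centers(truth)
  assoc <- list()
  for (f in sort(unique(gt$frame))) {
    g <- gt[gt$frame == f, ]
    t <- tl[tl$frame == f, ]
    if (nrow(t) == 0) next
    dmat <- sqrt(outer(g$cx, t$cx, `-`)^2 + outer(g$cy, t$cy, `-`)^2)
    ok <- dmat <= dist_threshold
    if (!any(ok)) next
    dmat[!ok] <- dist_threshold * 1e6
    asg <- hungarian_assign(dmat)
    for (k in seq_len(nrow(g))) {
      j <- asg[k]
      if (!is.na(j) && j > 0 && ok[k, j]) {
        assoc[[length(assoc) + 1L]] <-
          tibble::tibble(frame = f, truth_id = g$id[k], track_id = t$id[j])
      }
    }
  }
  assoc <- dplyr::bind_rows(assoc)
  if (nrow(assoc) == 0) {
    return(structure(list(Q_sh = 0L, S = count, M_mat = 0L, T_mat = 0L,
                          W_ID = 0, P_tr = 0, P_mt = 0),
                     class = "tracking_eval"))
  }
  per_truth <- assoc |>
    dplyr::arrange(.data$truth_id, .data$frame) |>
    dplyr::group_by(.data$truth_id) |>
    dplyr::summarise(
      switched = any(.data$track_id != dplyr::lag(.data$track_id),
                     na.rm = TRUE),
      dominant_share = max(table(.data$track_id)) / dplyr::n(),
      .groups = "drop")
  Q_sh <- sum(per_truth$switched)
  T_mat <- nrow(per_truth)
  M_mat <- sum(per_truth$dominant_share >= coverage)
  S <- count
  structure(list(Q_sh = as.integer(Q_sh), S = S, M_mat = as.integer(M_mat),
                 T_mat = as.integer(T_mat),
                 W_ID = if (S > 0) Q_sh / S else 0,
                 P_tr = if (S > 0) M_mat / S else 0,
                 P_mt = if (T_mat > 0) M_mat / T_mat else 0),
            class = "tracking_eval")
}

#' @export
print.tracking_eval <- function(x, ...) {
  cat(sprintf(
    "Tracking eval: Q_sh %d S %d M_mat %d T_mat %d  W_ID %.3f P_tr %.3f P_mt %.3f\n",
    x$Q_sh, x$S, x$M_mat, x$T_mat, x$W_ID, x$P_tr, x$P_mt))
  invisible(x)
}

#' @export
glance.tracking_eval <- function(x, ...) {
  tibble::tibble(Q_sh = x$Q_sh, S = x$S, M_mat = x$M_mat, T_mat = x$T_mat,
                 W_ID = x$W_ID, P_tr = x$P_tr, P_mt = x$P_mt)
}

#' Counting accuracy
#'
#' `Acc = (1 - |yhat - y| / y) * 100` percent. Equals 100 only for an exact
#' count and can be negative for a gross over-count (an over-count of more
#' than twice the truth).
#'
#' @param y true row count (> 0).
#' @param yhat predicted count (vectorised).
#' @return Accuracy in percent.
#' @examples
#' count_accuracy(680, 679)  # 99.85...
#' @export
count_accuracy <- function(y, yhat) {
  if (any(y <= 0)) stop("true count must be positive", call. = FALSE)
  (1 - abs(yhat - y) / y) * 100
}

#' Coefficient of determination for per-video counts
#'
#' `R^2 = 1 - sum((y_i - yhat_i)^2) / sum((y_i - ybar)^2)` over paired
#' per-video true and predicted counts.
#'
#' @param y true counts (length >= 2, not all equal).
#' @param yhat predicted counts, same length.
#' @return R-squared (at most 1; 0 when predicting the mean).
#' @export
r_squared <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 2)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("true counts are constant: R^2 undefined",
                        call. = FALSE)
  1 - sum((y - yhat)^2) / ss_tot
}

#' Counting evaluation over a set of videos
#'
#' @param y,yhat paired per-video true and predicted counts.
#' @return An object of class `counting_eval`: per-video tibble (`y`,
#'   `yhat`, `acc`), mean accuracy and (for >= 2 videos with varying y)
#'   R-squared. Supports [tidy()], [glance()] and `autoplot()`.
#' @export
counting_eval <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 1)
  per_video <- tibble::tibble(video = seq_along(y), y = y, yhat = yhat,
                              acc = count_accuracy(y, yhat))
  r2 <- if (length(y) >= 2 && stats::var(y) > 0) r_squared(y, yhat)
        else NA_real_
  structure(list(per_video = per_video, mean_acc = mean(per_video$acc),
                 r_squared = r2),
            class = "counting_eval")
}

#' @export
print.counting_eval <- function(x, ...) {
  cat(sprintf("Counting eval over %d video(s): mean Acc %.2f%%",
              nrow(x$per_video), x$mean_acc))
  if (!is.na(x$r_squared)) cat(sprintf(", R^2 %.3f", x$r_squared))
  cat("\n")
  invisible(x)
}

#' @export
tidy.counting_eval <- function(x, ...) x$per_video

#' @export
glance.counting_eval <- function(x, ...) {
  tibble::tibble(n_videos = nrow(x$per_video), mean_acc = x$mean_acc,
                 r_squared = x$r_squared)
}

#' Printed-metric summary of a tracking method
#'
#' Container for the percentage-scale tracking/counting summary metrics of a
#' method (ID switch rate, tracking accuracy, tracking precision, counting
#' accuracy), as tabulated in method-comparison tables. Subtraction of two
#' summaries gives the pairwise metric differences.
#'
#' @param w_id,p_tr,p_mt,acc metric values in percent.
#' @param method method label.
#' @return An object of class `tracking_summary`.
#' @examples
#' a <- tracking_summary(8.47, 87.53, 89.75, 97.13, "sort")
#' b <- tracking_summary(28.35, 78.62, 73.90, 80.25, "bytetrack")
#' metric_diff(a, b)
#' @export
tracking_summary <- function(w_id, p_tr, p_mt, acc, method = "method") {
  structure(list(W_ID = w_id, P_tr = p_tr, P_mt = p_mt, Acc = acc,
                 method = method),
            class = "tracking_summary")
}

#' @param a,b `tracking_summary` objects.
#' @rdname tracking_summary
#' @return `metric_diff()`: a tibble of `a - b` differences per metric.
#' @export
metric_diff <- function(a, b) {
  stopifnot(inherits(a, "tracking_summary"), inherits(b, "tracking_summary"))
  tibble::tibble(metric = c("W_ID", "P_tr", "P_mt", "Acc"),
                 difference = c(a$W_ID - b$W_ID, a$P_tr - b$P_tr,
                                a$P_mt - b$P_mt, a$Acc - b$Acc))
}
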