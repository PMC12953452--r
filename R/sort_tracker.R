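#' Tracker configuration
#'
#' Parameters of the SORT-style tracker: constant-velocity Kalman filtering
#' on the state `(u, v, s, r, du, dv, ds)` (box centre, area, aspect ratio
#' and their velocities; aspect ratio modelled constant), Hungarian
#' assignment on an IoU cost, and a hit/miss lifecycle.
#'
#' @param iou_threshold minimum IoU for a detection-track match, in (0, 1).
#' @param max_age frames a track may go unmatched before deletion (default 3:
#'   at 30 fps short motion-blur dropouts are expected).
#' @param min_hits matched frames required before a track is confirmed (and
#'   counted).
#' @param count_mode `"confirmed"` (default: the count is the number of ids
#'   ever confirmed) or `"retired"` (ids retired at the lower frame edge).
#' @param process_noise,measurement_noise scale factors applied to the
#'   base Kalman noise covariances. The process-noise default of 10 reflects
#'   the strong apparent acceleration a ground-level walking camera induces
#'   near the lower frame edge, which a constant-velocity model must absorb
#'   as process noise; smaller values make the filter lag and fragment
#'   tracks there.
#' @param rescue_iou relaxed IoU gate for a second association pass that
#'   re-binds still-unmatched detections to coasting (unmatched) tracks
#'   before any new identity is spawned; set 0 to disable. Near the lower
#'   frame edge apparent speed diverges quickly, so a single missed
#'   association at the strict gate would otherwise fragment the identity
#'   and inflate the count.
#' @return A list of class `tracker_config`.
#' @export
tracker_config <- function(iou_threshold = 0.3, max_age = 3, min_hits = 3,
                           count_mode = c("confirmed", "retired"),
                           process_noise = 10, measurement_noise = 1,
                           rescue_iou = iou_threshold / 2) {
  count_mode <- match.arg(count_mode)
  stopifnot(iou_threshold > 0, iou_threshold < 1, max_age >= 1, min_hits >= 1,
            process_noise > 0, measurement_noise > 0, rescue_iou >= 0,
            rescue_iou <= iou_threshold)
  structure(list(iou_threshold = iou_threshold, max_age = max_age,
                 min_hits = min_hits, count_mode = count_mode,
                 process_noise = process_noise,
                 measurement_noise = measurement_noise,
                 rescue_iou = rescue_iou),
            class = "tracker_config")
}

# Kalman system matrices for the 7-dimensional constant-velocity state.
kalman_matrices <- function(process_noise = 1, measurement_noise = 1) {
  F <- diag(7)
  F[1, 5] <- F[2, 6] <- F[3, 7] <- 1
  H <- cbind(diag(4), matrix(0, 4, 3))
  R <- diag(c(1, 1, 10, 10)) * measurement_noise
  P0 <- diag(c(10, 10, 10, 10, 1e4, 1e4, 1e4))
  Q <- diag(c(1, 1, 1, 1, 0.01, 0.01, 1e-4)) * process_noise
  list(F = F, H = H, R = R, P0 = P0, Q = Q)
}

box_to_z <- function(x, y, w, h) c(x + w / 2, y + h / 2, w * h, w / h)

state_to_box <- function(x) {
  s <- max(x[3], 1e-6); r <- max(x[4], 1e-6)
  w <- sqrt(s * r); h <- s / w
  c(x = x[1] - w / 2, y = x[2] - h / 2, w = w, h = h)
}

#' Hungarian assignment (minimum-cost perfect matching on rows)
#'
#' Shortest-augmenting-path solver for the rectangular assignment problem.
#' With `nrow(cost) <= ncol(cost)`, returns for each row the column it is
#' assigned to in a minimum-total-cost complete matching of the rows.
#'
#' @param cost numeric cost matrix (finite entries).
#' @return Integer vector of length `nrow(cost)`: assigned column per row.
#' @export
hungarian_assign <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0) return(integer(0))
  transposed <- n > m
  if (transposed) { cost <- t(cost); n <- nrow(cost); m <- ncol(cost) }
  u <- numeric(n); v <- numeric(m + 1)
  p <- integer(m + 1)          # p[j]: row matched to column j (0 = free)
  for (i in seq_len(n)) {
    p[m + 1] <- i
    j0 <- m + 1
    minv <- rep(Inf, m)
    way <- integer(m)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      cur <- cost[i0, ] - u[i0] - v[seq_len(m)]
      upd <- !used[seq_len(m)] & cur < minv
      minv[upd] <- cur[upd]
      way[upd] <- j0
      free_j <- which(!used[seq_len(m)])
      if (length(free_j) == 0) stop("assignment failed", call. = FALSE)
      j1 <- free_j[which.min(minv[free_j])]
      delta <- minv[j1]
      used_j <- which(used)
      rows <- p[used_j]
      u[rows[rows > 0]] <- u[rows[rows > 0]] + delta
      v[used_j] <- v[used_j] - delta
      minv[!used[seq_len(m)]] <- minv[!used[seq_len(m)]] - delta
      j0 <- j1
      if (p[j0] == 0) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == m + 1) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(m)) if (p[j] > 0) assignment[p[j]] <- j
  if (transposed) {
    # rows of the transposed problem are the original columns; report, per
    # original row, its matched original column (NA when unmatched)
    out <- rep(NA_integer_, m)
    out[assignment] <- seq_len(n)
    return(out)
  }
  assignment
}

#' Associate predicted track boxes with detections
#'
#' Optimal one-to-one assignment maximising total IoU (Hungarian on the
#' negated IoU, decomposed over connected components of the positive-overlap
#' graph); pairs below the IoU threshold are rejected into the unmatched
#' sets.
#'
#' @param track_boxes,det_boxes data frames with `x`, `y`, `w`, `h` columns.
#' @param threshold minimum IoU for a valid match.
#' @return A list with `matches` (two-column matrix: track row, detection
#'   row), `unmatched_tracks` and `unmatched_detections` (integer indices).
#' @export
associate_detections <- function(track_boxes, det_boxes, threshold = 0.3) {
  nt <- nrow(track_boxes); nd <- nrow(det_boxes)
  no_match <- list(matches = matrix(integer(0), 0, 2),
                   unmatched_tracks = seq_len(nt),
                   unmatched_detections = seq_len(nd))
  if (nt == 0 || nd == 0) return(no_match)
  iou <- box_iou(track_boxes, det_boxes)
  # connected components of the bipartite positive-IoU graph; solve each
  # small assignment problem independently (equivalent to the full problem
  # because zero-IoU pairs can never beat the threshold).
  adj <- iou >= threshold
  comp_t <- rep(0L, nt); comp_d <- rep(0L, nd)
  n_comp <- 0L
  for (t0 in seq_len(nt)) {
    if (comp_t[t0] > 0L || !any(adj[t0, ])) next
    n_comp <- n_comp + 1L
    qt <- t0
    while (length(qt) > 0) {
      t <- qt[[1]]; qt <- qt[-1]
      if (comp_t[t] > 0L) next
      comp_t[t] <- n_comp
      ds <- which(adj[t, ] & comp_d == 0L)
      comp_d[ds] <- n_comp
      for (dd in ds) qt <- c(qt, which(adj[, dd] & comp_t == 0L))
    }
  }
  matches <- matrix(integer(0), 0, 2)
  for (cc in seq_len(n_comp)) {
    ti <- which(comp_t == cc); di <- which(comp_d == cc)
    sub <- iou[ti, di, drop = FALSE]
    if (length(ti) == 1 && length(di) == 1) {
      asg <- 1L
    } else {
      asg <- hungarian_assign(-sub)
    }
    for (k in seq_along(ti)) {
      j <- asg[k]
      if (!is.na(j) && j > 0 && sub[k, j] >= threshold) {
        matches <- rbind(matches, c(ti[k], di[j]))
      }
    }
  }
  list(matches = matches,
       unmatched_tracks = setdiff(seq_len(nt), matches[, 1]),
       unmatched_detections = setdiff(seq_len(nd), matches[, 2]))
}

#' Create a SORT tracker
#'
#' Returns a mutable tracker object (an environment) that consumes frames via
#' [tracker_step()] and maintains the permanent-ID counting register: a track
#' whose box centre crosses the lower frame edge is retired and its id
#' blacklisted, so a seedling leaving the frame can never be re-counted.
#'
#' @param config a [tracker_config()].
#' @param frame_size `c(width, height)` in pixels.
#' @return An object of class `sort_tracker`.
#' @seealso [tracker_step()], [tracker_count()], [tracker_log()]
#' @export
sort_tracker <- function(config = tracker_config(),
                         frame_size = c(1920, 1080)) {
  trk <- new.env(parent = emptyenv())
  trk$config <- config
  trk$frame_size <- frame_size
  trk$mats <- kalman_matrices(config$process_noise, config$measurement_noise)
  trk$X <- matrix(0, 7, 0)       # states, one column per live track
  trk$P <- list()                # covariances
  trk$id <- integer(0)
  trk$hits <- integer(0)
  trk$age <- integer(0)
  trk$tsu <- integer(0)          # time since update
  trk$status <- character(0)     # TENTATIVE / CONFIRMED
  trk$ret_hits <- integer(0)     # matched detections flagged as retained
  trk$tot_hits <- integer(0)     # matched detections carrying a flag
  trk$next_id <- 1L
  trk$last_frame <- 0L
  trk$confirmed_ids <- integer(0)
  trk$retired_ids <- integer(0)
  trk$counted_ids <- integer(0)  # finalised tracks that entered the count
  trk$log <- list()
  class(trk) <- "sort_tracker"
  trk
}

# A track is finalised when it leaves the active set (deletion, lower-edge
# retirement, or end of video). A finalised track enters the count when it
# was confirmed and the majority of its flagged matches were retained by the
# clustering stage (with no flags it counts on confirmation alone).
finalize_tracks <- function(trk, idx) {
  for (i in idx) {
    if (trk$id[i] %in% trk$confirmed_ids &&
        (trk$tot_hits[i] == 0L ||
         trk$ret_hits[i] > trk$tot_hits[i] / 2)) {
      trk$counted_ids <- c(trk$counted_ids, trk$id[i])
    }
  }
}

drop_tracks <- function(trk, idx) {
  if (length(idx) == 0) return()
  keep <- setdiff(seq_along(trk$id), idx)
  trk$X <- trk$X[, keep, drop = FALSE]
  trk$P <- trk$P[keep]
  trk$id <- trk$id[keep]
  trk$hits <- trk$hits[keep]
  trk$age <- trk$age[keep]
  trk$tsu <- trk$tsu[keep]
  trk$status <- trk$status[keep]
  trk$ret_hits <- trk$ret_hits[keep]
  trk$tot_hits <- trk$tot_hits[keep]
}

#' Advance the tracker by one frame
#'
#' Runs the SORT cycle: Kalman time update for every live track, Hungarian
#' IoU association against the frame's detections, Kalman measurement update
#' for matches, spawning of tentative tracks for unmatched detections,
#' deletion of stale tracks, confirmation at `min_hits`, and lower-edge
#' retirement of tracks whose centre has reached `v >= frame height`.
#'
#' @param trk a [sort_tracker()].
#' @param det detections for this frame (tibble with `x`, `y`, `w`, `h`;
#'   zero rows for an empty frame). An optional logical `retained` column
#'   carries the clustering stage's verdict per detection; it feeds the
#'   majority vote that decides whether a finalised track is counted.
#' @param frame frame index; must exceed the previously processed index.
#' @return Invisibly, a tibble of live tracks after the update (`frame`,
#'   `id`, `x`, `y`, `w`, `h`, `status`, `hits`, `count` — the running count).
#' @export
tracker_step <- function(trk, det, frame) {
  if (frame <= trk$last_frame) {
    stop("frames must be presented in increasing order", call. = FALSE)
  }
  trk$last_frame <- as.integer(frame)
  mats <- trk$mats
  n <- length(trk$id)
  # --- predict
  if (n > 0) {
    for (i in seq_len(n)) {
      x <- trk$X[, i]
      if (x[3] + x[7] <= 0) x[7] <- 0   # keep predicted area positive
      x <- mats$F %*% x
      if (x[3] <= 0) { x[3] <- 1e-6; x[7] <- 0 }
      trk$X[, i] <- x
      trk$P[[i]] <- mats$F %*% trk$P[[i]] %*% t(mats$F) + mats$Q
    }
    trk$age <- trk$age + 1L
    trk$tsu <- trk$tsu + 1L
  }
  pred_boxes <- as.data.frame(t(apply(trk$X, 2, state_to_box)))
  if (n == 0) pred_boxes <- data.frame(x = double(0), y = double(0),
                                       w = double(0), h = double(0))
  colnames(pred_boxes) <- c("x", "y", "w", "h")
  nd <- nrow(det)
  assoc <- associate_detections(pred_boxes, det, trk$config$iou_threshold)
  # --- rescue pass: before spawning identities, try to re-bind leftover
  # detections to coasting tracks at a relaxed gate (apparent speed diverges
  # near the lower frame edge; one strict-gate miss must not fragment an id)
  if (trk$config$rescue_iou > 0 &&
      length(assoc$unmatched_tracks) > 0 &&
      length(assoc$unmatched_detections) > 0) {
    ut <- assoc$unmatched_tracks; ud <- assoc$unmatched_detections
    resc <- associate_detections(pred_boxes[ut, , drop = FALSE],
                                 det[ud, , drop = FALSE],
                                 trk$config$rescue_iou)
    if (nrow(resc$matches) > 0) {
      remap <- cbind(ut[resc$matches[, 1]], ud[resc$matches[, 2]])
      assoc$matches <- rbind(assoc$matches, remap)
      assoc$unmatched_tracks <- setdiff(ut, remap[, 1])
      assoc$unmatched_detections <- setdiff(ud, remap[, 2])
    }
  }
  # --- measurement update for matches
  if (nrow(assoc$matches) > 0) {
    for (k in seq_len(nrow(assoc$matches))) {
      i <- assoc$matches[k, 1]; j <- assoc$matches[k, 2]
      z <- box_to_z(det$x[j], det$y[j], det$w[j], det$h[j])
      x <- trk$X[, i]; P <- trk$P[[i]]
      y_res <- z - as.vector(mats$H %*% x)
      S <- mats$H %*% P %*% t(mats$H) + mats$R
      K <- P %*% t(mats$H) %*% solve(S)
      trk$X[, i] <- x + as.vector(K %*% y_res)
      trk$P[[i]] <- (diag(7) - K %*% mats$H) %*% P
      trk$hits[i] <- trk$hits[i] + 1L
      if ("retained" %in% names(det)) {
        trk$tot_hits[i] <- trk$tot_hits[i] + 1L
        trk$ret_hits[i] <- trk$ret_hits[i] + as.integer(det[["retained"]][j])
      }
      trk$tsu[i] <- 0L
      if (trk$status[i] == "TENTATIVE" && trk$hits[i] >= trk$config$min_hits) {
        trk$status[i] <- "CONFIRMED"
        trk$confirmed_ids <- c(trk$confirmed_ids, trk$id[i])
      }
    }
  }
  # --- spawn tentative tracks for unmatched detections. Image motion is
  # dominated by the camera's forward walk, so a fresh track starts with the
  # median velocity of established tracks (ego-motion prior) instead of
  # zero: with sub-spacing apparent motion a zero-velocity prediction sits
  # closer to the neighbouring plant's detection than to its own.
  vel_prior <- c(0, 0, 0)
  seasoned <- trk$hits >= 2L & trk$tsu == 0L
  if (any(seasoned)) {
    vel_prior[1:2] <- apply(trk$X[5:6, seasoned, drop = FALSE], 1,
                            stats::median)
    # area velocity stays 0: box growth is depth-specific, not shared
  }
  for (j in assoc$unmatched_detections) {
    z <- box_to_z(det$x[j], det$y[j], det$w[j], det$h[j])
    trk$X <- cbind(trk$X, c(z, vel_prior))
    trk$P <- c(trk$P, list(mats$P0))
    trk$id <- c(trk$id, trk$next_id)
    trk$hits <- c(trk$hits, 1L)
    has_flag <- "retained" %in% names(det)
    trk$tot_hits <- c(trk$tot_hits, as.integer(has_flag))
    trk$ret_hits <- c(trk$ret_hits,
                      if (has_flag) as.integer(det[["retained"]][j]) else 0L)
    trk$age <- c(trk$age, 1L)
    trk$tsu <- c(trk$tsu, 0L)
    st <- if (trk$config$min_hits <= 1L) "CONFIRMED" else "TENTATIVE"
    if (st == "CONFIRMED") trk$confirmed_ids <- c(trk$confirmed_ids,
                                                  trk$next_id)
    trk$status <- c(trk$status, st)
    trk$next_id <- trk$next_id + 1L
  }
  # --- delete stale tracks
  stale <- which(trk$tsu > trk$config$max_age)
  finalize_tracks(trk, stale)
  drop_tracks(trk, stale)
  # --- retire tracks whose centre has crossed the lower frame edge
  if (length(trk$id) > 0) {
    crossed <- which(trk$X[2, ] >= trk$frame_size[2])
    if (length(crossed) > 0) {
      trk$retired_ids <- c(trk$retired_ids, trk$id[crossed])
      finalize_tracks(trk, crossed)
      drop_tracks(trk, crossed)
    }
  }
  out <- tracker_tracks(trk, frame)
  trk$log[[length(trk$log) + 1L]] <- out
  invisible(out)
}

#' Live tracks as a tibble
#'
#' @param trk a [sort_tracker()].
#' @param frame frame index to stamp on the rows (defaults to the last
#'   processed frame).
#' @return Tibble with one row per live track: `frame`, `id`, `x`, `y`, `w`,
#'   `h`, `status`, `hits`, `count` (running count).
#' @export
tracker_tracks <- function(trk, frame = trk$last_frame) {
  n <- length(trk$id)
  boxes <- if (n > 0) t(apply(trk$X, 2, state_to_box)) else
    matrix(0, 0, 4)
  tibble::tibble(frame = rep(as.integer(frame), n), id = trk$id,
                 x = boxes[, 1], y = boxes[, 2], w = boxes[, 3],
                 h = boxes[, 4], status = trk$status, hits = trk$hits,
                 count = rep(tracker_count(trk), n))
}

#' Final (or running) seedling count
#'
#' Tracks enter the count when they finalise (deletion, lower-edge
#' retirement, or [tracker_finalize()] at end of video), provided they were
#' confirmed and — when the clustering stage supplied per-detection
#' `retained` flags — the majority of their matched detections were
#' retained. Because counting happens at finalisation the running count is
#' monotone non-decreasing, and each retired id is blacklisted so a
#' seedling crossing the lower edge contributes exactly once. Under
#' `count_mode = "retired"` only counted ids that retired at the lower
#' edge count.
#'
#' @param trk a [sort_tracker()].
#' @return Integer count.
#' @export
tracker_count <- function(trk) {
  if (trk$config$count_mode == "confirmed") {
    length(unique(trk$counted_ids))
  } else {
    length(unique(intersect(trk$counted_ids, trk$retired_ids)))
  }
}

#' Finalise all live tracks at end of video
#'
#' Flushes the remaining active tracks through the counting vote (a plant
#' still tracked when the video ends must be counted too).
#'
#' @param trk a [sort_tracker()].
#' @return The final count, invisibly.
#' @export
tracker_finalize <- function(trk) {
  live <- seq_along(trk$id)
  keep <- !(trk$id %in% trk$counted_ids)
  finalize_tracks(trk, live[keep])
  drop_tracks(trk, live)
  invisible(tracker_count(trk))
}

#' @rdname tracker_count
#' @export
final_count <- tracker_count

#' Per-frame track log
#'
#' @param trk a [sort_tracker()].
#' @return Tibble binding the per-frame live-track tables emitted by
#'   [tracker_step()] (columns as in [tracker_tracks()]).
#' @export
tracker_log <- function(trk) {
  if (length(trk$log) == 0) {
    return(tracker_tracks(trk, 0L)[0, ])
  }
  dplyr::bind_rows(trk$log)
}
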