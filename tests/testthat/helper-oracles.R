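# Independent reference implementations used as oracles. These deliberately
# use different algorithmic routes from the package (full loops, exhaustive
# enumeration) so agreement is informative.

# Classic DBSCAN, textbook formulation: seeded breadth-first expansion over a
# precomputed neighbour list. min_samples counts the point itself.
reference_dbscan <- function(pts, eps, min_samples) {
  n <- nrow(pts)
  d <- as.matrix(stats::dist(pts))
  nbrs <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(nbrs, length, integer(1)) >= min_samples
  label <- rep(NA_integer_, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || !is.na(label[i])) next
    cl <- cl + 1L
    queue <- i
    label[i] <- cl
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      for (q in nbrs[[p]]) {
        if (is.na(label[q])) {
          label[q] <- cl
          if (core[q]) queue <- c(queue, q)
        }
      }
    }
  }
  list(label = label, core = core)
}

# TRUE when two labelings partition points identically up to renaming of
# cluster ids (NA = noise must coincide exactly).
same_partition <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  if (!identical(is.na(a), is.na(b))) return(FALSE)
  ok <- !is.na(a)
  if (!any(ok)) return(TRUE)
  key_a <- match(a[ok], unique(a[ok]))
  key_b <- match(b[ok], unique(b[ok]))
  identical(key_a, key_b)
}

# Exhaustive minimum-cost assignment over all injections of rows into
# columns; returns the optimal total cost.
brute_force_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  if (n > m) return(brute_force_assignment(t(cost)))
  best <- Inf
  rec <- function(i, used, acc) {
    if (acc >= best) return()
    if (i > n) { best <<- acc; return() }
    for (j in seq_len(m)) {
      if (!used[j]) {
        used[j] <- TRUE
        rec(i + 1L, used, acc + cost[i, j])
        used[j] <- FALSE
      }
    }
  }
  rec(1L, rep(FALSE, m), 0)
  best
}

# Exhaustive best one-to-one detection/truth matching: maximises matched
# pairs, then total IoU, over all injective mappings (tiny instances only).
brute_force_det_match <- function(iou, thr) {
  np <- nrow(iou); nt <- ncol(iou)
  best <- list(n = -1L, total = -Inf)
  rec <- function(i, used, n_matched, total) {
    if (i > np) {
      if (n_matched > best$n ||
          (n_matched == best$n && total > best$total)) {
        best <<- list(n = n_matched, total = total)
      }
      return()
    }
    rec(i + 1L, used, n_matched, total)        # leave prediction i unmatched
    for (j in seq_len(nt)) {
      if (!used[j] && iou[i, j] >= thr) {
        used[j] <- TRUE
        rec(i + 1L, used, n_matched + 1L, total + iou[i, j])
        used[j] <- FALSE
      }
    }
  }
  rec(1L, rep(FALSE, nt), 0L, 0)
  best
}

# All-pairs spacing statistics for one point: the k Euclidean-nearest
# neighbours found by a full scan, then sorted-x consecutive gaps.
brute_force_spacings <- function(pts, i, k) {
  d2 <- (pts[, 1] - pts[i, 1])^2 + (pts[, 2] - pts[i, 2])^2
  ord <- order(d2)
  nn <- setdiff(ord, i)[seq_len(min(k, nrow(pts) - 1))]
  diff(sort(pts[c(i, nn), 1]))
}
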