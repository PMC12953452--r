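#' Detection tables
#'
#' Throughout rowcountr a set of detections is an ordinary tibble with one row
#' per bounding box and columns:
#'
#' * `frame` — 1-based frame index (integer),
#' * `id` — track / identity label (integer; `-1` when unknown, as in raw
#'   detector output),
#' * `x`, `y` — top-left corner in pixels (origin at the image top-left,
#'   y increasing downward, so the lower edge of the frame is `y = frame
#'   height`),
#' * `w`, `h` — box width and height in pixels (strictly positive),
#' * `conf` — detector confidence in \[0, 1\].
#'
#' `detections()` validates and normalises a data frame into this shape.
#' Confidence values outside \[0, 1\] are clamped with a warning (detector
#' exports vary); non-positive widths or heights are an error.
#'
#' @param df data frame with the columns above (extra columns are dropped).
#' @return A tibble with columns `frame`, `id`, `x`, `y`, `w`, `h`, `conf`,
#'   sorted by frame.
#' @examples
#' detections(data.frame(frame = 1, id = -1, x = 10, y = 20, w = 30, h = 40,
#'                       conf = 0.9))
#' @export
detections <- function(df) {
  cols <- c("frame", "id", "x", "y", "w", "h", "conf")
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols) > 0) {
    stop("missing detection columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::as_tibble(df)[cols]
  out$frame <- as.integer(out$frame)
  out$id <- as.integer(out$id)
  if (any(out$frame < 1L)) stop("frame indices must be >= 1", call. = FALSE)
  if (any(out$w <= 0) || any(out$h <= 0)) {
    stop("bounding boxes must have positive width and height", call. = FALSE)
  }
  if (any(out$conf < 0 | out$conf > 1)) {
    warning("confidence values outside [0, 1] clamped", call. = FALSE)
    out$conf <- pmin(1, pmax(0, out$conf))
  }
  dplyr::arrange(out, .data$frame)
}

empty_detections <- function() {
  tibble::tibble(frame = integer(), id = integer(), x = double(),
                 y = double(), w = double(), h = double(), conf = double())
}

#' Read a MOT-dialect detection or ground-truth file
#'
#' Parses the comma-separated multi-object-tracking text format
#' (`frame,id,x,y,w,h,conf,...`; at least seven columns, extra columns
#' ignored). For `kind = "detections"` the id column is discarded (set to
#' `-1`); for `kind = "ground_truth"` identities are preserved.
#'
#' @param path file path.
#' @param kind `"detections"` or `"ground_truth"`.
#' @return A detection tibble (see [detections()]); zero rows for an empty
#'   file.
#' @seealso [write_mot()], [read_yolo_labels()]
#' @export
read_mot <- function(path, kind = c("detections", "ground_truth")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(empty_detections())
  fields <- strsplit(lines, ",", fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields < 7)) {
    bad <- which(n_fields < 7)[1]
    stop("malformed row at line ", bad, ": expected >= 7 comma-separated ",
         "fields, got ", n_fields[bad], call. = FALSE)
  }
  num <- suppressWarnings(
    vapply(fields, function(f) as.numeric(f[1:7]), numeric(7))
  )
  if (anyNA(num)) {
    bad <- which(colSums(is.na(num)) > 0)[1]
    stop("malformed row at line ", bad, ": non-numeric field", call. = FALSE)
  }
  df <- tibble::tibble(
    frame = as.integer(num[1, ]), id = as.integer(num[2, ]),
    x = num[3, ], y = num[4, ], w = num[5, ], h = num[6, ], conf = num[7, ]
  )
  if (any(df$w <= 0) || any(df$h <= 0)) {
    bad <- which(df$w <= 0 | df$h <= 0)[1]
    stop("invalid box at line ", bad, ": non-positive width or height",
         call. = FALSE)
  }
  if (kind == "detections") df$id <- -1L
  detections(df)
}

#' Write detections to a MOT-dialect CSV file
#'
#' One detection per line, `frame,id,x,y,w,h,conf,-1,-1,-1`, frames in order;
#' coordinates and confidence are written with four decimals, so a
#' write/read round trip preserves values to that precision.
#'
#' @param det detection tibble (see [detections()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mot <- function(det, path) {
  det <- detections(det)
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (nrow(det) > 0) {
    writeLines(sprintf("%d,%d,%.4f,%.4f,%.4f,%.4f,%.4f,-1,-1,-1",
                       det$frame, det$id, det$x, det$y, det$w, det$h,
                       det$conf), con)
  }
  invisible(path)
}

#' Read YOLO-style normalised per-frame label files
#'
#' Each frame is a text file of rows `class cx cy w h [conf]` with centre and
#' size normalised to \[0, 1\]; pixel coordinates require the frame size to
#' denormalise. Files are mapped to frame indices by the integer embedded in
#' their file name (e.g. `000017.txt` is frame 17).
#'
#' @param dir directory containing one `.txt` file per frame.
#' @param frame_size `c(width, height)` in pixels.
#' @return A detection tibble; a missing `conf` column defaults to 1.
#' @export
read_yolo_labels <- function(dir, frame_size = c(1920, 1080)) {
  files <- list.files(dir, pattern = "\\.txt$", full.names = TRUE)
  if (length(files) == 0) return(empty_detections())
  frames <- as.integer(gsub("\\D", "", basename(files)))
  if (anyNA(frames)) stop("label file names must contain a frame number",
                          call. = FALSE)
  per_frame <- purrr::map2(files, frames, function(f, fr) {
    lines <- readLines(f, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) return(NULL)
    mat <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
    conf <- if (ncol(mat) >= 6) mat[, 6] else rep(1, nrow(mat))
    w <- mat[, 4] * frame_size[1]
    h <- mat[, 5] * frame_size[2]
    tibble::tibble(frame = fr, id = -1L,
                   x = mat[, 2] * frame_size[1] - w / 2,
                   y = mat[, 3] * frame_size[2] - h / 2,
                   w = w, h = h, conf = conf)
  })
  detections(dplyr::bind_rows(per_frame))
}

#' Box centres
#'
#' The single authoritative centre derivation used for clustering and for the
#' lower-edge counting rule: `(x + w/2, y + h/2)`.
#'
#' @param det detection tibble.
#' @return `det` with `cx` and `cy` columns added.
#' @export
box_centers <- function(det) {
  dplyr::mutate(det, cx = .data$x + .data$w / 2, cy = .data$y + .data$h / 2)
}

#' Clip boxes to the frame rectangle
#'
#' Intersects each box with `[0, width] x [0, height]`. Boxes whose
#' intersection with the frame is empty are flagged `degenerate` (their
#' coordinates are left unchanged) rather than collapsed to zero area.
#'
#' @param det detection tibble.
#' @param frame_size `c(width, height)` in pixels.
#' @return `det` with clipped `x`, `y`, `w`, `h` and a logical `degenerate`
#'   column.
#' @export
clip_boxes <- function(det, frame_size = c(1920, 1080)) {
  x2 <- pmin(det$x + det$w, frame_size[1])
  y2 <- pmin(det$y + det$h, frame_size[2])
  x1 <- pmax(det$x, 0)
  y1 <- pmax(det$y, 0)
  degenerate <- x2 <= x1 | y2 <= y1
  det$degenerate <- degenerate
  keep <- !degenerate
  det$x[keep] <- x1[keep]
  det$y[keep] <- y1[keep]
  det$w[keep] <- (x2 - x1)[keep]
  det$h[keep] <- (y2 - y1)[keep]
  det
}

#' Intersection over union between two sets of boxes
#'
#' @param a,b data frames (or tibbles) with columns `x`, `y`, `w`, `h`.
#' @return A `nrow(a)` by `nrow(b)` matrix of IoU values in \[0, 1\].
#' @examples
#' a <- data.frame(x = 0, y = 0, w = 10, h = 10)
#' b <- data.frame(x = 5, y = 0, w = 10, h = 10)
#' box_iou(a, b)  # 1/3
#' @export
box_iou <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  if (na == 0 || nb == 0) return(matrix(0, na, nb))
  ax1 <- a$x; ay1 <- a$y; ax2 <- a$x + a$w; ay2 <- a$y + a$h
  bx1 <- b$x; by1 <- b$y; bx2 <- b$x + b$w; by2 <- b$y + b$h
  # overlap: pmin of right/bottom edges minus pmax of left/top edges
  iw <- pmin(outer(ax2, rep(1, nb)), outer(rep(1, na), bx2)) -
    pmax(outer(ax1, rep(1, nb)), outer(rep(1, na), bx1))
  ih <- pmin(outer(ay2, rep(1, nb)), outer(rep(1, na), by2)) -
    pmax(outer(ay1, rep(1, nb)), outer(rep(1, na), by1))
  inter <- pmax(iw, 0) * pmax(ih, 0)
  union <- outer(a$w * a$h, b$w * b$h, `+`) - inter
  ifelse(union > 0, inter / union, 0)
}
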