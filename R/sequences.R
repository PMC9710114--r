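#' Per-frame feature sequence
#'
#' Container for the per-video matrix of per-frame feature vectors consumed
#' by the temporal network: one row per frame, one column per feature
#' dimension, plus the frame rate after any downsampling and an opaque
#' video identifier.
#'
#' @param values numeric matrix, `T x D` (frames by feature dimensions).
#'   All entries must be finite.
#' @param fps frames per second of the sequence (after downsampling), `> 0`.
#' @param video_id character scalar identifying the source video.
#' @return An object of class `frame_features` with elements `values`,
#'   `fps`, `video_id`.
#' @examples
#' x <- frame_features(matrix(rnorm(20), 5, 4), fps = 20)
#' nrow(x$values)
#' @export
frame_features <- function(values, fps = 20, video_id = "video") {
  values <- as.matrix(values)
  if (!is.numeric(values) || nrow(values) < 1L || ncol(values) < 1L)
    stop("`values` must be a numeric matrix with at least one row and column")
  if (!all(is.finite(values)))
    stop("`values` must be finite")
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0)
    stop("`fps` must be a positive scalar")
  structure(list(values = values, fps = fps, video_id = as.character(video_id)),
            class = "frame_features")
}

#' @export
print.frame_features <- function(x, ...) {
  cat(sprintf("<frame_features> %s: %d frames x %d dims @ %g fps\n",
              x$video_id, nrow(x$values), ncol(x$values), x$fps))
  invisible(x)
}

#' Per-frame phase label sequence
#'
#' Integer phase labels (1..C) for every frame of a video, with frame-rate
#' metadata so segment durations can be expressed in seconds.
#'
#' @param labels integer vector of per-frame phase labels in `1..n_classes`.
#' @param n_classes number of phases `C`; defaults to `max(labels)`.
#' @param fps frames per second, `> 0`.
#' @return An object of class `phase_labels` with elements `labels`,
#'   `n_classes`, `fps`.
#' @examples
#' phase_labels(c(1, 1, 2, 2, 3), n_classes = 3)
#' @export
phase_labels <- function(labels, n_classes = max(labels), fps = 20) {
  labels <- as.integer(labels)
  if (length(labels) < 1L || anyNA(labels))
    stop("`labels` must be a non-empty integer vector without NA")
  n_classes <- as.integer(n_classes)
  if (any(labels < 1L) || any(labels > n_classes))
    stop("labels must lie in 1..n_classes")
  if (fps <= 0) stop("`fps` must be positive")
  structure(list(labels = labels, n_classes = n_classes, fps = fps),
            class = "phase_labels")
}

#' @export
print.phase_labels <- function(x, ...) {
  cat(sprintf("<phase_labels> %d frames, %d classes @ %g fps\n",
              length(x$labels), x$n_classes, x$fps))
  invisible(x)
}

# ---- feature-matrix file format ---------------------------------------------
#
# One video is stored as three files sharing a stem:
#   <stem>.fmat  binary dense matrix: ASCII magic "FMAT1\n", then two int32
#                (T, D, little-endian), then T*D float64 in row-major order.
#   <stem>.labels.csv  CSV with header frame_index,label (0-based, strictly
#                increasing frame_index).
#   <stem>.meta.json   JSON {video_id, fps, n_frames, n_dims, n_classes}.

#' Write a feature sequence (and labels) to disk
#'
#' Writes the binary feature matrix, the label sidecar CSV and the JSON
#' metadata file for one video. See the package vignette for the format.
#'
#' @param x a [frame_features] object.
#' @param labels a [phase_labels] object aligned with `x` (optional).
#' @param stem file path without extension; three files are written.
#' @return `stem`, invisibly.
#' @export
write_features <- function(x, labels = NULL, stem) {
  stopifnot(inherits(x, "frame_features"))
  con <- file(paste0(stem, ".fmat"), "wb")
  on.exit(close(con), add = TRUE)
  writeBin(charToRaw("FMAT1\n"), con)
  writeBin(as.integer(c(nrow(x$values), ncol(x$values))), con,
           size = 4L, endian = "little")
  writeBin(as.numeric(t(x$values)), con, size = 8L, endian = "little")
  n_classes <- NA_integer_
  if (!is.null(labels)) {
    stopifnot(inherits(labels, "phase_labels"),
              length(labels$labels) == nrow(x$values))
    utils::write.csv(
      data.frame(frame_index = seq_len(nrow(x$values)) - 1L,
                 label = labels$labels),
      paste0(stem, ".labels.csv"), row.names = FALSE)
    n_classes <- labels$n_classes
  }
  meta <- list(video_id = x$video_id, fps = x$fps,
               n_frames = nrow(x$values), n_dims = ncol(x$values),
               n_classes = n_classes)
  jsonlite::write_json(meta, paste0(stem, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' Read a feature sequence (and labels) from disk
#'
#' @param stem file path without extension, as used by [write_features()].
#' @return list with `features` ([frame_features]) and `labels`
#'   ([phase_labels] or `NULL` when no label sidecar exists).
#' @export
read_features <- function(stem) {
  path <- paste0(stem, ".fmat")
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  magic <- rawToChar(readBin(con, "raw", 6L))
  if (magic != "FMAT1\n") stop("not a feature-matrix file: ", path)
  dims <- readBin(con, "integer", 2L, size = 4L, endian = "little")
  vals <- readBin(con, "numeric", prod(dims), size = 8L, endian = "little")
  m <- matrix(vals, nrow = dims[1], ncol = dims[2], byrow = TRUE)
  meta <- jsonlite::read_json(paste0(stem, ".meta.json"))
  feats <- frame_features(m, fps = meta$fps, video_id = meta$video_id)
  labels <- NULL
  lab_path <- paste0(stem, ".labels.csv")
  if (file.exists(lab_path)) {
    lab <- utils::read.csv(lab_path)
    if (is.unsorted(lab$frame_index, strictly = TRUE))
      stop("frame_index must be strictly increasing in ", lab_path)
    nc <- if (is.null(meta$n_classes) || is.na(meta$n_classes))
      max(lab$label) else meta$n_classes
    labels <- phase_labels(lab$label, n_classes = nc, fps = meta$fps)
  }
  list(features = feats, labels = labels)
}

#' Downsample a feature/label pair to a target frame rate
#'
#' Keeps every `round(fps/target_fps)`-th frame of both the features and the
#' labels, mirroring the frame-rate reduction applied to surgical video
#' before temporal modelling.
#'
#' @param x a [frame_features] object.
#' @param labels a [phase_labels] object aligned with `x`, or `NULL`.
#' @param target_fps desired output frame rate; must not exceed `x$fps`.
#' @return list with downsampled `features` and `labels`.
#' @export
downsample_fps <- function(x, labels = NULL, target_fps) {
  stopifnot(inherits(x, "frame_features"), target_fps > 0)
  if (target_fps > x$fps) stop("target_fps exceeds source fps")
  step <- max(1L, as.integer(round(x$fps / target_fps)))
  keep <- seq(1L, nrow(x$values), by = step)
  out_fps <- x$fps / step
  feats <- frame_features(x$values[keep, , drop = FALSE], fps = out_fps,
                          video_id = x$video_id)
  labs <- NULL
  if (!is.null(labels)) {
    stopifnot(length(labels$labels) == nrow(x$values))
    labs <- phase_labels(labels$labels[keep], n_classes = labels$n_classes,
                         fps = out_fps)
  }
  list(features = feats, labels = labs)
}
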