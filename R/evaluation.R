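# Frame-level evaluation: one-vs-rest confusion counts per phase, macro
# accuracy/precision/recall/Jaccard, run-length segment extraction,
# transition-deviation analysis in seconds, and the color-coded phase
# ribbon visualization.

as_label_vec <- function(x) {
  if (inherits(x, "phase_labels")) x$labels else as.integer(x)
}

#' One-vs-rest confusion counts per phase
#'
#' For every class `c`, counts the frames that are true/false
#' positives/negatives of the binary problem "is this frame phase c".
#'
#' @param pred predicted labels ([phase_labels] or integer vector).
#' @param truth ground-truth labels of the same length.
#' @param n_classes number of phases `C`; defaults to the larger of the
#'   two label ranges.
#' @return object of class `confusion_counts`: data.frame with columns
#'   `class`, `tp`, `tn`, `fp`, `fn` plus attributes `n_frames` and
#'   `n_classes`.
#' @export
confusion_counts <- function(pred, truth, n_classes = NULL) {
  p <- as_label_vec(pred); y <- as_label_vec(truth)
  if (length(p) != length(y)) stop("pred and truth lengths differ")
  if (is.null(n_classes)) {
    n_classes <- max(p, y)
    if (inherits(pred, "phase_labels")) n_classes <- max(n_classes, pred$n_classes)
    if (inherits(truth, "phase_labels")) n_classes <- max(n_classes, truth$n_classes)
  }
  N <- length(y)
  cls <- seq_len(n_classes)
  tp <- vapply(cls, function(c) sum(p == c & y == c), numeric(1))
  fp <- vapply(cls, function(c) sum(p == c & y != c), numeric(1))
  fn <- vapply(cls, function(c) sum(p != c & y == c), numeric(1))
  out <- data.frame(class = cls, tp = tp, tn = N - tp - fp - fn,
                    fp = fp, fn = fn)
  attr(out, "n_frames") <- N
  attr(out, "n_classes") <- as.integer(n_classes)
  class(out) <- c("confusion_counts", "data.frame")
  out
}

#' Confusion matrix (truth in rows, prediction in columns)
#'
#' @inheritParams confusion_counts
#' @return `C x C` integer matrix of frame counts.
#' @export
confusion_matrix <- function(pred, truth, n_classes = NULL) {
  p <- as_label_vec(pred); y <- as_label_vec(truth)
  if (length(p) != length(y)) stop("pred and truth lengths differ")
  if (is.null(n_classes)) n_classes <- max(p, y)
  m <- matrix(0L, n_classes, n_classes,
              dimnames = list(truth = seq_len(n_classes),
                              pred = seq_len(n_classes)))
  tab <- table(factor(y, levels = seq_len(n_classes)),
               factor(p, levels = seq_len(n_classes)))
  m[] <- as.integer(tab)
  m
}

#' Frame-level macro metrics
#'
#' Macro precision, recall and Jaccard average the per-class one-vs-rest
#' ratios `TP/(TP+FP)`, `TP/(TP+FN)` and `TP/(TP+FP+FN)`; accuracy is the
#' overall fraction of correctly labeled frames `sum(TP_c) / N`.  Classes
#' absent from both truth and prediction contribute nothing; per-class
#' terms with a zero denominator are skipped from the macro mean and the
#' number skipped is reported.
#'
#' @param counts a [confusion_counts()] object.
#' @return list with `accuracy`, `precision`, `recall`, `jaccard`,
#'   `per_class` (data.frame of per-class ratios) and `n_skipped`.
#' @export
phase_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  N <- attr(counts, "n_frames")
  if (N == 0) stop("no frames")
  present <- counts$tp + counts$fp + counts$fn > 0
  safe_mean <- function(num, den) {
    ok <- present & den > 0
    list(mean = if (any(ok)) mean(num[ok] / den[ok]) else NA_real_,
         skipped = sum(present & den == 0))
  }
  prec <- safe_mean(counts$tp, counts$tp + counts$fp)
  rec <- safe_mean(counts$tp, counts$tp + counts$fn)
  jac <- safe_mean(counts$tp, counts$tp + counts$fp + counts$fn)
  per_class <- data.frame(
    class = counts$class,
    precision = ifelse(counts$tp + counts$fp > 0,
                       counts$tp / (counts$tp + counts$fp), NA_real_),
    recall = ifelse(counts$tp + counts$fn > 0,
                    counts$tp / (counts$tp + counts$fn), NA_real_),
    jaccard = ifelse(counts$tp + counts$fp + counts$fn > 0,
                     counts$tp / (counts$tp + counts$fp + counts$fn),
                     NA_real_))
  list(accuracy = sum(counts$tp) / N,
       precision = prec$mean, recall = rec$mean, jaccard = jac$mean,
       per_class = per_class,
       n_skipped = max(prec$skipped, rec$skipped, jac$skipped))
}

#' Run-length segments and transitions of a label sequence
#'
#' @param labels a [phase_labels] object or integer vector.
#' @return object of class `segment_list`: list with `segments`
#'   (data.frame `phase`, `start`, `end`; half-open 0-based frame ranges
#'   partitioning `[0, T)`) and `transitions` (data.frame `frame`,
#'   `from`, `to`; `frame` is the first frame of each new run).
#' @examples
#' segments_and_transitions(c(1, 1, 2, 2, 2, 3))
#' @export
segments_and_transitions <- function(labels) {
  y <- as_label_vec(labels)
  r <- rle(y)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  segs <- data.frame(phase = r$values, start = starts, end = ends)
  if (length(r$values) > 1L) {
    tr <- data.frame(frame = starts[-1L],
                     from = r$values[-length(r$values)],
                     to = r$values[-1L])
  } else {
    tr <- data.frame(frame = integer(0), from = integer(0), to = integer(0))
  }
  structure(list(segments = segs, transitions = tr,
                 n_frames = length(y)),
            class = "segment_list")
}

#' Expand a segment list back to per-frame labels
#'
#' @param x a `segment_list`.
#' @return integer vector of length `T`.
#' @export
expand_segments <- function(x) {
  stopifnot(inherits(x, "segment_list"))
  rep(x$segments$phase, x$segments$end - x$segments$start)
}

#' Transition timing deviation in seconds
#'
#' For every ground-truth transition into a phase `p`, the deviation is the
#' time (in seconds) to the nearest predicted transition into `p`.  When
#' the prediction contains no transition into `p` the deviation is
#' reported as missing (`NA`), not as zero.
#'
#' @param pred a `segment_list` from the predicted labels.
#' @param truth a `segment_list` from the ground truth (same video length).
#' @param fps frames per second (`> 0`).
#' @return data.frame with one row per true transition: `frame`, `from`,
#'   `to`, `pred_frame`, `deviation_s`; attribute `summary` holds the
#'   mean/median/max over matched transitions.
#' @export
transition_deviation <- function(pred, truth, fps) {
  stopifnot(inherits(pred, "segment_list"), inherits(truth, "segment_list"))
  if (fps <= 0) stop("fps must be positive")
  if (pred$n_frames != truth$n_frames)
    stop("pred and truth cover different numbers of frames")
  tt <- truth$transitions
  pt <- pred$transitions
  out <- tt
  out$pred_frame <- NA_integer_
  out$deviation_s <- NA_real_
  if (nrow(tt) > 0) {
    for (i in seq_len(nrow(tt))) {
      cand <- pt$frame[pt$to == tt$to[i]]
      if (length(cand) > 0) {
        j <- which.min(abs(cand - tt$frame[i]))
        out$pred_frame[i] <- cand[j]
        out$deviation_s[i] <- abs(cand[j] - tt$frame[i]) / fps
      }
    }
  }
  dev <- out$deviation_s[!is.na(out$deviation_s)]
  attr(out, "summary") <- list(
    mean_s = if (length(dev)) mean(dev) else NA_real_,
    median_s = if (length(dev)) stats::median(dev) else NA_real_,
    max_s = if (length(dev)) max(dev) else NA_real_,
    n_missing = sum(is.na(out$deviation_s)))
  out
}

#' Default phase color palette
#'
#' A fixed nine-color palette for up to `n` phases (recycled beyond nine),
#' so that ribbon renderings are deterministic.
#'
#' @param n number of phases.
#' @return character vector of hex colors.
#' @export
phase_palette <- function(n) {
  base <- c("#E64B35", "#4DBBD5", "#00A087", "#3C5488", "#F39B7F",
            "#8491B4", "#91D1C2", "#DC0000", "#7E6148")
  rep_len(base, n)
}

#' Render a color-coded phase ribbon
#'
#' Draws one horizontal color bar per label sequence (e.g. prediction above
#' ground truth) with a shared phase-to-color map and time on the
#' horizontal axis, and writes it as a PNG.  The output is deterministic:
#' the same inputs and palette produce a byte-identical file.
#'
#' @param sequences named list of [phase_labels] objects (or integer
#'   vectors), all of the same length.
#' @param path output PNG path.
#' @param palette colors per phase; default [phase_palette()].
#' @param row_px bar height in pixels (default 24); a 2-pixel white gap
#'   separates bars.
#' @param width_px image width in pixels; label sequences are resampled
#'   column-wise to this width (default `min(T, 1024)`).
#' @return `path`, invisibly.
#' @export
render_ribbon <- function(sequences, path, palette = NULL, row_px = 24L,
                          width_px = NULL) {
  labs <- lapply(sequences, as_label_vec)
  lens <- vapply(labs, length, integer(1))
  if (length(unique(lens)) != 1L) stop("sequences have mixed lengths")
  Tn <- lens[1]
  C <- max(unlist(labs))
  if (is.null(palette)) palette <- phase_palette(C)
  if (is.null(width_px)) width_px <- min(Tn, 1024L)
  cols_rgb <- grDevices::col2rgb(palette) / 255
  gap <- 2L
  nseq <- length(labs)
  H <- nseq * row_px + (nseq - 1L) * gap
  img <- array(1, dim = c(H, width_px, 3))
  x_idx <- pmin(Tn, pmax(1L, ceiling(seq_len(width_px) * Tn / width_px)))
  for (s in seq_len(nseq)) {
    rows <- (s - 1L) * (row_px + gap) + seq_len(row_px)
    phase_cols <- cols_rgb[, labs[[s]][x_idx], drop = FALSE]
    for (ch in 1:3)
      img[rows, , ch] <- matrix(phase_cols[ch, ], nrow = length(rows),
                                ncol = width_px, byrow = TRUE)
  }
  png::writePNG(img, path)
  invisible(path)
}
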