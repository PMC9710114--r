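# Synthetic phase-structured "surgery videos" at two fidelities:
# feature-level sequences (Gaussian per-phase emissions) for the temporal
# network, and small rendered frames with pupil/instrument boxes for the
# frontend.  The generator emulates the structure that makes surgical
# phase recognition hard -- ordered phases with highly variable durations,
# rare short phases, and designated near-identical phase pairs -- without
# any claim to real microscope appearance.

#' Specification of a synthetic surgery-video distribution
#'
#' @param n_phases number of phases `C` (default 9, the cataract workflow).
#' @param phase_order order in which phases appear (default `1:n_phases`,
#'   the quasi-standardized strictly increasing progression).
#' @param duration_range integer matrix `C x 2` of per-phase
#'   `(min, max)` frame counts for the uniform duration draw; default
#'   `(40, 160)` frames per phase with `(6, 20)` for `rare_phases`.
#' @param rare_phases phases given short durations (default phase 1,
#'   mimicking the brief incision phase).
#' @param feature_dim feature dimensionality `D` (default 64; must be
#'   `>= n_phases` for the default orthogonal means).
#' @param noise_sd per-dimension Gaussian emission noise (default 1).
#' @param mean_sep pairwise Euclidean distance between phase means in
#'   units of `noise_sd` (default 8, a cleanly recoverable regime).
#' @param phase_means optional `C x D` matrix of phase means; by default
#'   phase `p` sits at `mean_sep * noise_sd / sqrt(2)` along axis `p`, so
#'   all pairwise distances equal `mean_sep * noise_sd`.
#' @param confusable_pairs list of `(p, q, overlap)` triples; the mean of
#'   phase `q` is moved to
#'   `(1 - overlap) * mean_q + overlap * mean_p`, so `overlap = 1` makes
#'   the two phases emission-identical (the irrigation/aspiration versus
#'   viscous-removal analog). With at least 8 phases the default moves
#'   phase 8 most of the way to phase 5; otherwise no pair is confused.
#' @param drift_amount amplitude of a slow linear within-phase feature
#'   drift (default 0 = off).
#' @param markov if `TRUE`, each phase transition may revisit an earlier
#'   phase with probability `revisit_prob` (default off; the strict order
#'   is the default workflow).
#' @param revisit_prob revisit probability in markov mode.
#' @param image_size side length of rendered frames (default 128).
#' @param instrument_free_phases phases rendered without an instrument
#'   (default the final phase), emulating instrument-free hard frames.
#' @param render_noise_sd pixel noise of rendered frames (default 0.02).
#' @param fps nominal frame rate of generated sequences (default 20).
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_phases = 9L,
                           phase_order = seq_len(n_phases),
                           duration_range = NULL,
                           rare_phases = 1L,
                           feature_dim = 64L,
                           noise_sd = 1,
                           mean_sep = 8,
                           phase_means = NULL,
                           confusable_pairs = NULL,
                           drift_amount = 0,
                           markov = FALSE,
                           revisit_prob = 0.15,
                           image_size = 128L,
                           instrument_free_phases = n_phases,
                           render_noise_sd = 0.02,
                           fps = 20) {
  n_phases <- as.integer(n_phases)
  stopifnot(n_phases >= 2, all(phase_order %in% seq_len(n_phases)),
            noise_sd > 0, fps > 0)
  # default near-identical pair: the irrigation/aspiration (P5) versus
  # viscous-removal (P8) analog, only meaningful with enough phases
  if (is.null(confusable_pairs))
    confusable_pairs <- if (n_phases >= 8) list(c(5L, 8L, 0.9)) else list()
  if (is.null(duration_range)) {
    duration_range <- matrix(rep(c(40L, 160L), each = n_phases), n_phases, 2)
    duration_range[rare_phases, ] <- rep(c(6L, 20L), each = length(rare_phases))
  }
  duration_range <- matrix(as.integer(duration_range), n_phases, 2)
  stopifnot(all(duration_range[, 1] >= 1),
            all(duration_range[, 2] >= duration_range[, 1]))
  if (is.null(phase_means)) {
    if (feature_dim < n_phases)
      stop("feature_dim must be >= n_phases for the default phase means")
    phase_means <- matrix(0, n_phases, feature_dim)
    for (p in seq_len(n_phases))
      phase_means[p, p] <- mean_sep * noise_sd / sqrt(2)
  }
  phase_means <- as.matrix(phase_means)
  stopifnot(nrow(phase_means) == n_phases, all(is.finite(phase_means)))
  for (cp in confusable_pairs)
    stopifnot(length(cp) == 3, cp[1] %in% seq_len(n_phases),
              cp[2] %in% seq_len(n_phases), cp[3] >= 0, cp[3] <= 1)
  structure(list(n_phases = n_phases, phase_order = as.integer(phase_order),
                 duration_range = duration_range,
                 rare_phases = as.integer(rare_phases),
                 feature_dim = as.integer(feature_dim),
                 noise_sd = noise_sd, mean_sep = mean_sep,
                 phase_means = phase_means,
                 confusable_pairs = confusable_pairs,
                 drift_amount = drift_amount,
                 markov = markov, revisit_prob = revisit_prob,
                 image_size = as.integer(image_size),
                 instrument_free_phases = as.integer(instrument_free_phases),
                 render_noise_sd = render_noise_sd, fps = fps),
            class = "synthetic_spec")
}

#' Phase means after applying the confusable-pair overlaps
#'
#' @param spec a [synthetic_spec()].
#' @return `C x D` matrix of effective emission means.
#' @export
effective_means <- function(spec) {
  m <- spec$phase_means
  for (cp in spec$confusable_pairs) {
    p <- as.integer(cp[1]); q <- as.integer(cp[2]); ov <- cp[3]
    m[q, ] <- (1 - ov) * m[q, ] + ov * m[p, ]
  }
  m
}

#' Sample one per-frame phase label sequence
#'
#' Phases appear in `spec$phase_order`, each with a duration drawn
#' uniformly from its range; in markov mode a revisit to a random earlier
#' phase may be inserted after each scheduled phase.  Draws from the
#' current RNG stream (use `set.seed()` for reproducibility).
#'
#' @param spec a [synthetic_spec()].
#' @return a [phase_labels] object.
#' @export
sample_phase_sequence <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  order_seq <- spec$phase_order
  if (spec$markov && length(order_seq) > 1L) {
    out <- integer(0)
    for (i in seq_along(order_seq)) {
      out <- c(out, order_seq[i])
      if (i > 1L && stats::runif(1) < spec$revisit_prob)
        out <- c(out, sample(order_seq[seq_len(i - 1L)], 1L), order_seq[i])
    }
    order_seq <- out
  }
  dur <- vapply(order_seq, function(p) {
    rng <- spec$duration_range[p, ]
    as.integer(rng[1] + floor(stats::runif(1) * (rng[2] - rng[1] + 1L)))
  }, integer(1))
  phase_labels(rep(order_seq, dur), n_classes = spec$n_phases,
               fps = spec$fps)
}

#' Sample per-frame features for a label sequence
#'
#' Emits `x_t ~ Normal(mean(phase_t), noise_sd^2 I)` using the effective
#' means (after confusable-pair overlap), plus an optional slow linear
#' drift within each phase run.
#'
#' @param labels a [phase_labels] object.
#' @param spec a [synthetic_spec()].
#' @param video_id identifier stored in the result.
#' @return a [frame_features] object.
#' @export
sample_features <- function(labels, spec, video_id = "synthetic") {
  stopifnot(inherits(labels, "phase_labels"), inherits(spec, "synthetic_spec"))
  mu <- effective_means(spec)
  Tn <- length(labels$labels)
  D <- spec$feature_dim
  x <- mu[labels$labels, , drop = FALSE] +
    matrix(stats::rnorm(Tn * D, sd = spec$noise_sd), Tn, D)
  if (spec$drift_amount > 0) {
    segs <- segments_and_transitions(labels)$segments
    for (i in seq_len(nrow(segs))) {
      len <- segs$end[i] - segs$start[i]
      dir <- stats::rnorm(D)
      dir <- dir / sqrt(sum(dir^2))
      ramp <- seq(0, spec$drift_amount, length.out = len)
      x[(segs$start[i] + 1L):segs$end[i], ] <-
        x[(segs$start[i] + 1L):segs$end[i], , drop = FALSE] +
        outer(ramp, dir)
    }
  }
  frame_features(x, fps = spec$fps, video_id = video_id)
}

phase_color <- function(p) {
  # fixed, seed-independent map from phase to an RGB triple
  c(r = 0.15 + 0.8 * (((p * 37) %% 97) / 97),
    g = 0.15 + 0.8 * (((p * 59) %% 83) / 83),
    b = 0.15 + 0.8 * (((p * 17) %% 71) / 71))
}

#' Render synthetic frames and their detection table
#'
#' Every frame shows a fixed-position "pupil" disk whose color depends on
#' the phase and, except in `instrument_free_phases`, a phase-colored
#' rectangular "instrument" glyph at a random pose.  The emitted boxes
#' tightly bound the drawn shapes.  Draws from the current RNG stream.
#'
#' @param labels a [phase_labels] object.
#' @param spec a [synthetic_spec()].
#' @param video_id identifier used in the detection table.
#' @return list with `frames` (list of `S x S x 3` arrays) and
#'   `detections` (a detection data.frame; see [select_detections()]).
#' @export
render_frames <- function(labels, spec, video_id = "synthetic") {
  stopifnot(inherits(labels, "phase_labels"), inherits(spec, "synthetic_spec"))
  S <- spec$image_size
  cx <- S / 2; cy <- S / 2; r <- round(S * 0.22)
  px <- matrix(rep(seq_len(S) - 0.5, each = S), S, S)   # column coords
  py <- matrix(rep(seq_len(S) - 0.5, times = S), S, S)  # row coords
  disk <- (px - cx)^2 + (py - cy)^2 <= r^2
  frames <- vector("list", length(labels$labels))
  det <- vector("list", length(labels$labels))
  for (t in seq_along(labels$labels)) {
    p <- labels$labels[t]
    col3 <- phase_color(p)
    img <- array(stats::rnorm(S * S * 3, mean = 0.35,
                              sd = spec$render_noise_sd), c(S, S, 3))
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[disk] <- col3[ch]
      img[, , ch] <- plane
    }
    rows <- list(data.frame(video_id = video_id, frame_index = t - 1L,
                            object_class = "pupil",
                            x1 = cx - r, y1 = cy - r, x2 = cx + r,
                            y2 = cy + r, confidence = 1))
    if (!(p %in% spec$instrument_free_phases)) {
      w <- sample(10:24, 1L); h <- sample(4:10, 1L)
      if (stats::runif(1) < 0.5) { tmp <- w; w <- h; h <- tmp }
      ix <- sample.int(S - w, 1L) - 1L
      iy <- sample.int(S - h, 1L) - 1L
      icol <- phase_color(p + spec$n_phases)  # distinct from pupil colors
      img[iy + seq_len(h), ix + seq_len(w), 1] <- icol[1]
      img[iy + seq_len(h), ix + seq_len(w), 2] <- icol[2]
      img[iy + seq_len(h), ix + seq_len(w), 3] <- icol[3]
      rows[[2]] <- data.frame(video_id = video_id, frame_index = t - 1L,
                              object_class = "instrument",
                              x1 = ix, y1 = iy, x2 = ix + w, y2 = iy + h,
                              confidence = 1)
    }
    img[img < 0] <- 0; img[img > 1] <- 1
    frames[[t]] <- img
    det[[t]] <- do.call(rbind, rows)
  }
  list(frames = frames, detections = do.call(rbind, det))
}

#' Generate a synthetic train/validation/test dataset
#'
#' Draws `n_videos` independent videos from `spec`, assigns them to
#' disjoint video-level splits, and records a manifest (seed, spec
#' summary, per-video length and per-phase frame counts).
#'
#' @param spec a [synthetic_spec()].
#' @param n_videos total number of videos.
#' @param split_fractions length-3 fractions (train, validation, test)
#'   summing to 1.
#' @param mode `"features"` (default) emits feature sequences;
#'   `"rendered"` additionally emits frames and detection tables.
#' @param seed integer seed for the whole dataset.
#' @return object of class `synthetic_dataset`: list with `train`, `val`,
#'   `test` (lists of videos, each `list(features, labels, frames,
#'   detections)`) and `manifest`.
#' @export
generate_dataset <- function(spec, n_videos, split_fractions = c(0.7, 0.1, 0.2),
                             mode = c("features", "rendered"), seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "synthetic_spec"),
            abs(sum(split_fractions) - 1) < 1e-8,
            all(split_fractions >= 0))
  sizes <- floor(split_fractions * n_videos)
  rem <- n_videos - sum(sizes)
  if (rem > 0) {
    frac_rem <- split_fractions * n_videos - sizes
    add <- order(frac_rem, decreasing = TRUE)[seq_len(rem)]
    sizes[add] <- sizes[add] + 1L
  }
  if (any(split_fractions > 0 & sizes == 0))
    stop("n_videos too small for the requested split")
  set.seed(seed)
  split_of <- rep(c("train", "val", "test"), sizes)
  videos <- vector("list", n_videos)
  man_videos <- vector("list", n_videos)
  for (i in seq_len(n_videos)) {
    vid <- sprintf("synthetic_%03d", i)
    labels <- sample_phase_sequence(spec)
    v <- list(labels = labels,
              features = sample_features(labels, spec, video_id = vid))
    if (mode == "rendered") {
      rf <- render_frames(labels, spec, video_id = vid)
      v$frames <- rf$frames
      v$detections <- rf$detections
    }
    videos[[i]] <- v
    counts <- tabulate(labels$labels, spec$n_phases)
    man_videos[[i]] <- list(video_id = vid, split = split_of[i],
                            n_frames = length(labels$labels),
                            phase_counts = counts)
  }
  manifest <- list(seed = seed, mode = mode,
                   n_videos = n_videos, split_sizes = as.integer(sizes),
                   spec = list(n_phases = spec$n_phases,
                               feature_dim = spec$feature_dim,
                               noise_sd = spec$noise_sd,
                               mean_sep = spec$mean_sep,
                               fps = spec$fps),
                   videos = man_videos)
  structure(list(train = videos[split_of == "train"],
                 val = videos[split_of == "val"],
                 test = videos[split_of == "test"],
                 manifest = manifest),
            class = "synthetic_dataset")
}

#' Write a dataset manifest as JSON
#'
#' @param dataset a `synthetic_dataset`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(dataset, path) {
  jsonlite::write_json(dataset$manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
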