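# Independent oracles used across the suite.

# Brute-force direct-summation dilated convolution: no padding tricks, no
# matrix algebra shared with the implementation.
oracle_dilated_conv <- function(x, W, b, dilation, causal = TRUE) {
  Tn <- nrow(x); K <- dim(W)[1]; Cout <- dim(W)[3]
  out <- matrix(0, Tn, Cout)
  offsets <- if (causal) ((1:K) - K) * dilation
  else ((1:K) - (K + 1) / 2) * dilation
  for (t in seq_len(Tn)) {
    for (co in seq_len(Cout)) {
      acc <- b[co]
      for (k in seq_len(K)) {
        src <- t + offsets[k]
        if (src >= 1 && src <= Tn)
          for (ci in seq_len(ncol(x)))
            acc <- acc + W[k, ci, co] * x[src, ci]
      }
      out[t, co] <- acc
    }
  }
  out
}

# Naive unweighted cross-entropy, written independently of the package.
oracle_cross_entropy <- function(probs, labels) {
  -mean(log(probs[cbind(seq_along(labels), labels)]))
}

# Perturbation-measured receptive field of a stage: feed a constant
# sequence, perturb single input frames, and count which input frames can
# change the output at the last frame.  The layer-norm offsets are raised
# so every ReLU unit stays active: the measurement probes temporal
# connectivity, not the liveness of individual random units.
measure_receptive_field <- function(stage, Tn) {
  for (i in seq_along(stage$params$layers))
    stage$params$layers[[i]]$ln$beta[] <- 5
  x <- matrix(0.5, Tn, stage$cfg$in_dim)
  base <- stage_forward(stage, x)[Tn, ]
  influential <- vapply(seq_len(Tn), function(t) {
    xp <- x
    xp[t, ] <- xp[t, ] + 1
    any(stage_forward(stage, xp)[Tn, ] != base)
  }, logical(1))
  # span from the farthest influential frame to the output frame (the
  # influence set of a dual stage can skip odd offsets, so its size is
  # not the receptive field)
  Tn - min(which(influential)) + 1L
}

# Shared small recoverable-regime dataset builder for pipeline tests.
tiny_feature_dataset <- function(n_videos = 6, n_phases = 3, seed = 42) {
  spec <- synthetic_spec(
    n_phases = n_phases, feature_dim = 8, noise_sd = 1, mean_sep = 8,
    duration_range = matrix(rep(c(10L, 30L), each = n_phases), n_phases, 2),
    rare_phases = integer(0), confusable_pairs = list(), fps = 20)
  generate_dataset(spec, n_videos,
                   c(1 - 2 / n_videos, 1 / n_videos, 1 / n_videos) ,
                   seed = seed)
}

# Tiny rendered dataset for frontend tests.
tiny_rendered_dataset <- function(n_videos = 2, n_phases = 3, seed = 7) {
  spec <- synthetic_spec(
    n_phases = n_phases, feature_dim = 8, image_size = 64L,
    duration_range = matrix(rep(c(4L, 8L), each = n_phases), n_phases, 2),
    rare_phases = integer(0), confusable_pairs = list(),
    instrument_free_phases = n_phases, fps = 20)
  generate_dataset(spec, n_videos, c(1, 0, 0), mode = "rendered",
                   seed = seed)
}
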