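test_that("label sequences follow the phase order with seeded determinism", {
  # fixed durations: exactly one run per phase, in order
  spec <- synthetic_spec(n_phases = 9,
                         duration_range = matrix(10L, 9, 2),
                         rare_phases = integer(0))
  set.seed(1)
  lab <- sample_phase_sequence(spec)
  expect_identical(length(lab$labels), 90L)
  segs <- segments_and_transitions(lab)$segments
  expect_equal(segs$phase, 1:9)
  # identical seed, identical sequence
  spec2 <- synthetic_spec(n_phases = 5, feature_dim = 8)
  set.seed(99); a <- sample_phase_sequence(spec2)
  set.seed(99); b <- sample_phase_sequence(spec2)
  expect_identical(a$labels, b$labels)
})

test_that("uniform duration draws have the right mean", {
  spec <- synthetic_spec(n_phases = 2, feature_dim = 4,
                         duration_range = matrix(rep(c(5L, 50L), each = 2), 2, 2),
                         rare_phases = integer(0), confusable_pairs = list())
  set.seed(5)
  durs <- replicate(500, {
    segs <- segments_and_transitions(sample_phase_sequence(spec))$segments
    segs$end - segs$start
  })
  n <- length(durs)
  se <- sd(durs) / sqrt(n)
  expect_lt(abs(mean(durs) - 27.5), 3 * se)
})

test_that("feature emissions follow the phase means", {
  spec <- synthetic_spec(n_phases = 3, feature_dim = 6, noise_sd = 1,
                         mean_sep = 8, confusable_pairs = list(),
                         rare_phases = integer(0),
                         duration_range = matrix(rep(c(5L, 10L), each = 3), 3, 2))
  lab <- phase_labels(rep(1:3, each = 5), n_classes = 3)
  # zero noise reproduces the means exactly
  spec0 <- spec; spec0$noise_sd <- 1e-12
  set.seed(3)
  x0 <- sample_features(lab, spec0)
  mu <- effective_means(spec0)
  expect_equal(x0$values, mu[lab$labels, ], tolerance = 1e-6,
               ignore_attr = TRUE)
  # full overlap makes the pair emission-identical
  specc <- synthetic_spec(n_phases = 3, feature_dim = 6,
                          confusable_pairs = list(c(1, 3, 1)))
  muc <- effective_means(specc)
  expect_equal(muc[3, ], muc[1, ])
  # within-phase drift keeps lengths and finiteness
  specd <- spec; specd$drift_amount <- 2
  set.seed(4)
  xd <- sample_features(lab, specd)
  expect_identical(nrow(xd$values), length(lab$labels))
  expect_true(all(is.finite(xd$values)))
  # partial overlap moves the mean linearly
  spech <- synthetic_spec(n_phases = 3, feature_dim = 6,
                          confusable_pairs = list(c(1, 3, 0.5)))
  muh <- effective_means(spech)
  expect_equal(muh[3, ], (spech$phase_means[1, ] + spech$phase_means[3, ]) / 2)
})

test_that("well-separated means give near-perfect nearest-mean accuracy", {
  spec <- synthetic_spec(n_phases = 4, feature_dim = 8, noise_sd = 1,
                         mean_sep = 10, confusable_pairs = list(),
                         rare_phases = integer(0),
                         duration_range = matrix(rep(c(2500L, 2500L), each = 4),
                                                 4, 2))
  set.seed(11)
  lab <- sample_phase_sequence(spec)
  x <- sample_features(lab, spec)
  mu <- effective_means(spec)
  d2 <- outer(rowSums(x$values^2), rowSums(mu^2), `+`) -
    2 * x$values %*% t(mu)
  pred <- max.col(-d2)
  expect_gte(mean(pred == lab$labels), 0.999)
})

test_that("rendered frames carry exact boxes and instrument-free phases", {
  spec <- synthetic_spec(n_phases = 3, feature_dim = 4, image_size = 64,
                         duration_range = matrix(2L, 3, 2),
                         rare_phases = integer(0), confusable_pairs = list(),
                         instrument_free_phases = 2L)
  lab <- phase_labels(rep(1:3, each = 2), n_classes = 3)
  set.seed(21)
  rf <- render_frames(lab, spec)
  expect_identical(length(rf$frames), 6L)
  # the pupil box tightly bounds the drawn disk
  pup <- rf$detections[rf$detections$object_class == "pupil", ][1, ]
  r <- round(64 * 0.22)
  expect_equal(unlist(pup[c("x1", "y1", "x2", "y2")]),
               c(x1 = 32 - r, y1 = 32 - r, x2 = 32 + r, y2 = 32 + r))
  # instrument-free phases emit no instrument rows
  inst <- rf$detections[rf$detections$object_class == "instrument", ]
  expect_false(any(inst$frame_index %in% c(2, 3)))
  expect_true(all(inst$frame_index %in% c(0, 1, 4, 5)))
  # instrument boxes tightly bound the drawn glyph
  i1 <- inst[1, ]
  fr <- rf$frames[[i1$frame_index + 1]]
  glyph_cols <- (i1$x1 + 1):i1$x2
  glyph_rows <- (i1$y1 + 1):i1$y2
  patch <- fr[glyph_rows, glyph_cols, 1]
  expect_identical(length(unique(as.vector(patch))), 1L)
  # seeded determinism: identical frames and tables
  set.seed(21)
  rf2 <- render_frames(lab, spec)
  expect_identical(rf$frames, rf2$frames)
  expect_identical(rf$detections, rf2$detections)
})

test_that("dataset generation splits videos and keeps a consistent manifest", {
  spec <- synthetic_spec(n_phases = 4, feature_dim = 6,
                         duration_range = matrix(rep(c(3L, 6L), each = 4), 4, 2),
                         rare_phases = integer(0), confusable_pairs = list())
  ds <- generate_dataset(spec, 32, c(22 / 32, 4 / 32, 6 / 32), seed = 4)
  expect_identical(lengths(ds[c("train", "val", "test")]),
                   c(train = 22L, val = 4L, test = 6L))
  # per-phase counts in the manifest sum to the video length
  for (mv in ds$manifest$videos)
    expect_identical(sum(mv$phase_counts), mv$n_frames)
  # features and labels agree in length
  for (v in ds$train)
    expect_identical(nrow(v$features$values), length(v$labels$labels))
  # same seed: identical dataset; different seed: different labels,
  # identical split sizes
  ds2 <- generate_dataset(spec, 32, c(22 / 32, 4 / 32, 6 / 32), seed = 4)
  expect_identical(ds2$train[[1]]$features$values, ds$train[[1]]$features$values)
  ds3 <- generate_dataset(spec, 32, c(22 / 32, 4 / 32, 6 / 32), seed = 5)
  expect_identical(lengths(ds3[c("train", "val", "test")]),
                   lengths(ds[c("train", "val", "test")]))
  expect_false(identical(ds3$train[[1]]$labels$labels,
                         ds$train[[1]]$labels$labels))
  expect_error(generate_dataset(spec, 2, c(0.5, 0.25, 0.25)), "too small")
})

test_that("a configured rare phase hits its expected frame share", {
  dr <- matrix(rep(c(40L, 80L), each = 5), 5, 2)
  dr[2, ] <- c(8L, 18L)
  spec <- synthetic_spec(n_phases = 5, feature_dim = 8, duration_range = dr,
                         rare_phases = 2L, confusable_pairs = list())
  expected_share <- 13 / (4 * 60 + 13)
  set.seed(31)
  labs <- unlist(replicate(50, sample_phase_sequence(spec)$labels))
  expect_lt(abs(mean(labs == 2) - expected_share), 0.02)
})
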