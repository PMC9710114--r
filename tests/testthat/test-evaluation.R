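test_that("confusion counts match hand enumeration", {
  cc <- confusion_counts(c(1, 2, 2, 2), c(1, 1, 2, 2), n_classes = 2)
  expect_equal(cc$tp, c(1, 2))
  expect_equal(cc$fn, c(1, 0))
  expect_equal(cc$fp, c(0, 1))
  expect_equal(cc$tn, c(2, 1))
  # per class, the four counts always partition the frames
  expect_true(all(cc$tp + cc$tn + cc$fp + cc$fn == attr(cc, "n_frames")))
  # perfect prediction has no false positives or negatives
  y <- rep(1:3, each = 10)
  cc2 <- confusion_counts(y, y)
  expect_true(all(cc2$fp == 0) && all(cc2$fn == 0))
  # single correct frame: TP for its class, TN elsewhere
  cc3 <- confusion_counts(2, 2, n_classes = 4)
  expect_equal(cc3$tp, c(0, 1, 0, 0))
  expect_equal(cc3$tn, c(1, 0, 1, 1))
  expect_error(confusion_counts(1:3, 1:4), "lengths differ")
})

test_that("phase metrics reproduce hand-derived values", {
  y <- rep(1:3, each = 10)
  m <- phase_metrics(confusion_counts(y, y))
  expect_equal(m$accuracy, 1)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 1)
  expect_equal(m$jaccard, 1)
  # two classes, both with TP 4, FP 1, FN 1 over 10 frames
  truth <- c(1, 1, 1, 1, 2, 2, 2, 2, 1, 2)
  pred <- c(1, 1, 1, 1, 2, 2, 2, 2, 2, 1)
  m2 <- phase_metrics(confusion_counts(pred, truth))
  expect_equal(m2$precision, 0.8)
  expect_equal(m2$recall, 0.8)
  expect_equal(m2$jaccard, 4 / 6)
  expect_equal(m2$accuracy, 0.8)
  # constant prediction on balanced truth: accuracy 0.5, macro recall 0.5
  m3 <- phase_metrics(confusion_counts(rep(1, 10), rep(1:2, each = 5)))
  expect_equal(m3$accuracy, 0.5)
  expect_equal(m3$recall, 0.5)
  # class 2 never predicted: its precision denominator is zero and skipped
  expect_equal(m3$precision, 0.5)
  expect_identical(m3$n_skipped, 1L)
})

test_that("metrics lie in [0,1] with jaccard below precision and recall", {
  set.seed(17)
  for (i in 1:30) {
    C <- sample(2:6, 1); Tn <- sample(5:60, 1)
    truth <- sample(C, Tn, replace = TRUE)
    pred <- sample(C, Tn, replace = TRUE)
    m <- phase_metrics(confusion_counts(pred, truth, n_classes = C))
    for (v in c(m$accuracy, m$precision, m$recall, m$jaccard)) {
      expect_gte(v, 0); expect_lte(v, 1)
    }
    pc <- m$per_class
    ok <- !is.na(pc$jaccard) & !is.na(pc$precision) & !is.na(pc$recall)
    expect_true(all(pc$jaccard[ok] <= pmin(pc$precision[ok], pc$recall[ok]) + 1e-12))
  }
})

test_that("relabeling permutes per-class metrics and fixes macro metrics", {
  set.seed(23)
  truth <- sample(4, 80, replace = TRUE)
  pred <- ifelse(runif(80) < 0.3, sample(4, 80, replace = TRUE), truth)
  m <- phase_metrics(confusion_counts(pred, truth, n_classes = 4))
  perm <- c(3, 1, 4, 2)
  m2 <- phase_metrics(confusion_counts(perm[pred], perm[truth], n_classes = 4))
  expect_equal(m2$accuracy, m$accuracy)
  expect_equal(m2$precision, m$precision)
  expect_equal(m2$jaccard, m$jaccard)
  expect_equal(m2$per_class$recall[perm], m$per_class$recall)
})

test_that("phase metrics agree with an independent reference implementation", {
  skip_if_not_installed("caret")
  set.seed(41)
  for (i in 1:100) {
    C <- sample(2:5, 1); Tn <- sample(10:50, 1)
    truth <- sample(C, Tn, replace = TRUE)
    pred <- sample(C, Tn, replace = TRUE)
    cc <- confusion_counts(pred, truth, n_classes = C)
    m <- phase_metrics(cc)
    cm <- caret::confusionMatrix(factor(pred, levels = 1:C),
                                 factor(truth, levels = 1:C))
    expect_equal(m$accuracy, unname(cm$overall["Accuracy"]))
    # caret collapses the two-class case to positive-class statistics
    prec_ref <- if (C == 2) c(cm$byClass["Pos Pred Value"],
                              cm$byClass["Neg Pred Value"])
    else cm$byClass[, "Pos Pred Value"]
    rec_ref <- if (C == 2) c(cm$byClass["Sensitivity"],
                             cm$byClass["Specificity"])
    else cm$byClass[, "Sensitivity"]
    pc <- m$per_class
    ok <- !is.na(pc$precision) & !is.na(prec_ref)
    expect_equal(unname(pc$precision[ok]), unname(prec_ref[ok]),
                 tolerance = 1e-12)
    ok <- !is.na(pc$recall) & !is.na(rec_ref)
    expect_equal(unname(pc$recall[ok]), unname(rec_ref[ok]),
                 tolerance = 1e-12)
  }
})

test_that("segment extraction and expansion round-trip", {
  s <- segments_and_transitions(c(1, 1, 1))
  expect_equal(s$segments, data.frame(phase = 1, start = 0, end = 3))
  expect_identical(nrow(s$transitions), 0L)
  s2 <- segments_and_transitions(c(1, 1, 2, 2, 2, 3))
  expect_equal(s2$segments$phase, c(1, 2, 3))
  expect_equal(s2$segments$start, c(0, 2, 5))
  expect_equal(s2$segments$end, c(2, 5, 6))
  expect_equal(s2$transitions$frame, c(2, 5))
  s3 <- segments_and_transitions(c(1, 2, 1, 2))
  expect_identical(nrow(s3$segments), 4L)
  expect_identical(nrow(s3$transitions), 3L)
  set.seed(2)
  for (i in 1:10) {
    y <- sample(3, 40, replace = TRUE)
    expect_identical(expand_segments(segments_and_transitions(y)),
                     as.integer(y))
  }
})

test_that("transition deviations are in seconds with missing phases reported", {
  truth <- segments_and_transitions(rep(1:3, each = 100))
  expect_equal(transition_deviation(truth, truth, fps = 20)$deviation_s,
               c(0, 0))
  # predicted transition 10 frames late at 20 fps -> 0.5 s
  pred <- segments_and_transitions(rep(1:3, times = c(110, 90, 100)))
  td <- transition_deviation(pred, truth, fps = 20)
  expect_equal(td$deviation_s[1], 0.5)
  # prediction lacking phase 3 reports a missing deviation, not zero
  pred2 <- segments_and_transitions(rep(1:2, times = c(100, 200)))
  td2 <- transition_deviation(pred2, truth, fps = 20)
  expect_true(is.na(td2$deviation_s[td2$to == 3]))
  expect_identical(attr(td2, "summary")$n_missing, 1L)
  expect_error(transition_deviation(pred, truth, fps = 0), "positive")
})

test_that("phase ribbon rendering is deterministic with aligned bars", {
  dir <- withr::local_tempdir()
  pred <- rep(1:3, each = 20)
  truth <- rep(c(1, 2, 3), times = c(25, 15, 20))
  f1 <- file.path(dir, "a.png"); f2 <- file.path(dir, "b.png")
  render_ribbon(list(pred = pred, truth = truth), f1)
  render_ribbon(list(pred = pred, truth = truth), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # constant sequence renders one solid color
  f3 <- file.path(dir, "c.png")
  render_ribbon(list(only = rep(2, 30)), f3)
  img <- png::readPNG(f3)
  expect_identical(length(unique(as.vector(img[, , 1]))), 1L)
  expect_error(render_ribbon(list(a = 1:5, b = 1:6), file.path(dir, "d.png")),
               "mixed lengths")
})
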