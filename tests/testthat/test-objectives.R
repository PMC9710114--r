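test_that("median frequency balancing reproduces hand-derived weights", {
  expect_equal(median_frequency_weights(c(100, 100, 100))$omega, c(1, 1, 1))
  # freqs (0.2, 0.8), median 0.5 (mean of the two middle values)
  expect_equal(median_frequency_weights(c(10, 40))$omega, c(2.5, 0.625))
  # freqs (0.5, 0.25, 0.25), median 0.25
  expect_equal(median_frequency_weights(c(50, 25, 25))$omega, c(0.5, 1, 1))
  # zero-count classes get weight 0 and are excluded from the median
  w <- median_frequency_weights(c(50, 25, 25, 0))
  expect_equal(w$omega, c(0.5, 1, 1, 0))
  expect_error(median_frequency_weights(c(0, 0)), "zero")
})

test_that("median frequency weights are permutation- and scale-equivariant", {
  set.seed(12)
  for (i in 1:10) {
    counts <- sample(1:500, 7)
    w <- median_frequency_weights(counts)$omega
    perm <- sample(7)
    expect_equal(median_frequency_weights(counts[perm])$omega, w[perm])
    expect_equal(median_frequency_weights(counts * 13)$omega, w)
  }
  # weight of the median-frequency class is 1 (odd class count)
  counts <- c(10, 20, 40)
  w <- median_frequency_weights(counts)$omega
  expect_equal(w[2], 1)
})

test_that("weighted cross-entropy reproduces hand-derived values", {
  # perfect prediction has zero loss whatever the weights
  p <- diag(3)[c(1, 2, 3), ]
  expect_equal(weighted_cross_entropy(p, 1:3, c(5, 2, 9))$total, 0)
  # one frame, true-class probability e^-1, unit weight -> loss 1
  q <- matrix(c(exp(-1), 1 - exp(-1)), 1, 2)
  expect_equal(weighted_cross_entropy(q, 1L)$total, 1)
  # two frames at prob 0.5 with weight 2 -> 2 log 2
  r <- matrix(0.5, 2, 2)
  expect_equal(weighted_cross_entropy(r, c(1, 2), c(2, 2))$total, 2 * log(2))
  expect_error(weighted_cross_entropy(r, c(1, 2, 1)), "mismatch")
  expect_error(weighted_cross_entropy(r, c(1, 2), c(1, 2, 3)), "length")
})

test_that("unit-weight cross-entropy equals an independent naive implementation", {
  set.seed(31)
  for (i in 1:20) {
    N <- sample(2:40, 1); C <- sample(2:6, 1)
    p <- matrix(stats::rgamma(N * C, 1), N, C)
    p <- p / rowSums(p)
    y <- sample(C, N, replace = TRUE)
    expect_equal(weighted_cross_entropy(p, y)$total,
                 oracle_cross_entropy(p, y), tolerance = 1e-12)
  }
})

test_that("multi-stage loss is the stage mean and permutation invariant", {
  set.seed(8)
  p1 <- matrix(stats::rgamma(12, 1), 4, 3); p1 <- p1 / rowSums(p1)
  p2 <- matrix(stats::rgamma(12, 1), 4, 3); p2 <- p2 / rowSums(p2)
  y <- c(1, 3, 2, 1)
  l1 <- weighted_cross_entropy(p1, y)$total
  l2 <- weighted_cross_entropy(p2, y)$total
  ms <- multistage_loss(list(p1, p2), y)
  expect_equal(ms$total, mean(c(l1, l2)))
  expect_equal(ms$per_stage, c(l1, l2))
  expect_equal(multistage_loss(list(p2, p1), y)$total, ms$total)
  # identical stages: total equals the single-stage loss
  expect_equal(multistage_loss(list(p1, p1), y)$total, l1)
  # M = 1 reduces exactly to the weighted cross-entropy
  expect_equal(multistage_loss(list(p1), y)$total, l1)
  expect_error(multistage_loss(list(), y), "non-empty")
})

test_that("poly learning-rate decay reproduces its closed form", {
  expect_equal(poly_lr(0, 5e-4, 1000), 5e-4)
  expect_equal(poly_lr(1000, 5e-4, 1000), 0)
  expect_equal(poly_lr(500, 5e-4, 1000, 0.9), 5e-4 * 0.5^0.9)
  expect_equal(poly_lr(500, 5e-4, 1000, 0.9), 2.680e-4, tolerance = 1e-3)
  expect_warning(lr <- poly_lr(1001, 5e-4, 1000), "clamped")
  expect_equal(lr, 0)
  # monotone non-increasing in iter for positive power
  lrs <- vapply(0:100, poly_lr, numeric(1), init_lr = 1e-3,
                total_iters = 100, power = 0.9)
  expect_true(all(diff(lrs) <= 0))
})

test_that("larger class weight strictly increases the misclassified-frame gradient", {
  # numeric derivative of the loss in the true-class probability direction
  p <- matrix(c(0.2, 0.8), 1, 2)  # frame of class 1, misclassified
  grad_mag <- function(w) {
    eps <- 1e-6
    pp <- matrix(c(0.2 + eps, 0.8 - eps), 1, 2)
    pm <- matrix(c(0.2 - eps, 0.8 + eps), 1, 2)
    abs(weighted_cross_entropy(pp, 1L, c(w, 1))$total -
          weighted_cross_entropy(pm, 1L, c(w, 1))$total) / (2 * eps)
  }
  mags <- vapply(c(0.5, 1, 2, 4), grad_mag, numeric(1))
  expect_true(all(diff(mags) > 0))
})

test_that("class weights survive a JSON round trip", {
  w <- median_frequency_weights(c(30, 5, 65))
  path <- withr::local_tempfile(fileext = ".json")
  write_class_weights(w, path)
  w2 <- read_class_weights(path)
  expect_equal(w2$omega, w$omega)
  expect_equal(w2$source_counts, w$source_counts)
})
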