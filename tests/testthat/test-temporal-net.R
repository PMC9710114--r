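test_that("causal dilated convolution matches hand-derived and brute-force values", {
  # kernel of ones, dilation 2: y_t = x_{t-4} + x_{t-2} + x_t with zero padding
  w <- array(1, c(3, 1, 1))
  expect_equal(drop(causal_dilated_conv(matrix(1:5), w, dilation = 2)),
               c(1, 2, 4, 6, 9))
  # zero weights give the zero map
  w0 <- array(0, c(3, 2, 4))
  x <- matrix(rnorm(20), 10, 2)
  expect_equal(causal_dilated_conv(x, w0), matrix(0, 10, 4))
  # random instances against the direct-summation oracle, both paddings
  set.seed(101)
  for (i in 1:25) {
    Tn <- sample(3:32, 1); Cin <- sample(1:4, 1); Cout <- sample(1:4, 1)
    d <- sample(c(1L, 2L, 4L), 1)
    causal <- i %% 2 == 0
    x <- matrix(rnorm(Tn * Cin), Tn, Cin)
    W <- array(rnorm(3 * Cin * Cout), c(3, Cin, Cout))
    b <- rnorm(Cout)
    got <- causal_dilated_conv(x, W, b, dilation = d, causal = causal)
    want <- oracle_dilated_conv(x, W, b, d, causal = causal)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("causal convolution ignores the future exactly", {
  set.seed(7)
  x <- matrix(rnorm(100), 50, 2)
  W <- array(rnorm(3 * 2 * 3), c(3, 2, 3))
  base <- causal_dilated_conv(x, W, dilation = 4)
  x2 <- x
  x2[50, ] <- x2[50, ] + 100
  pert <- causal_dilated_conv(x2, W, dilation = 4)
  expect_identical(pert[1:49, ], base[1:49, ])
})

test_that("convolution argument validation", {
  x <- matrix(1:4, 4, 1)
  w_even <- array(1, c(2, 1, 1))
  expect_error(causal_dilated_conv(x, w_even, causal = FALSE), "odd")
  expect_error(causal_dilated_conv(x, array(1, c(3, 1, 1)), dilation = 0),
               ">= 1")
  expect_error(causal_dilated_conv(x, array(1, c(3, 2, 1))), "channels")
})

test_that("dual dilated layer uses opposing exponential dilation schedules", {
  expect_identical(dilation_schedule(1, 9, "dual"), c(1L, 256L))
  expect_identical(dilation_schedule(9, 9, "dual"), c(256L, 1L))
  expect_identical(dilation_schedule(5, 9, "dual"), c(16L, 16L))
  expect_identical(dilation_schedule(3, 9, "single"), 4L)
})

test_that("zero-weight dual layer is the identity on its residual path", {
  set.seed(3)
  p <- dual_layer_params(4)
  p <- rapply(p, function(x) x * 0, how = "replace")
  p$ln$gamma <- rep(1, 4)
  x <- matrix(rnorm(40), 10, 4)
  out <- dual_dilated_layer(x, p, layer_index = 2, n_layers = 4)
  expect_equal(out$d_out, x)
  expect_equal(out$q_d1, matrix(0, 10, 4))
  # channel mismatch is rejected
  expect_error(dual_dilated_layer(matrix(0, 10, 3), dual_layer_params(4), 1, 4),
               "channel mismatch")
})

test_that("dual layer activations all preserve temporal length", {
  set.seed(11)
  p <- dual_layer_params(6)
  x <- matrix(rnorm(17 * 6), 17, 6)
  act <- dual_dilated_layer(x, p, layer_index = 1, n_layers = 5)
  for (nm in c("q_d1", "q_d2", "q", "d_out"))
    expect_identical(nrow(act[[nm]]), 17L)
})

test_that("stage forward has the shape contract and zero-weight passthrough", {
  set.seed(5)
  st <- tcn_stage(in_dim = 64, channels = 32, n_layers = 9, kind = "dual")
  x <- matrix(rnorm(100 * 64), 100, 64)
  expect_identical(dim(stage_forward(st, x)), c(100L, 32L))
  # zeroing the layer weights (keeping the input projection) makes the
  # residual chain pass the projection through unchanged
  st2 <- tcn_stage(in_dim = 5, channels = 4, n_layers = 3, kind = "single")
  st2$params$layers <- rapply(st2$params$layers, function(x) x * 0,
                              how = "replace")
  for (i in 1:3) st2$params$layers[[i]]$ln$gamma <- rep(1, 4)
  x <- matrix(rnorm(60), 12, 5)
  proj <- causal_dilated_conv(x, array(st2$params$proj$W, c(1, 5, 4)),
                              st2$params$proj$b)
  expect_equal(stage_forward(st2, x), proj)
})

test_that("analytic receptive field matches closed forms", {
  expect_identical(receptive_field(list(n_layers = 9, kernel_size = 3,
                                        kind = "single")), 1023L)
  expect_identical(receptive_field(list(n_layers = 9, kernel_size = 3,
                                        kind = "dual")), 1953L)
  expect_identical(receptive_field(list(n_layers = 1, kernel_size = 1,
                                        kind = "single")), 1L)
  expect_identical(receptive_field(list(n_layers = 4, kernel_size = 3,
                                        kind = "single")), 31L)
})

test_that("measured receptive field equals the analytic formula", {
  set.seed(21)
  for (kind in c("single", "dual")) {
    for (N in 1:3) {
      st <- tcn_stage(in_dim = 2, channels = 3, n_layers = N, kind = kind)
      rf <- receptive_field(st)
      expect_identical(measure_receptive_field(st, rf + 5L), rf)
    }
  }
})

test_that("model forward: shapes, degenerate length, determinism, causality", {
  set.seed(9)
  m <- mstcn(in_dim = 6, n_classes = 4, n_layers = 3, channels = 8, seed = 2)
  # T = 1 video is valid and each stage emits one probability vector
  p1 <- mstcn_forward(m, matrix(rnorm(6), 1, 6))
  for (s in 1:2) {
    expect_identical(dim(p1$stage_probs[[s]]), c(1L, 4L))
    expect_equal(sum(p1$stage_probs[[s]]), 1, tolerance = 1e-6)
  }
  expect_error(mstcn_forward(m, matrix(numeric(0), 0, 6)), "empty")
  # determinism: identical input twice gives bit-identical logits
  x <- matrix(rnorm(40 * 6), 40, 6)
  a <- mstcn_forward(m, x)
  b <- mstcn_forward(m, x)
  expect_identical(a$stage_logits, b$stage_logits)
  # rows of every stage's probabilities sum to 1
  for (s in 1:2)
    expect_equal(rowSums(a$stage_probs[[s]]), rep(1, 40), tolerance = 1e-6)
  # causal model: noise in the future leaves earlier predictions unchanged
  x2 <- x
  x2[21:40, ] <- rnorm(20 * 6)
  a2 <- mstcn_forward(m, x2)
  expect_identical(a$stage_logits[[2]][1:20, ], a2$stage_logits[[2]][1:20, ])
  # all sequences keep full temporal resolution
  expect_identical(nrow(a$y1_features), 40L)
  expect_identical(nrow(a$y2_features), 40L)
})

test_that("the probability-fed stage-2 ablation keeps the output contract", {
  m <- mstcn(in_dim = 4, n_classes = 3, n_layers = 2, channels = 6,
             stage2_input = "probs", seed = 13)
  out <- mstcn_forward(m, matrix(rnorm(48), 12, 4))
  expect_identical(dim(out$stage_logits[[2]]), c(12L, 3L))
  expect_equal(rowSums(out$stage_probs[[2]]), rep(1, 12), tolerance = 1e-6)
})

test_that("argmax prediction breaks ties toward the lowest class index", {
  m <- mstcn(in_dim = 2, n_classes = 3, n_layers = 1, channels = 2, seed = 4)
  # zero the final head so all logits tie
  m$params$head2$W[] <- 0
  m$params$head2$b[] <- 0
  pr <- predict(m, matrix(rnorm(10), 5, 2))
  expect_identical(pr$labels$labels, rep(1L, 5))
})
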