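# Residual multi-stage temporal convolutional network (MSTCN).
#
# Stage 1 stacks N dual dilated layers: two parallel dilated convolutions
# with opposing exponential dilation schedules (2^(n-1) growing, 2^(N-n)
# shrinking) fused by a 1x1 convolution, layer normalization and ReLU, with
# a residual connection.  Stage 2 stacks N single dilated layers with the
# growing schedule only.  All convolutions preserve temporal length; causal
# mode restricts every output frame to past context so the network can run
# online.  Forward passes store the intermediates needed by the
# hand-derived backward passes used for training.

#' Dilation schedule of a stage
#'
#' @param n layer index in `1..n_layers`.
#' @param n_layers number of layers `N` in the stage.
#' @param kind `"dual"` (two opposing schedules) or `"single"`.
#' @return integer vector of dilations used by layer `n`: length 2 for dual
#'   layers (`2^(n-1)` and `2^(N-n)`), length 1 for single layers.
#' @export
dilation_schedule <- function(n, n_layers, kind = c("dual", "single")) {
  kind <- match.arg(kind)
  stopifnot(n >= 1, n <= n_layers)
  if (kind == "dual") as.integer(c(2^(n - 1), 2^(n_layers - n)))
  else as.integer(2^(n - 1))
}

#' Parameters of one dual dilated layer
#'
#' Allocates He-uniform initialized weights for the two parallel dilated
#' convolutions, the 1x1 fusion convolution, the layer norm, and the 1x1
#' residual-branch convolution.
#'
#' @param channels feature width of the stage.
#' @param kernel_size taps per dilated convolution (default 3).
#' @return named list of parameter tensors.
#' @export
dual_layer_params <- function(channels, kernel_size = 3L) {
  list(d1 = conv1d_params(kernel_size, channels, channels),
       d2 = conv1d_params(kernel_size, channels, channels),
       fuse = conv1d_params(1L, 2L * channels, channels),
       ln = layernorm_params(channels),
       res = conv1d_params(1L, channels, channels))
}

single_layer_params <- function(channels, kernel_size = 3L) {
  list(conv = conv1d_params(kernel_size, channels, channels),
       ln = layernorm_params(channels),
       res = conv1d_params(1L, channels, channels))
}

dual_layer_forward <- function(x, p, n, n_layers, causal) {
  dil <- dilation_schedule(n, n_layers, "dual")
  c1 <- conv1d_forward(x, p$d1, dil[1], causal)
  c2 <- conv1d_forward(x, p$d2, dil[2], causal)
  cf <- conv1d_forward(cbind(c1$out, c2$out), p$fuse, 1L, causal)
  ln <- layernorm_forward(cf$out, p$ln$gamma, p$ln$beta)
  q <- relu(ln$out)
  cr <- conv1d_forward(q, p$res, 1L, causal)
  list(out = x + cr$out,
       cache = list(c1 = c1, c2 = c2, cf = cf, ln = ln, mask = ln$out > 0,
                    cr = cr, q_d1 = c1$out, q_d2 = c2$out, q = q))
}

dual_layer_backward <- function(cache, p, dOut) {
  ch <- length(p$ln$gamma)
  br <- conv1d_backward(cache$cr, p$res, dOut)
  dq <- br$dX * cache$mask
  bl <- layernorm_backward(cache$ln, p$ln$gamma, dq)
  bf <- conv1d_backward(cache$cf, p$fuse, bl$dX)
  b1 <- conv1d_backward(cache$c1, p$d1, bf$dX[, seq_len(ch), drop = FALSE])
  b2 <- conv1d_backward(cache$c2, p$d2,
                        bf$dX[, ch + seq_len(ch), drop = FALSE])
  list(dX = dOut + b1$dX + b2$dX,
       grads = list(d1 = list(W = b1$dW, b = b1$db),
                    d2 = list(W = b2$dW, b = b2$db),
                    fuse = list(W = bf$dW, b = bf$db),
                    ln = list(gamma = bl$dgamma, beta = bl$dbeta),
                    res = list(W = br$dW, b = br$db)))
}

single_layer_forward <- function(x, p, n, causal) {
  cc <- conv1d_forward(x, p$conv, as.integer(2^(n - 1)), causal)
  ln <- layernorm_forward(cc$out, p$ln$gamma, p$ln$beta)
  q <- relu(ln$out)
  cr <- conv1d_forward(q, p$res, 1L, causal)
  list(out = x + cr$out,
       cache = list(cc = cc, ln = ln, mask = ln$out > 0, cr = cr, q = q))
}

single_layer_backward <- function(cache, p, dOut) {
  br <- conv1d_backward(cache$cr, p$res, dOut)
  dq <- br$dX * cache$mask
  bl <- layernorm_backward(cache$ln, p$ln$gamma, dq)
  bc <- conv1d_backward(cache$cc, p$conv, bl$dX)
  list(dX = dOut + bc$dX,
       grads = list(conv = list(W = bc$dW, b = bc$db),
                    ln = list(gamma = bl$dgamma, beta = bl$dbeta),
                    res = list(W = br$dW, b = br$db)))
}

#' Apply one dual dilated layer
#'
#' Runs the two parallel dilated convolutions of layer `n` (dilations
#' `2^(n-1)` and `2^(N-n)`), fuses them (concat, 1x1 convolution, layer
#' norm, ReLU) and adds the residual branch.
#'
#' @param x numeric matrix `T x channels`, output of the previous layer.
#' @param params parameters from [dual_layer_params()].
#' @param layer_index layer position `n` in `1..n_layers`.
#' @param n_layers stage depth `N`.
#' @param causal use causal (left-only) padding; default `TRUE`.
#' @return list with `q_d1`, `q_d2` (the two dilated convolution outputs),
#'   `q` (fused normalized activation) and `d_out` (residual layer output),
#'   all `T`-row matrices.
#' @export
dual_dilated_layer <- function(x, params, layer_index, n_layers,
                               causal = TRUE) {
  x <- as.matrix(x)
  if (ncol(x) != ncol(params$res$W))
    stop("channel mismatch between input and residual branch")
  fw <- dual_layer_forward(x, params, layer_index, n_layers, causal)
  list(q_d1 = fw$cache$q_d1, q_d2 = fw$cache$q_d2, q = fw$cache$q,
       d_out = fw$out)
}

# ---- stages -----------------------------------------------------------------

#' Construct a temporal convolution stage
#'
#' A stage is a 1x1 input projection to `channels` followed by `n_layers`
#' residual dilated layers ("dual" uses the opposing dilation schedules;
#' "single" the growing schedule only).
#'
#' @param in_dim width of the input feature vectors.
#' @param channels internal feature width (default 64).
#' @param n_layers stage depth `N` (default 9).
#' @param kind `"dual"` or `"single"`.
#' @param kernel_size taps per dilated convolution (default 3).
#' @param causal causal padding flag (default `TRUE`).
#' @return object of class `tcn_stage` holding `cfg` and `params`.
#' @export
tcn_stage <- function(in_dim, channels = 64L, n_layers = 9L,
                      kind = c("dual", "single"), kernel_size = 3L,
                      causal = TRUE) {
  kind <- match.arg(kind)
  stopifnot(n_layers >= 1, channels >= 1, kernel_size >= 1)
  mk <- if (kind == "dual") dual_layer_params else single_layer_params
  params <- list(proj = conv1d_params(1L, in_dim, channels),
                 layers = lapply(seq_len(n_layers),
                                 function(i) mk(channels, kernel_size)))
  structure(list(cfg = list(in_dim = in_dim, channels = channels,
                            n_layers = n_layers, kind = kind,
                            kernel_size = kernel_size, causal = causal),
                 params = params),
            class = "tcn_stage")
}

stage_fwd <- function(x, params, cfg) {
  pr <- conv1d_forward(x, params$proj, 1L, cfg$causal)
  h <- pr$out
  caches <- vector("list", cfg$n_layers)
  for (n in seq_len(cfg$n_layers)) {
    fw <- if (cfg$kind == "dual")
      dual_layer_forward(h, params$layers[[n]], n, cfg$n_layers, cfg$causal)
    else single_layer_forward(h, params$layers[[n]], n, cfg$causal)
    h <- fw$out
    caches[[n]] <- fw$cache
  }
  list(out = h, proj = pr, layers = caches)
}

stage_bwd <- function(cache, params, cfg, dOut) {
  gl <- vector("list", cfg$n_layers)
  d <- dOut
  for (n in rev(seq_len(cfg$n_layers))) {
    bw <- if (cfg$kind == "dual")
      dual_layer_backward(cache$layers[[n]], params$layers[[n]], d)
    else single_layer_backward(cache$layers[[n]], params$layers[[n]], d)
    gl[[n]] <- bw$grads
    d <- bw$dX
  }
  bp <- conv1d_backward(cache$proj, params$proj, d)
  list(dX = bp$dX,
       grads = list(proj = list(W = bp$dW, b = bp$db), layers = gl))
}

#' Run a stage over a feature sequence
#'
#' @param stage a [tcn_stage()] object.
#' @param x numeric matrix `T x in_dim` (or a [frame_features] object).
#' @return numeric matrix `T x channels`.
#' @export
stage_forward <- function(stage, x) {
  stopifnot(inherits(stage, "tcn_stage"))
  if (inherits(x, "frame_features")) x <- x$values
  x <- as.matrix(x)
  if (ncol(x) != stage$cfg$in_dim) stop("input width mismatch")
  stage_fwd(x, stage$params, stage$cfg)$out
}

# ---- full model -------------------------------------------------------------

#' Construct a multi-stage temporal convolutional phase-recognition model
#'
#' Stage 1 (dual dilated layers) maps the per-frame feature sequence `X` to
#' features `Y1`; a 1x1 classifier head on `Y1` provides the stage-1
#' prediction used by the multi-stage loss.  Stage 2 (single dilated
#' layers) consumes `Y1` and produces `Y2`, which is concatenated with `X`
#' and reduced by a 1x1 convolution before the stage-2 (final) classifier
#' head.  With `causal = TRUE` (default) every prediction depends only on
#' current and past frames.
#'
#' @param in_dim width `D` of the per-frame input feature vectors.
#' @param n_classes number of phases `C`.
#' @param n_layers layers per stage `N` (default 9).
#' @param channels internal feature width (default 64).
#' @param kernel_size taps per dilated convolution (default 3).
#' @param causal causal padding flag (default `TRUE`).
#' @param stage2_input `"features"` feeds `Y1` to stage 2 (default);
#'   `"probs"` feeds the stage-1 softmax instead (ablation).
#' @param seed optional integer seed for parameter initialization.
#' @return object of class `mstcn`.
#' @examples
#' m <- mstcn(in_dim = 8, n_classes = 4, n_layers = 3, channels = 8, seed = 1)
#' p <- mstcn_forward(m, matrix(rnorm(160), 20, 8))
#' dim(p$stage_probs[[2]])
#' @export
mstcn <- function(in_dim, n_classes, n_layers = 9L, channels = 64L,
                  kernel_size = 3L, causal = TRUE,
                  stage2_input = c("features", "probs"), seed = NULL) {
  stage2_input <- match.arg(stage2_input)
  stopifnot(in_dim >= 1, n_classes >= 2, n_layers >= 1, channels >= 1)
  if (!is.null(seed)) set.seed(seed)
  s2_in <- if (stage2_input == "features") channels else n_classes
  params <- list(
    s1 = tcn_stage(in_dim, channels, n_layers, "dual", kernel_size,
                   causal)$params,
    head1 = conv1d_params(1L, channels, n_classes),
    s2 = tcn_stage(s2_in, channels, n_layers, "single", kernel_size,
                   causal)$params,
    fusion = conv1d_params(1L, in_dim + channels, channels),
    head2 = conv1d_params(1L, channels, n_classes))
  structure(list(
    config = list(in_dim = in_dim, n_classes = n_classes,
                  n_layers = n_layers, channels = channels,
                  kernel_size = kernel_size, causal = causal,
                  stage2_input = stage2_input, n_stages = 2L),
    params = params), class = "mstcn")
}

#' @export
print.mstcn <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<mstcn> %d-class, D=%d, N=%d layers/stage, ",
                     "%d channels, kernel %d, %s\n"),
              cfg$n_classes, cfg$in_dim, cfg$n_layers, cfg$channels,
              cfg$kernel_size, if (cfg$causal) "causal" else "non-causal"))
  invisible(x)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

mstcn_fwd_full <- function(model, x) {
  cfg <- model$config
  p <- model$params
  s1cfg <- list(n_layers = cfg$n_layers, kind = "dual", causal = cfg$causal)
  s2cfg <- list(n_layers = cfg$n_layers, kind = "single", causal = cfg$causal)
  s1 <- stage_fwd(x, p$s1, s1cfg)
  h1 <- conv1d_forward(s1$out, p$head1, 1L, cfg$causal)
  probs1 <- softmax_rows(h1$out)
  y2in <- if (cfg$stage2_input == "features") s1$out else probs1
  s2 <- stage_fwd(y2in, p$s2, s2cfg)
  fus <- conv1d_forward(cbind(x, s2$out), p$fusion, 1L, cfg$causal)
  h2 <- conv1d_forward(fus$out, p$head2, 1L, cfg$causal)
  list(y1 = s1$out, y2 = s2$out, logits1 = h1$out, logits2 = h2$out,
       probs1 = probs1, probs2 = softmax_rows(h2$out),
       cache = list(s1 = s1, h1 = h1, s2 = s2, fus = fus, h2 = h2,
                    s1cfg = s1cfg, s2cfg = s2cfg))
}

# Backward pass given gradients on the two stage-logit matrices; returns a
# gradient tree mirroring model$params.
mstcn_bwd_full <- function(model, fw, dlogits1, dlogits2) {
  cfg <- model$config
  p <- model$params
  ca <- fw$cache
  bh2 <- conv1d_backward(ca$h2, p$head2, dlogits2)
  bfus <- conv1d_backward(ca$fus, p$fusion, bh2$dX)
  dY2 <- bfus$dX[, cfg$in_dim + seq_len(cfg$channels), drop = FALSE]
  bs2 <- stage_bwd(ca$s2, p$s2, ca$s2cfg, dY2)
  bh1 <- conv1d_backward(ca$h1, p$head1, dlogits1)
  if (cfg$stage2_input == "features") {
    dY1 <- bs2$dX + bh1$dX
  } else {
    # route stage-2 input gradient through the stage-1 softmax
    pr <- fw$probs1
    dz <- pr * (bs2$dX - rowSums(bs2$dX * pr))
    bh1b <- conv1d_backward(ca$h1, p$head1, dz)
    dY1 <- bh1$dX + bh1b$dX
    bh1$dW <- bh1$dW + bh1b$dW
    bh1$db <- bh1$db + bh1b$db
  }
  bs1 <- stage_bwd(ca$s1, p$s1, ca$s1cfg, dY1)
  list(s1 = bs1$grads,
       head1 = list(W = bh1$dW, b = bh1$db),
       s2 = bs2$grads,
       fusion = list(W = bfus$dW, b = bfus$db),
       head2 = list(W = bh2$dW, b = bh2$db))
}

#' Forward pass of the multi-stage model
#'
#' @param model an [mstcn()] model.
#' @param x a [frame_features] object or a `T x D` numeric matrix.
#' @return list of class `stage_predictions` with `y1_features`,
#'   `y2_features`, `stage_logits` (list of `T x C` matrices, one per
#'   stage), `stage_probs` (their per-frame softmax) and `n_stages`.
#' @export
mstcn_forward <- function(model, x) {
  stopifnot(inherits(model, "mstcn"))
  if (inherits(x, "frame_features")) x <- x$values
  x <- as.matrix(x)
  if (nrow(x) < 1L) stop("empty sequence")
  if (ncol(x) != model$config$in_dim) stop("input width mismatch")
  fw <- mstcn_fwd_full(model, x)
  structure(list(y1_features = fw$y1, y2_features = fw$y2,
                 stage_logits = list(fw$logits1, fw$logits2),
                 stage_probs = list(fw$probs1, fw$probs2),
                 n_stages = 2L),
            class = "stage_predictions")
}

#' Predict per-frame phases with a trained model
#'
#' Takes the per-frame argmax of the final stage's softmax; ties break to
#' the lowest class index.
#'
#' @param object an [mstcn()] model.
#' @param x a [frame_features] object or `T x D` matrix.
#' @param fps frame rate recorded in the returned labels (taken from `x`
#'   when it is a [frame_features] object).
#' @param ... unused.
#' @return list with `labels` (a [phase_labels]) and `probs` (final-stage
#'   `T x C` probability matrix).
#' @export
predict.mstcn <- function(object, x, fps = NULL, ...) {
  if (inherits(x, "frame_features") && is.null(fps)) fps <- x$fps
  if (is.null(fps)) fps <- 20
  out <- mstcn_forward(object, x)
  pr <- out$stage_probs[[object$config$n_stages]]
  lab <- max.col(pr, ties.method = "first")
  list(labels = phase_labels(lab, n_classes = object$config$n_classes,
                             fps = fps),
       probs = pr)
}

#' Analytic receptive field in frames
#'
#' Number of input frames that can influence one output frame:
#' `1 + sum((kernel_size - 1) * d_l)` over all dilated layers, where `d_l`
#' is `2^(l-1)` for single layers and `max(2^(l-1), 2^(N-l))` for dual
#' layers (the wider of the two parallel branches).  For a full model the
#' sum runs over both stages.
#'
#' @param x an [mstcn()] model, a [tcn_stage()], or a list with
#'   `n_layers`, `kernel_size` and `kind`.
#' @return integer number of frames.
#' @examples
#' receptive_field(list(n_layers = 9, kernel_size = 3, kind = "single"))
#' @export
receptive_field <- function(x) {
  stage_rf_span <- function(n_layers, kernel_size, kind) {
    l <- seq_len(n_layers)
    d <- if (kind == "dual") pmax(2^(l - 1), 2^(n_layers - l)) else 2^(l - 1)
    sum((kernel_size - 1) * d)
  }
  if (inherits(x, "mstcn")) {
    cfg <- x$config
    span <- stage_rf_span(cfg$n_layers, cfg$kernel_size, "dual") +
      stage_rf_span(cfg$n_layers, cfg$kernel_size, "single")
    return(as.integer(1 + span))
  }
  cfg <- if (inherits(x, "tcn_stage")) x$cfg else x
  stopifnot(!is.null(cfg$n_layers), !is.null(cfg$kernel_size),
            !is.null(cfg$kind))
  as.integer(1 + stage_rf_span(cfg$n_layers, cfg$kernel_size, cfg$kind))
}
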