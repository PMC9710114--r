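# Training objectives: median-frequency class balancing, weighted
# cross-entropy (per stage and averaged across stages), the poly
# learning-rate schedule, and the Adam optimizer used by both training
# loops.

#' Median frequency balancing class weights
#'
#' Computes per-class weights `omega_c = median(freq) / freq_c`, where
#' `freq_c` is the share of frames carrying class `c` among classes that
#' occur at all.  The class sitting at the median frequency gets weight 1;
#' rarer phases get proportionally larger weights.  Classes with zero
#' count receive weight 0 and are excluded from the median.
#'
#' @param counts non-negative numeric vector of per-class frame counts
#'   (names preserved); at least one count must be positive.
#' @return object of class `class_weights`: list with `omega` (weights)
#'   and `source_counts`.
#' @examples
#' median_frequency_weights(c(10, 40))$omega  # 2.5, 0.625
#' @export
median_frequency_weights <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) < 1L || any(counts < 0) || anyNA(counts))
    stop("`counts` must be non-negative")
  if (all(counts == 0)) stop("all class counts are zero")
  pos <- counts > 0
  freq <- counts / sum(counts)
  med <- stats::median(freq[pos])
  omega <- numeric(length(counts))
  omega[pos] <- med / freq[pos]
  structure(list(omega = omega, source_counts = counts),
            class = "class_weights")
}

#' Export / import class weights as JSON
#'
#' @param w a `class_weights` object.
#' @param path file path.
#' @return `path` invisibly (write) or a `class_weights` object (read).
#' @export
write_class_weights <- function(w, path) {
  stopifnot(inherits(w, "class_weights"))
  obj <- as.list(stats::setNames(w$omega, seq_along(w$omega)))
  jsonlite::write_json(list(omega = obj,
                            source_counts = as.numeric(w$source_counts)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_class_weights
#' @export
read_class_weights <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ids <- as.integer(names(obj$omega))
  omega <- numeric(length(obj$omega))
  omega[ids] <- as.numeric(obj$omega)
  structure(list(omega = omega, source_counts = obj$source_counts),
            class = "class_weights")
}

LOG_CLAMP <- 1e-12

as_one_hot <- function(labels, n_classes) {
  m <- matrix(0, length(labels), n_classes)
  m[cbind(seq_along(labels), labels)] <- 1
  m
}

#' Class-weighted cross-entropy loss
#'
#' `L = -(1/N) sum_i sum_c omega_c y_ic log(p_ic)` over `N` frames, with
#' probabilities clamped below at `1e-12` before the log.  With all
#' weights 1 this is the ordinary cross-entropy.
#'
#' @param probs `N x C` matrix of predicted probabilities (rows sum to 1).
#' @param labels integer vector of true classes (length `N`) or an `N x C`
#'   one-hot matrix.
#' @param weights a `class_weights` object, a numeric vector of length `C`,
#'   or `NULL` for uniform weights.
#' @return object of class `loss_value`: list with `total`, `per_stage`
#'   (length 1 here) and `kind = "frontend"`.
#' @examples
#' p <- matrix(c(0.5, 0.5, 0.5, 0.5), 2, 2)
#' weighted_cross_entropy(p, c(1, 2))$total  # log(2)
#' @export
weighted_cross_entropy <- function(probs, labels, weights = NULL) {
  probs <- as.matrix(probs)
  C <- ncol(probs)
  if (is.matrix(labels)) {
    if (!all(dim(labels) == dim(probs))) stop("labels/probs shape mismatch")
    y <- labels
  } else {
    if (length(labels) != nrow(probs)) stop("labels/probs shape mismatch")
    y <- as_one_hot(as.integer(labels), C)
  }
  omega <- weight_vector(weights, C)
  lp <- log(pmax(probs, LOG_CLAMP))
  total <- -sum(sweep(y * lp, 2, omega, `*`)) / nrow(probs)
  structure(list(total = total, per_stage = total, kind = "frontend"),
            class = "loss_value")
}

weight_vector <- function(weights, n_classes) {
  if (is.null(weights)) return(rep(1, n_classes))
  omega <- if (inherits(weights, "class_weights")) weights$omega
  else as.numeric(weights)
  if (length(omega) != n_classes)
    stop("weights length does not match number of classes")
  omega
}

#' Multi-stage weighted cross-entropy loss
#'
#' Mean of the per-stage weighted cross-entropy losses,
#' `L = (1/M) sum_m L_m`, the training objective of the multi-stage
#' temporal network (both stage heads are supervised).
#'
#' @param stage_probs list over stages of `N x C` probability matrices.
#' @param labels integer vector (length `N`) or one-hot matrix.
#' @param weights shared class weights (see [weighted_cross_entropy()]);
#'   per-stage weights may be given as a list of the same length.
#' @return object of class `loss_value` with `total` (the mean),
#'   `per_stage` and `kind = "multistage"`.
#' @export
multistage_loss <- function(stage_probs, labels, weights = NULL) {
  if (!is.list(stage_probs) || length(stage_probs) < 1L)
    stop("`stage_probs` must be a non-empty list")
  M <- length(stage_probs)
  wlist <- if (is.list(weights) && !inherits(weights, "class_weights"))
    weights else rep(list(weights), M)
  if (length(wlist) != M) stop("one weight set per stage required")
  per <- vapply(seq_len(M), function(m)
    weighted_cross_entropy(stage_probs[[m]], labels, wlist[[m]])$total,
    numeric(1))
  structure(list(total = mean(per), per_stage = per, kind = "multistage"),
            class = "loss_value")
}

#' Poly learning-rate decay
#'
#' `lr = init_lr * (1 - iter / total_iters)^power`; the rate decays from
#' `init_lr` at iteration 0 to exactly 0 at `total_iters`.
#'
#' @param iter current iteration (0-based); values beyond `total_iters`
#'   are clamped to the final rate 0 with a warning.
#' @param init_lr initial learning rate.
#' @param total_iters total number of iterations.
#' @param power decay exponent (default 0.9).
#' @return the learning rate, a non-negative scalar.
#' @examples
#' poly_lr(0, 5e-4, 1000)          # 5e-4
#' poly_lr(500, 5e-4, 1000, 0.9)   # 5e-4 * 0.5^0.9
#' @export
poly_lr <- function(iter, init_lr, total_iters, power = 0.9) {
  stopifnot(init_lr > 0, total_iters > 0, iter >= 0)
  if (iter > total_iters) {
    warning("iter exceeds total_iters; learning rate clamped to 0")
    return(0)
  }
  init_lr * (1 - iter / total_iters)^power
}

# ---- loss gradient and Adam -------------------------------------------------

# gradient of the weighted cross-entropy w.r.t. the logits of one stage,
# already including the 1/N (and optional 1/M) normalization
wce_logit_grad <- function(probs, labels, omega, scale = 1) {
  N <- nrow(probs)
  y <- as_one_hot(as.integer(labels), ncol(probs))
  (probs - y) * omega[labels] * (scale / N)
}

# Adam over an arbitrary nested list of numeric arrays.  `state` mirrors
# the parameter tree with `m` and `v` slots per leaf.
adam_init <- function(params) {
  rapply(params, function(p) list(m = p * 0, v = p * 0),
         classes = c("numeric", "array", "matrix"), how = "replace")
}

adam_step <- function(params, grads, state, t, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      weight_decay = 0) {
  step_leaf <- function(p, g, s) {
    if (weight_decay > 0) g <- g + weight_decay * p
    s$m <- beta1 * s$m + (1 - beta1) * g
    s$v <- beta2 * s$v + (1 - beta2) * g * g
    mhat <- s$m / (1 - beta1^t)
    vhat <- s$v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), s = s)
  }
  walk <- function(p, g, s) {
    if (is.list(p)) {
      out <- Map(walk, p, g, s)
      list(p = lapply(out, `[[`, "p"), s = lapply(out, `[[`, "s"))
    } else {
      step_leaf(p, g, s)
    }
  }
  walk(params, grads, state)
}
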