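# 1-D temporal convolution primitives.
#
# Sequences are dense matrices with one row per frame (T x channels).
# Internally a kernel is stored as a (kernel_size * in_channels) x
# out_channels matrix in tap-major row blocks (tap 1 = most-past), the
# layout the compiled kernels consume; the user-facing
# causal_dilated_conv() accepts the natural kernel_size x Cin x Cout
# array and converts.

#' Causal (or symmetric) dilated temporal convolution
#'
#' Applies a dilated 1-D convolution along the time axis of a `T x Cin`
#' sequence at full temporal resolution. In causal mode the output at frame
#' `t` depends only on frames `<= t` (the input is left-padded with
#' `(kernel_size - 1) * dilation` zero frames), which is what permits
#' streaming deployment of the temporal network in the operating room. In
#' non-causal mode the padding is symmetric and the kernel size must be odd.
#'
#' @param x numeric matrix `T x Cin`, one row per frame.
#' @param weights numeric array `kernel_size x Cin x Cout`; tap 1 is the
#'   most-past tap.
#' @param bias numeric vector of length `Cout` (default zeros).
#' @param dilation integer spacing between kernel taps, `>= 1`.
#' @param causal if `TRUE` (default) use left-only zero padding.
#' @return numeric matrix `T x Cout`.
#' @examples
#' w <- array(1, c(3, 1, 1))
#' causal_dilated_conv(matrix(1:5), w, dilation = 2)  # 1 2 4 6 9
#' @export
causal_dilated_conv <- function(x, weights, bias = NULL, dilation = 1L,
                                causal = TRUE) {
  x <- as.matrix(x)
  if (length(dim(weights)) != 3L)
    stop("`weights` must be a 3-d array (kernel_size x Cin x Cout)")
  if (dilation < 1L) stop("`dilation` must be >= 1")
  K <- dim(weights)[1]
  if (dim(weights)[2] != ncol(x))
    stop("weight in_channels do not match input channels")
  if (!causal && K %% 2L == 0L)
    stop("non-causal convolution requires an odd kernel_size")
  if (is.null(bias)) bias <- numeric(dim(weights)[3])
  wf <- flatten_kernel(weights)
  conv1d_fwd_cpp(x, wf, bias, K, as.integer(dilation), causal)
}

# kernel_size x Cin x Cout array -> (K*Cin) x Cout tap-major matrix
flatten_kernel <- function(W) {
  d <- dim(W)
  m <- aperm(W, c(2, 1, 3))
  dim(m) <- c(d[1] * d[2], d[3])
  m
}

# forward keeps the input in the cache; padding is recomputed on the
# backward pass inside the compiled kernel.  The kernel size is implied
# by the flat weight layout: nrow(W) = kernel_size * in_channels.
conv1d_forward <- function(x, p, dilation, causal) {
  K <- nrow(p$W) %/% ncol(x)
  out <- conv1d_fwd_cpp(x, p$W, p$b, K, as.integer(dilation), causal)
  list(out = out, x = x, dilation = as.integer(dilation), causal = causal)
}

conv1d_backward <- function(cache, p, dY) {
  K <- nrow(p$W) %/% ncol(cache$x)
  conv1d_bwd_cpp(cache$x, p$W, dY, K, cache$dilation, cache$causal)
}

# ---- layer normalization (per frame, over channels) -------------------------

LN_EPS <- 1e-5

layernorm_forward <- function(x, gamma, beta) {
  layernorm_fwd_cpp(x, gamma, beta, LN_EPS)
}

layernorm_backward <- function(cache, gamma, dY) {
  layernorm_bwd_cpp(cache$xhat, cache$inv, gamma, dY)
}

relu <- function(x) (x > 0) * x

# ---- parameter construction -------------------------------------------------

# He-uniform initialization: U(-l, l) with l = sqrt(6 / fan_in); weights
# are stored flat (tap-major), with the kernel size alongside
conv1d_params <- function(kernel_size, in_channels, out_channels) {
  limit <- sqrt(6 / (kernel_size * in_channels))
  list(W = matrix(stats::runif(kernel_size * in_channels * out_channels,
                               -limit, limit),
                  kernel_size * in_channels, out_channels),
       b = numeric(out_channels))
}

layernorm_params <- function(channels) {
  list(gamma = rep(1, channels), beta = numeric(channels))
}
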