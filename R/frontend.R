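# Triple-stream per-frame feature frontend: consume frames plus
# pupil/instrument bounding boxes, crop patches, encode the three streams
# (whole frame, pupil patch, instrument patch) with pluggable backbones,
# concatenate into one fine-grained per-frame feature vector, and classify.
#
# Images are numeric arrays H x W x 3 with values in [0, 1]; boxes use
# 0-based half-open pixel coordinates [x1, x2) x [y1, y2).

DETECTION_COLUMNS <- c("video_id", "frame_index", "object_class",
                       "x1", "y1", "x2", "y2", "confidence")

#' Select one detection per frame and object class
#'
#' Clips boxes to the image bounds, drops malformed rows with a warning,
#' and keeps, per `(video_id, frame_index, object_class)`, the
#' highest-confidence box; ties break to the larger area, then to the
#' first occurrence.
#'
#' @param raw data.frame with columns `video_id`, `frame_index`,
#'   `object_class` (`"pupil"` or `"instrument"`), `x1`, `y1`, `x2`, `y2`,
#'   `confidence`.
#' @param width,height image dimensions in pixels used for clipping.
#' @return data.frame with the same columns, at most one row per
#'   `(video_id, frame_index, object_class)`.
#' @export
select_detections <- function(raw, width, height) {
  stopifnot(is.data.frame(raw))
  missing_cols <- setdiff(DETECTION_COLUMNS, names(raw))
  if (length(missing_cols))
    stop("detection table lacks columns: ", paste(missing_cols, collapse = ", "))
  raw <- raw[, DETECTION_COLUMNS]
  if (nrow(raw) == 0L) return(raw)
  raw$x1 <- pmax(0, raw$x1); raw$y1 <- pmax(0, raw$y1)
  raw$x2 <- pmin(width, raw$x2); raw$y2 <- pmin(height, raw$y2)
  bad <- !is.finite(raw$x1) | !is.finite(raw$x2) | !is.finite(raw$y1) |
    !is.finite(raw$y2) | raw$x1 >= raw$x2 | raw$y1 >= raw$y2 |
    !is.finite(raw$confidence) | raw$confidence < 0 | raw$confidence > 1
  if (any(bad)) {
    warning(sum(bad), " malformed detection row(s) rejected")
    raw <- raw[!bad, , drop = FALSE]
  }
  if (nrow(raw) == 0L) return(raw)
  area <- (raw$x2 - raw$x1) * (raw$y2 - raw$y1)
  key <- paste(raw$video_id, raw$frame_index, raw$object_class, sep = "\r")
  ord <- order(key, -raw$confidence, -area, seq_len(nrow(raw)))
  raw <- raw[ord, , drop = FALSE]
  keep <- !duplicated(key[ord])
  out <- raw[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read / write a detection table CSV
#'
#' CSV with the exact header `video_id,frame_index,object_class,x1,y1,x2,
#' y2,confidence`, 0-based frame indices and half-open pixel coordinates.
#'
#' @param path CSV file path.
#' @param det detection data.frame.
#' @return the data.frame (read) or `path` invisibly (write).
#' @export
read_detections <- function(path) {
  det <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(DETECTION_COLUMNS, names(det))
  if (length(missing_cols))
    stop("detection CSV lacks columns: ", paste(missing_cols, collapse = ", "))
  det
}

#' @rdname read_detections
#' @export
write_detections <- function(det, path) {
  utils::write.csv(det[, DETECTION_COLUMNS], path, row.names = FALSE)
  invisible(path)
}

#' Crop a detection patch out of a frame
#'
#' Pixel-exact sub-image `[y1:y2) x [x1:x2)` of the frame, optionally
#' resized to a square stream input size with bilinear interpolation.
#'
#' @param frame numeric array `H x W x 3`.
#' @param box numeric vector `(x1, y1, x2, y2)` in 0-based half-open pixel
#'   coordinates, already clipped to the frame.
#' @param out_size optional side length of the resized square patch.
#' @return numeric array (the patch), or `NULL` for a zero-area box.
#' @export
crop_patch <- function(frame, box, out_size = NULL) {
  box <- as.numeric(box)
  x1 <- floor(box[1]); y1 <- floor(box[2])
  x2 <- ceiling(box[3]); y2 <- ceiling(box[4])
  if (x2 <= x1 || y2 <= y1) return(NULL)
  if (x1 < 0 || y1 < 0 || x2 > dim(frame)[2] || y2 > dim(frame)[1])
    stop("box exceeds frame bounds; clip first")
  patch <- frame[(y1 + 1L):y2, (x1 + 1L):x2, , drop = FALSE]
  if (!is.null(out_size)) patch <- resize_image(patch, out_size, out_size)
  patch
}

# bilinear resize via EBImage (which uses x = column-major image axes)
resize_image <- function(img, out_h, out_w) {
  x <- aperm(img, c(2, 1, 3))
  y <- EBImage::resize(x, w = out_w, h = out_h, filter = "bilinear")
  aperm(as.array(y), c(2, 1, 3))
}

rotate_image <- function(img, angle_deg) {
  x <- aperm(img, c(2, 1, 3))
  y <- EBImage::rotate(x, angle_deg, output.dim = dim(x)[1:2], bg.col = 0)
  aperm(as.array(y), c(2, 1, 3))
}

#' Training-time image augmentation
#'
#' Random square crop followed by resize to the stream input size, then
#' horizontal and vertical flips each with probability 0.5 and a rotation
#' with probability 0.5 by an angle uniform in `[-30, 30]` degrees.
#' Applied only while training the frontend; draws from the current RNG
#' stream.
#'
#' @param img numeric array `H x W x 3`.
#' @param out_size side length of the output square image.
#' @return augmented numeric array `out_size x out_size x 3`.
#' @export
augment_image <- function(img, out_size) {
  H <- dim(img)[1]; W <- dim(img)[2]
  side <- min(H, W)
  side_crop <- max(1L, floor(side * stats::runif(1, 0.8, 1)))
  r0 <- sample.int(H - side_crop + 1L, 1L) - 1L
  c0 <- sample.int(W - side_crop + 1L, 1L) - 1L
  img <- img[r0 + seq_len(side_crop), c0 + seq_len(side_crop), , drop = FALSE]
  img <- resize_image(img, out_size, out_size)
  if (stats::runif(1) < 0.5) img <- img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
  if (stats::runif(1) < 0.5) img <- img[rev(seq_len(dim(img)[1])), , , drop = FALSE]
  if (stats::runif(1) < 0.5)
    img <- rotate_image(img, stats::runif(1, -30, 30))
  img
}

# ---- small convolutional encoder (default stream backbone) ------------------

conv2d_params <- function(kernel, in_ch, out_ch) {
  limit <- sqrt(6 / (kernel * kernel * in_ch))
  list(W = array(stats::runif(kernel^2 * in_ch * out_ch, -limit, limit),
                 dim = c(kernel, kernel, in_ch, out_ch)),
       b = numeric(out_ch))
}

conv2d_forward <- function(x, W, b) {
  K <- dim(W)[1]; Cin <- dim(W)[3]; Cout <- dim(W)[4]
  H <- dim(x)[1]; Wd <- dim(x)[2]
  p <- K %/% 2L
  Xp <- array(0, c(H + 2L * p, Wd + 2L * p, Cin))
  Xp[p + seq_len(H), p + seq_len(Wd), ] <- x
  out <- matrix(rep(b, each = H * Wd), H * Wd, Cout)
  for (ki in seq_len(K)) for (kj in seq_len(K)) {
    sl <- Xp[(ki - 1L) + seq_len(H), (kj - 1L) + seq_len(Wd), , drop = FALSE]
    dim(sl) <- c(H * Wd, Cin)
    out <- out + sl %*% matrix(W[ki, kj, , ], Cin, Cout)
  }
  dim(out) <- c(H, Wd, Cout)
  list(out = out, Xp = Xp, K = K, p = p)
}

conv2d_backward <- function(cache, W, dY) {
  K <- cache$K; p <- cache$p
  H <- dim(dY)[1]; Wd <- dim(dY)[2]
  Cin <- dim(W)[3]; Cout <- dim(W)[4]
  dYm <- dY; dim(dYm) <- c(H * Wd, Cout)
  dW <- array(0, dim(W))
  dXp <- array(0, dim(cache$Xp))
  for (ki in seq_len(K)) for (kj in seq_len(K)) {
    ri <- (ki - 1L) + seq_len(H); cj <- (kj - 1L) + seq_len(Wd)
    sl <- cache$Xp[ri, cj, , drop = FALSE]
    dim(sl) <- c(H * Wd, Cin)
    dW[ki, kj, , ] <- crossprod(sl, dYm)
    dsl <- tcrossprod(dYm, matrix(W[ki, kj, , ], Cin, Cout))
    dim(dsl) <- c(H, Wd, Cin)
    dXp[ri, cj, ] <- dXp[ri, cj, , drop = FALSE] + dsl
  }
  list(dX = dXp[p + seq_len(H), p + seq_len(Wd), , drop = FALSE],
       dW = dW, db = colSums(dYm))
}

meanpool2_forward <- function(x) {
  H <- dim(x)[1]; W <- dim(x)[2]
  o1 <- seq(1L, H, 2L); o2 <- seq(2L, H, 2L)
  c1 <- seq(1L, W, 2L); c2 <- seq(2L, W, 2L)
  (x[o1, c1, , drop = FALSE] + x[o2, c1, , drop = FALSE] +
     x[o1, c2, , drop = FALSE] + x[o2, c2, , drop = FALSE]) / 4
}

meanpool2_backward <- function(dY, in_dim) {
  dX <- array(0, in_dim)
  H <- in_dim[1]; W <- in_dim[2]
  o1 <- seq(1L, H, 2L); o2 <- seq(2L, H, 2L)
  c1 <- seq(1L, W, 2L); c2 <- seq(2L, W, 2L)
  q <- dY / 4
  dX[o1, c1, ] <- q; dX[o2, c1, ] <- q
  dX[o1, c2, ] <- q; dX[o2, c2, ] <- q
  dX
}

#' Small convolutional stream encoder
#'
#' The default desk-scale backbone for each stream: three blocks of 3x3
#' same-padded convolution, ReLU and 2x2 mean pooling, followed by global
#' average pooling and a fully connected layer with ReLU.  Any other
#' backbone can be plugged in by registering an object with the same
#' `encoder_forward()` contract under the stream's config key.
#'
#' @param input_size square input side length in pixels (default 32; must
#'   be divisible by 8).
#' @param channels integer vector of the three block widths
#'   (default `c(8, 16, 32)`).
#' @param out_dim width of the emitted feature vector (default 64).
#' @return object of class `conv_encoder`.
#' @export
conv_encoder <- function(input_size = 32L, channels = c(8L, 16L, 32L),
                         out_dim = 64L) {
  stopifnot(length(channels) == 3L, input_size %% 8L == 0L)
  limit <- sqrt(6 / channels[3])
  params <- list(
    b1 = conv2d_params(3L, 3L, channels[1]),
    b2 = conv2d_params(3L, channels[1], channels[2]),
    b3 = conv2d_params(3L, channels[2], channels[3]),
    fc = list(W = matrix(stats::runif(channels[3] * out_dim, -limit, limit),
                         channels[3], out_dim),
              b = numeric(out_dim)))
  structure(list(params = params,
                 cfg = list(input_size = input_size, channels = channels,
                            out_dim = out_dim)),
            class = "conv_encoder")
}

encoder_fwd_full <- function(enc, img) {
  p <- enc$params
  caches <- list()
  h <- img
  for (bn in c("b1", "b2", "b3")) {
    cv <- conv2d_forward(h, p[[bn]]$W, p[[bn]]$b)
    mask <- cv$out > 0
    r <- cv$out * mask
    pooled <- meanpool2_forward(r)
    caches[[bn]] <- list(cv = cv, mask = mask, r_dim = dim(r),
                         pool_in = dim(r))
    h <- pooled
  }
  sp <- dim(h)
  hm <- h; dim(hm) <- c(sp[1] * sp[2], sp[3])
  g <- colMeans(hm)
  z <- drop(g %*% p$fc$W) + p$fc$b
  f <- pmax(z, 0)
  list(f = f, cache = list(blocks = caches, sp = sp, g = g, z = z))
}

encoder_bwd_full <- function(enc, cache, df) {
  p <- enc$params
  dz <- df * (cache$z > 0)
  dW_fc <- outer(cache$g, dz)
  db_fc <- dz
  dg <- drop(p$fc$W %*% dz)
  sp <- cache$sp
  dh <- array(rep(dg / (sp[1] * sp[2]), each = sp[1] * sp[2]), sp)
  grads <- list()
  for (bn in c("b3", "b2", "b1")) {
    ca <- cache$blocks[[bn]]
    dr <- meanpool2_backward(dh, ca$pool_in)
    dc <- dr * ca$mask
    bw <- conv2d_backward(ca$cv, p[[bn]]$W, dc)
    grads[[bn]] <- list(W = bw$dW, b = bw$db)
    dh <- bw$dX
  }
  list(grads = list(b1 = grads$b1, b2 = grads$b2, b3 = grads$b3,
                    fc = list(W = dW_fc, b = db_fc)))
}

#' Encode one image with a stream backbone
#'
#' @param enc a [conv_encoder()] (or any backbone providing an
#'   `encoder_forward` method and a `cfg$out_dim`).
#' @param img numeric array `input_size x input_size x 3`.
#' @return numeric feature vector of length `out_dim`.
#' @export
encoder_forward <- function(enc, img) UseMethod("encoder_forward")

#' @export
encoder_forward.conv_encoder <- function(enc, img) {
  if (!all(dim(img)[1:2] == enc$cfg$input_size))
    img <- resize_image(img, enc$cfg$input_size, enc$cfg$input_size)
  encoder_fwd_full(enc, img)$f
}

# ---- stream fusion and preliminary classifier -------------------------------

#' Fuse the three stream encodings of one frame
#'
#' Runs the frame image, the pupil patch and the instrument patch through
#' their registered backbones and concatenates the three feature vectors;
#' an absent patch contributes a zero vector.  Two presence flags (pupil,
#' instrument) are appended so that absence is learnable.
#'
#' @param triple list with `frame_image` (required array), `pupil_patch`
#'   and `instrument_patch` (arrays or `NULL`).
#' @param backbones named list with encoders for `frame`, `pupil` and
#'   `instrument`.
#' @return list with `frame_vec`, `pupil_vec`, `instrument_vec`,
#'   `presence` (length-2 0/1 vector) and `fused_vec`.
#' @export
extract_stream_features <- function(triple, backbones) {
  for (nm in c("frame", "pupil", "instrument"))
    if (is.null(backbones[[nm]]))
      stop("no backbone registered for stream: ", nm)
  fvec <- encoder_forward(backbones$frame, triple$frame_image)
  enc_or_zero <- function(enc, patch) {
    if (is.null(patch)) numeric(enc$cfg$out_dim)
    else encoder_forward(enc, patch)
  }
  pvec <- enc_or_zero(backbones$pupil, triple$pupil_patch)
  ivec <- enc_or_zero(backbones$instrument, triple$instrument_patch)
  presence <- c(pupil = as.numeric(!is.null(triple$pupil_patch)),
                instrument = as.numeric(!is.null(triple$instrument_patch)))
  list(frame_vec = fvec, pupil_vec = pvec, instrument_vec = ivec,
       presence = presence,
       fused_vec = c(fvec, pvec, ivec, unname(presence)))
}

#' Preliminary per-frame phase classifier head
#'
#' A single fully connected map from the fused feature vector to `C`
#' logits, used to train the frontend and as a per-frame baseline.
#'
#' @param in_dim fused feature width.
#' @param n_classes number of phases `C`.
#' @return list with `W` (`in_dim x C`) and `b`, class `frontend_head`.
#' @export
frontend_head <- function(in_dim, n_classes) {
  limit <- sqrt(6 / in_dim)
  structure(list(W = matrix(stats::runif(in_dim * n_classes, -limit, limit),
                            in_dim, n_classes),
                 b = numeric(n_classes)),
            class = "frontend_head")
}

#' Classify a fused frame feature vector
#'
#' @param features output of [extract_stream_features()] or a numeric
#'   fused feature vector.
#' @param head a [frontend_head()].
#' @return numeric vector of `C` logits.
#' @export
frontend_classify <- function(features, head) {
  f <- if (is.list(features)) features$fused_vec else as.numeric(features)
  if (length(f) != nrow(head$W))
    stop("fused feature width does not match classifier head")
  drop(f %*% head$W) + head$b
}
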