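# Orchestration: two-phase training (frontend on frames, then the
# temporal network on exported per-frame features), feature export,
# prediction, evaluation reports, and checkpoint/manifest handling.

#' Default experimental configuration
#'
#' Returns the default hyperparameters of the two training phases: the
#' frontend trains with Adam (weight decay 5e-4), batch size 16, up to 50
#' epochs, poly learning-rate decay from 5e-4 with power 0.9 and
#' augmentation on; the temporal network trains with Adam, one whole
#' video per optimization step (batch size 1), up to 200 epochs and poly
#' decay from 2e-4.  Desk-scale runs usually shrink `epochs`, `n_layers`
#' and `channels`.
#'
#' @param ... named overrides of any default.
#' @return named list of configuration values.
#' @export
default_config <- function(...) {
  cfg <- list(
    # frontend
    frontend_epochs = 50L, frontend_lr = 5e-4, frontend_batch = 16L,
    frontend_weight_decay = 5e-4, frontend_power = 0.9,
    stream_width = 64L, input_size = 32L, augment = TRUE,
    # temporal network
    temporal_epochs = 200L, temporal_lr = 2e-4, temporal_power = 0.9,
    n_layers = 9L, channels = 64L, kernel_size = 3L, causal = TRUE,
    stage2_input = "features", temporal_weight_decay = 0,
    # shared
    seed = 1L, fps = 20)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config keys: ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

label_counts <- function(videos, n_classes) {
  counts <- numeric(n_classes)
  for (v in videos) counts <- counts + tabulate(v$labels$labels, n_classes)
  counts
}

frame_accuracy <- function(model, videos) {
  ok <- 0; tot <- 0
  for (v in videos) {
    pr <- predict(model, v$features, fps = v$labels$fps)
    ok <- ok + sum(pr$labels$labels == v$labels$labels)
    tot <- tot + length(v$labels$labels)
  }
  ok / tot
}

#' Train the temporal network on per-frame feature sequences
#'
#' Optimizes the mean of the two stage-wise median-frequency-weighted
#' cross-entropy losses with Adam, one whole video per optimization step,
#' and poly learning-rate decay per step.  When a validation set is given
#' the checkpoint with the best validation frame accuracy is returned.
#'
#' @param train list of videos, each `list(features, labels)` with a
#'   [frame_features] and an aligned [phase_labels].
#' @param val optional validation list in the same shape.
#' @param n_classes number of phases `C`.
#' @param config a [default_config()] list (temporal fields are used).
#' @param class_weights optional `class_weights`; by default computed from
#'   the training labels by [median_frequency_weights()] and shared by
#'   both stages. Pass a vector of ones for unweighted training.
#' @param verbose print one line per few epochs.
#' @return object of class `mstcn_fit`: `model` (selected), `history`
#'   (per-epoch data.frame: `loss`, `loss_s1`, `loss_s2`, `val_accuracy`),
#'   `class_weights`, `config`, `best_epoch`.
#' @export
train_temporal <- function(train, val = NULL, n_classes, config = default_config(),
                           class_weights = NULL, verbose = FALSE) {
  stopifnot(length(train) >= 1L)
  set.seed(config$seed)
  in_dim <- ncol(train[[1]]$features$values)
  model <- mstcn(in_dim, n_classes, n_layers = config$n_layers,
                 channels = config$channels,
                 kernel_size = config$kernel_size, causal = config$causal,
                 stage2_input = config$stage2_input)
  if (is.null(class_weights))
    class_weights <- median_frequency_weights(label_counts(train, n_classes))
  omega <- weight_vector(class_weights, n_classes)
  state <- adam_init(model$params)
  epochs <- config$temporal_epochs
  total_iters <- epochs * length(train)
  it <- 0L
  hist <- data.frame(epoch = seq_len(epochs), loss = NA_real_,
                     loss_s1 = NA_real_, loss_s2 = NA_real_,
                     val_accuracy = NA_real_)
  best <- list(acc = -Inf, params = model$params, epoch = 0L)
  for (ep in seq_len(epochs)) {
    ord <- sample(length(train))
    ep_loss <- c(0, 0)
    for (vi in ord) {
      v <- train[[vi]]
      x <- v$features$values
      y <- v$labels$labels
      fw <- mstcn_fwd_full(model, x)
      d1 <- wce_logit_grad(fw$probs1, y, omega, scale = 1 / 2)
      d2 <- wce_logit_grad(fw$probs2, y, omega, scale = 1 / 2)
      grads <- mstcn_bwd_full(model, fw, d1, d2)
      lr <- poly_lr(it, config$temporal_lr, total_iters,
                    config$temporal_power)
      it <- it + 1L
      upd <- adam_step(model$params, grads, state, it, lr,
                       weight_decay = config$temporal_weight_decay)
      model$params <- upd$p
      state <- upd$s
      ep_loss <- ep_loss +
        c(weighted_cross_entropy(fw$probs1, y, omega)$total,
          weighted_cross_entropy(fw$probs2, y, omega)$total)
    }
    ep_loss <- ep_loss / length(train)
    hist$loss_s1[ep] <- ep_loss[1]
    hist$loss_s2[ep] <- ep_loss[2]
    hist$loss[ep] <- mean(ep_loss)
    if (!is.null(val)) {
      acc <- frame_accuracy(model, val)
      hist$val_accuracy[ep] <- acc
      if (acc > best$acc) best <- list(acc = acc, params = model$params,
                                       epoch = ep)
    }
    if (verbose && (ep %% 10L == 0L || ep == 1L))
      message(sprintf("epoch %3d  loss %.4f  val acc %s", ep, hist$loss[ep],
                      ifelse(is.null(val), "-",
                             sprintf("%.3f", hist$val_accuracy[ep]))))
  }
  if (!is.null(val) && best$epoch > 0L) model$params <- best$params
  structure(list(model = model, history = hist,
                 class_weights = class_weights, config = config,
                 best_epoch = if (is.null(val)) NA_integer_ else best$epoch),
            class = "mstcn_fit")
}

# ---- frontend training ------------------------------------------------------

build_frame_samples <- function(videos, input_size) {
  samples <- list()
  for (v in videos) {
    S <- dim(v$frames[[1]])[1:2]
    det <- select_detections(v$detections, width = S[2], height = S[1])
    for (t in seq_along(v$frames)) {
      frame <- v$frames[[t]]
      drows <- det[det$frame_index == t - 1L, , drop = FALSE]
      get_patch <- function(cls) {
        row <- drows[drows$object_class == cls, , drop = FALSE]
        if (nrow(row) == 0L) return(NULL)
        crop_patch(frame, unlist(row[1, c("x1", "y1", "x2", "y2")]),
                   out_size = input_size)
      }
      samples[[length(samples) + 1L]] <- list(
        frame_image = frame,
        pupil_patch = get_patch("pupil"),
        instrument_patch = get_patch("instrument"),
        label = v$labels$labels[t])
    }
  }
  samples
}

#' Train the triple-stream frontend on rendered frames
#'
#' Trains the three stream encoders and the preliminary classifier head
#' jointly with the median-frequency-weighted cross-entropy, Adam (weight
#' decay 5e-4), poly learning-rate decay and, optionally, the standard
#' augmentation recipe (random square crop + resize, horizontal/vertical
#' flips with probability 0.5, rotation with probability 0.5 uniform in
#' [-30, 30] degrees).
#'
#' @param videos list of rendered videos, each
#'   `list(frames, detections, labels)` as produced by
#'   [generate_dataset()] in `"rendered"` mode.
#' @param n_classes number of phases `C`.
#' @param config a [default_config()] list (frontend fields are used).
#' @param verbose print progress.
#' @return object of class `frontend_fit`: `backbones` (named list of
#'   encoders), `head`, `history` (per-epoch loss and training accuracy),
#'   `class_weights`, `config`.
#' @export
train_frontend <- function(videos, n_classes, config = default_config(),
                           verbose = FALSE) {
  if (any(vapply(videos, function(v) is.null(v$detections), logical(1))))
    stop("rendered videos with detection tables are required")
  set.seed(config$seed)
  isz <- config$input_size
  wd <- config$stream_width
  backbones <- list(frame = conv_encoder(isz, out_dim = wd),
                    pupil = conv_encoder(isz, out_dim = wd),
                    instrument = conv_encoder(isz, out_dim = wd))
  head <- frontend_head(3L * wd + 2L, n_classes)
  samples <- build_frame_samples(videos, isz)
  counts <- tabulate(vapply(samples, `[[`, integer(1), "label"), n_classes)
  cw <- median_frequency_weights(counts)
  omega <- weight_vector(cw, n_classes)
  params <- list(frame = backbones$frame$params,
                 pupil = backbones$pupil$params,
                 instrument = backbones$instrument$params,
                 head = list(W = head$W, b = head$b))
  state <- adam_init(params)
  n <- length(samples)
  batches_per_epoch <- ceiling(n / config$frontend_batch)
  total_iters <- config$frontend_epochs * batches_per_epoch
  it <- 0L
  hist <- data.frame(epoch = seq_len(config$frontend_epochs),
                     loss = NA_real_, train_accuracy = NA_real_)
  zero_like <- function(p) rapply(p, function(x) x * 0, how = "replace")
  for (ep in seq_len(config$frontend_epochs)) {
    ord <- sample(n)
    ep_loss <- 0; ep_ok <- 0
    for (bi in seq_len(batches_per_epoch)) {
      idx <- ord[((bi - 1L) * config$frontend_batch + 1L):
                   min(bi * config$frontend_batch, n)]
      grads <- zero_like(params)
      bloss <- 0
      for (si in idx) {
        s <- samples[[si]]
        prep <- function(img) {
          if (is.null(img)) return(NULL)
          if (config$augment) augment_image(img, isz)
          else resize_image(img, isz, isz)
        }
        imgs <- list(frame = prep(s$frame_image),
                     pupil = prep(s$pupil_patch),
                     instrument = prep(s$instrument_patch))
        fwds <- list()
        vecs <- list()
        for (nm in names(imgs)) {
          if (is.null(imgs[[nm]])) {
            fwds[[nm]] <- NULL
            vecs[[nm]] <- numeric(wd)
          } else {
            enc <- backbones[[nm]]
            enc$params <- params[[nm]]
            fwds[[nm]] <- encoder_fwd_full(enc, imgs[[nm]])
            vecs[[nm]] <- fwds[[nm]]$f
          }
        }
        presence <- c(as.numeric(!is.null(imgs$pupil)),
                      as.numeric(!is.null(imgs$instrument)))
        fvec <- c(vecs$frame, vecs$pupil, vecs$instrument, presence)
        logits <- drop(fvec %*% params$head$W) + params$head$b
        pr <- exp(logits - max(logits))
        pr <- pr / sum(pr)
        bloss <- bloss - omega[s$label] * log(max(pr[s$label], LOG_CLAMP))
        ep_ok <- ep_ok + (which.max(pr) == s$label)
        dlog <- pr
        dlog[s$label] <- dlog[s$label] - 1
        dlog <- dlog * omega[s$label] / length(idx)
        grads$head$W <- grads$head$W + outer(fvec, dlog)
        grads$head$b <- grads$head$b + dlog
        dfvec <- drop(params$head$W %*% dlog)
        off <- 0L
        for (nm in names(imgs)) {
          dseg <- dfvec[off + seq_len(wd)]
          off <- off + wd
          if (!is.null(fwds[[nm]])) {
            enc <- backbones[[nm]]
            enc$params <- params[[nm]]
            bw <- encoder_bwd_full(enc, fwds[[nm]]$cache, dseg)
            grads[[nm]] <- add_trees(grads[[nm]], bw$grads)
          }
        }
      }
      lr <- poly_lr(it, config$frontend_lr, total_iters,
                    config$frontend_power)
      it <- it + 1L
      upd <- adam_step(params, grads, state, it, lr,
                       weight_decay = config$frontend_weight_decay)
      params <- upd$p
      state <- upd$s
      ep_loss <- ep_loss + bloss / length(idx)
    }
    hist$loss[ep] <- ep_loss / batches_per_epoch
    hist$train_accuracy[ep] <- ep_ok / n
    if (verbose)
      message(sprintf("frontend epoch %3d  loss %.4f  acc %.3f",
                      ep, hist$loss[ep], hist$train_accuracy[ep]))
  }
  for (nm in c("frame", "pupil", "instrument"))
    backbones[[nm]]$params <- params[[nm]]
  head$W <- params$head$W
  head$b <- params$head$b
  structure(list(backbones = backbones, head = head, history = hist,
                 class_weights = cw, config = config),
            class = "frontend_fit")
}

add_trees <- function(a, b) {
  if (is.list(a)) Map(add_trees, a, b) else a + b
}

#' Export fused per-frame features for whole videos
#'
#' Runs the trained frontend deterministically (no augmentation) over
#' every frame of each video and stacks the fused vectors into the
#' `T x D` matrix the temporal network consumes.
#'
#' @param fit a [train_frontend()] result.
#' @param videos list of rendered videos (`frames`, `detections`,
#'   optionally `labels`).
#' @param out_dir optional directory; when given, each video is written
#'   via [write_features()] under its `video_id`.
#' @return list of videos with `features` ([frame_features]) and `labels`.
#' @export
export_features <- function(fit, videos, out_dir = NULL) {
  stopifnot(inherits(fit, "frontend_fit"))
  isz <- fit$config$input_size
  out <- vector("list", length(videos))
  for (i in seq_along(videos)) {
    v <- videos[[i]]
    samples <- build_frame_samples(list(v), isz)
    rows <- lapply(samples, function(s) {
      trip <- list(frame_image = resize_image(s$frame_image, isz, isz),
                   pupil_patch = s$pupil_patch,
                   instrument_patch = s$instrument_patch)
      extract_stream_features(trip, fit$backbones)$fused_vec
    })
    vid <- if (!is.null(v$detections)) v$detections$video_id[1] else
      sprintf("video_%03d", i)
    feats <- frame_features(do.call(rbind, rows),
                            fps = if (!is.null(v$labels)) v$labels$fps
                            else fit$config$fps,
                            video_id = vid)
    out[[i]] <- list(features = feats, labels = v$labels)
    if (!is.null(out_dir))
      write_features(feats, v$labels, file.path(out_dir, vid))
  }
  out
}

#' Per-frame predictions as a table
#'
#' @param model a trained [mstcn()] model.
#' @param features a [frame_features] object.
#' @param path optional CSV output path (`frame_index`,
#'   `predicted_phase`, `max_prob`).
#' @return data.frame of per-frame predictions; the final-stage
#'   probability matrix is attached as attribute `"probs"`.
#' @export
predict_phases <- function(model, features, path = NULL) {
  pr <- predict(model, features)
  out <- data.frame(frame_index = seq_along(pr$labels$labels) - 1L,
                    predicted_phase = pr$labels$labels,
                    max_prob = apply(pr$probs, 1, max))
  attr(out, "probs") <- pr$probs
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}

#' Streaming (frame-by-frame) final-stage logits
#'
#' Emulates online deployment: frames arrive one at a time into a
#' preallocated zero buffer of length `horizon`, and after each arrival
#' the model is re-run and the newest frame's logits are kept.  For a
#' causal model the not-yet-arrived zero frames cannot influence the
#' frames already seen, so the result equals the whole-video forward pass
#' frame for frame.
#'
#' @param model an [mstcn()] model.
#' @param x `T x D` matrix or [frame_features].
#' @param horizon buffer length (default `T`).
#' @return `T x C` matrix of final-stage logits.
#' @export
streaming_logits <- function(model, x, horizon = NULL) {
  if (inherits(x, "frame_features")) x <- x$values
  Tn <- nrow(x)
  if (is.null(horizon)) horizon <- Tn
  stopifnot(horizon >= Tn)
  buffer <- matrix(0, horizon, ncol(x))
  out <- matrix(NA_real_, Tn, model$config$n_classes)
  for (t in seq_len(Tn)) {
    buffer[t, ] <- x[t, ]
    fw <- mstcn_forward(model, buffer)
    out[t, ] <- fw$stage_logits[[2]][t, ]
  }
  out
}

#' Evaluate predictions against ground truth and write a report
#'
#' Computes the frame-level macro metrics, the confusion matrix, the
#' segment/transition-deviation table and the phase ribbon, and writes
#' them under `out_dir` (`metrics.json`, `metrics.csv`, `confusion.csv`,
#' `transitions.csv`, `ribbon.png`).
#'
#' @param pred predicted [phase_labels] (or integer vector).
#' @param truth ground-truth [phase_labels].
#' @param out_dir output directory (created if missing); `NULL` skips
#'   writing.
#' @param fps frame rate for transition deviations (default from truth).
#' @return list with `metrics`, `confusion`, `transitions`.
#' @export
evaluate_run <- function(pred, truth, out_dir = NULL, fps = NULL) {
  if (is.null(fps))
    fps <- if (inherits(truth, "phase_labels")) truth$fps else 20
  nc <- if (inherits(truth, "phase_labels")) truth$n_classes else
    max(as_label_vec(pred), as_label_vec(truth))
  cc <- confusion_counts(pred, truth, n_classes = nc)
  met <- phase_metrics(cc)
  cm <- confusion_matrix(pred, truth, n_classes = nc)
  sp <- segments_and_transitions(pred)
  st <- segments_and_transitions(truth)
  td <- transition_deviation(sp, st, fps)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(accuracy = met$accuracy, precision = met$precision,
           recall = met$recall, jaccard = met$jaccard,
           n_skipped_classes = met$n_skipped),
      file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
    macro <- data.frame(class = "macro", precision = met$precision,
                        recall = met$recall, jaccard = met$jaccard)
    utils::write.csv(rbind(transform(met$per_class, class = as.character(class)),
                           macro),
                     file.path(out_dir, "metrics.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(cm), file.path(out_dir, "confusion.csv"),
                     row.names = TRUE)
    utils::write.csv(td, file.path(out_dir, "transitions.csv"),
                     row.names = FALSE)
    render_ribbon(list(prediction = pred, ground_truth = truth),
                  file.path(out_dir, "ribbon.png"))
  }
  list(metrics = met, confusion = cm, transitions = td)
}

# ---- checkpoints and run manifests ------------------------------------------

CHECKPOINT_VERSION <- 1L

#' Save / load a model checkpoint
#'
#' Single-file serialized parameter archive with an embedded config echo
#' and a format version.
#'
#' @param object an `mstcn`, `mstcn_fit` or `frontend_fit`.
#' @param path checkpoint file path.
#' @return `path` invisibly (save); the restored object (load).
#' @export
save_checkpoint <- function(object, path) {
  saveRDS(list(format_version = CHECKPOINT_VERSION,
               class = class(object)[1], object = object), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("missing checkpoint: ", path)
  ck <- readRDS(path)
  if (is.null(ck$format_version) || ck$format_version > CHECKPOINT_VERSION)
    stop("unsupported checkpoint format")
  ck$object
}

#' Write a run manifest
#'
#' Records the configuration echo, the seed, the per-epoch history and
#' the package version -- enough to reproduce the run on one platform.
#'
#' @param fit an `mstcn_fit` or `frontend_fit`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(fit, path) {
  jsonlite::write_json(
    list(package_version = as.character(utils::packageVersion("phasetcn")),
         config = fit$config, seed = fit$config$seed,
         class_weights = if (inherits(fit$class_weights, "class_weights"))
           fit$class_weights$omega else as.numeric(fit$class_weights),
         history = fit$history,
         best_epoch = fit$best_epoch),
    path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}
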