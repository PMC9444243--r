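# Per-frame cell-state classification and sequence classification.
# A small convolutional network (stack of conv/relu/maxpool blocks sized
# for ~60x60 trap images) classifies individual frames into the six
# canonical states; its penultimate-layer activations feed a bidirectional
# LSTM that classifies the whole sequence, buffering isolated per-frame
# errors.  A rule-based post-processing variant ("CNN+PP") is also
# provided: two consecutive dead frames are required to call a death.

#' Training configuration for the frame classifier
#'
#' @param conv_channels output channels of the successive conv/relu/maxpool
#'   blocks; the input side must be divisible by `2^length(conv_channels)`.
#' @param feature_dim width of the penultimate dense layer (the feature
#'   vector fed to the sequence LSTM).
#' @param epochs,batch_size,lr Adam training schedule.
#' @param seed integer seed governing initialisation and shuffling.
#' @return named list.
#' @export
cnn_config <- function(conv_channels = c(8L, 16L, 32L, 32L),
                       feature_dim = 32L, epochs = 10L, batch_size = 32L,
                       lr = 1e-3, seed = 1L) {
  as.list(environment())
}

# images: (N, H, W, C) array -> internal (H, W, C, N)
to_hwcn <- function(images) aperm(images, c(2L, 3L, 4L, 1L))

build_cnn_layers <- function(H, W, C, cfg) {
  layers <- list()
  cin <- C
  h <- H; w <- W
  for (co in cfg$conv_channels) {
    layers <- c(layers, list(layer_conv(3L, 3L, cin, co, pad = 1L),
                             layer_relu(), layer_maxpool()))
    cin <- co; h <- h / 2; w <- w / 2
  }
  head <- layer_dense(cfg$feature_dim, 6L)
  # zero-init the classification head: training is then exactly
  # equivariant under class relabelling (permuting the training labels
  # permutes the logit trajectories)
  head$W[] <- 0
  layers <- c(layers, list(layer_flatten(),
                           layer_dense(h * w * cin, cfg$feature_dim),
                           layer_relu(),
                           head))
  layers
}

#' Train the per-frame state classifier
#'
#' @param images numeric array (N, H, W, C) of training frames; H and W
#'   must be divisible by `2^length(conv_channels)`.
#' @param labels character vector of length N with canonical class labels.
#' @param config list from [cnn_config()].
#' @return a fitted `frame_cnn` model; `final_train_accuracy` reports the
#'   training-set accuracy after the last epoch and `loss_trajectory` the
#'   per-epoch mean loss.
#' @export
train_frame_cnn <- function(images, labels, config = cnn_config()) {
  cfg <- utils::modifyList(cnn_config(), config)
  if (length(dim(images)) != 4L)
    stop("invalid-input: images must be (N, H, W, C)")
  N <- dim(images)[1]
  if (length(labels) != N)
    stop("invalid-input: one label per image required")
  cls <- trap_classes()
  if (!all(labels %in% cls)) stop("invalid-input: unknown labels")
  if (length(unique(labels)) < 2L)
    stop("degenerate-training: need at least 2 classes")
  H <- dim(images)[2]; W <- dim(images)[3]; C <- dim(images)[4]
  down <- 2^length(cfg$conv_channels)
  if (H %% down != 0 || W %% down != 0)
    stop("invalid-input: H and W must be divisible by ", down)
  y <- match(labels, cls)
  X <- to_hwcn(images) - 0.5      # centre intensities around zero
  with_seed(cfg$seed, {
    layers <- build_cnn_layers(H, W, C, cfg)
    st <- adam_state()
    step <- 0L
    losses <- numeric(cfg$epochs)
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(N)
      ep_loss <- 0; nb <- 0L
      for (b0 in seq(1L, N, by = cfg$batch_size)) {
        ii <- ord[b0:min(b0 + cfg$batch_size - 1L, N)]
        xb <- X[, , , ii, drop = FALSE]
        fw <- net_forward(layers, xb)
        sm <- softmax_xent(fw$out, y[ii])
        bk <- net_backward(layers, fw$caches, sm$dlogits)
        step <- step + 1L
        layers <- net_adam_step(layers, bk$grads, st, cfg$lr, step)
        ep_loss <- ep_loss + sm$loss; nb <- nb + 1L
      }
      losses[ep] <- ep_loss / nb
    }
    model <- structure(list(layers = layers, classes = cls,
                            input_size = c(H, W, C),
                            feature_dim = cfg$feature_dim,
                            config = cfg, fitted = TRUE,
                            loss_trajectory = losses),
                       class = "frame_cnn")
    pr <- predict_frames_array(model, images)
    model$final_train_accuracy <- mean(cls[max.col(pr, "first")] == labels)
    model
  })
}

#' @export
print.frame_cnn <- function(x, ...) {
  cat(sprintf("<frame_cnn> input %s, %d conv blocks, %d features%s\n",
              paste(x$input_size, collapse = "x"),
              length(x$config$conv_channels), x$feature_dim,
              if (!is.null(x$final_train_accuracy))
                sprintf(", train acc %.3f", x$final_train_accuracy) else ""))
  invisible(x)
}

# Nearest-neighbour resize of (N, H, W, C) to (N, th, tw, C).
resize_frames <- function(images, th, tw) {
  d <- dim(images)
  ih <- round(seq(1, d[2], length.out = th))
  iw <- round(seq(1, d[3], length.out = tw))
  images[, ih, iw, , drop = FALSE]
}

# Align a movie's frames with the model input: channel subset (brightfield
# channels come first) and nearest-neighbour resize when needed.
model_input_frames <- function(model, movie) {
  fr <- movie$frames
  C <- dim(fr)[4]; mc <- model$input_size[3]
  if (C < mc)
    stop("invalid-input: movie has ", C, " channel(s); model needs ", mc)
  if (C > mc) fr <- fr[, , , seq_len(mc), drop = FALSE]
  resized <- FALSE
  if (dim(fr)[2] != model$input_size[1] || dim(fr)[3] != model$input_size[2]) {
    fr <- resize_frames(fr, model$input_size[1], model$input_size[2])
    resized <- TRUE
  }
  attr(fr, "resized") <- resized
  fr
}

# Forward an (N, H, W, C) array; returns the N x 6 probability matrix.
predict_frames_array <- function(model, images, batch = 64L) {
  N <- dim(images)[1]
  out <- matrix(0, N, 6L)
  X <- to_hwcn(images) - 0.5
  for (b0 in seq(1L, N, by = batch)) {
    ii <- b0:min(b0 + batch - 1L, N)
    fw <- net_forward(model$layers, X[, , , ii, drop = FALSE], train = FALSE)
    out[ii, ] <- softmax_rows(fw$out)
  }
  out
}

#' Classify every frame of a movie independently
#'
#' Stateless per-frame classification: identical frames give identical
#' probability rows.  Frames are resized (nearest neighbour, recorded in
#' attribute `resized`) and extra trailing channels dropped when the movie
#' does not match the model input.
#'
#' @param model a fitted `frame_cnn`.
#' @param movie a [trap_movie()].
#' @return a [label_sequence()] with a T x 6 probability matrix; labels are
#'   the row argmax (ties to the first class in canonical order).
#' @export
classify_frames <- function(model, movie) {
  if (!inherits(model, "frame_cnn") || !isTRUE(model$fitted))
    stop("not-fitted: model must be a fitted frame_cnn")
  fr <- model_input_frames(model, movie)
  probs <- predict_frames_array(model, fr)
  out <- label_sequence(model$classes[max.col(probs, "first")], probs,
                        frame_interval_min = movie$frame_interval_min)
  attr(out, "resized") <- attr(fr, "resized")
  out
}

#' Extract per-frame CNN features from a movie
#'
#' Returns the penultimate-layer activations (the representation the
#' sequence LSTM consumes); identical frames map to identical rows.
#'
#' @param model a fitted `frame_cnn`.
#' @param movie a [trap_movie()].
#' @return T x d numeric matrix, d = `model$feature_dim`.
#' @export
extract_features <- function(model, movie) {
  if (!inherits(model, "frame_cnn") || !isTRUE(model$fitted))
    stop("not-fitted: model must be a fitted frame_cnn")
  fr <- model_input_frames(model, movie)
  X <- to_hwcn(fr) - 0.5
  N <- dim(X)[4]
  feat_layers <- model$layers[seq_len(length(model$layers) - 1L)]
  out <- matrix(0, N, model$feature_dim)
  for (b0 in seq(1L, N, by = 64L)) {
    ii <- b0:min(b0 + 63L, N)
    fw <- net_forward(feat_layers, X[, , , ii, drop = FALSE], train = FALSE)
    out[ii, ] <- fw$out
  }
  out
}

#' Train the sequence classifier (bidirectional LSTM)
#'
#' @param feature_seqs list of T x d feature matrices from
#'   [extract_features()].
#' @param label_seqs list of [label_sequence()]s (or character vectors)
#'   aligned frame-by-frame with the features.
#' @param hidden LSTM hidden width (default 150).
#' @param epochs,lr,batch_size Adam schedule (minibatches of sequences).
#' @param seed integer seed.
#' @return a fitted `seq_lstm` model.
#' @export
train_sequence_lstm <- function(feature_seqs, label_seqs, hidden = 150L,
                                epochs = 30L, lr = 5e-3, batch_size = 16L,
                                seed = 1L) {
  stopifnot(length(feature_seqs) == length(label_seqs))
  N <- length(feature_seqs)
  labs <- lapply(label_seqs, function(l)
    if (inherits(l, "label_sequence")) l$labels else as.character(l))
  Ts <- vapply(feature_seqs, nrow, integer(1))
  if (!all(vapply(labs, length, integer(1)) == Ts))
    stop("invalid-input: features and labels must align per frame")
  d <- ncol(feature_seqs[[1L]])
  cls <- trap_classes()
  TT <- max(Ts)
  x <- array(0, dim = c(N, TT, d))
  lab <- matrix(1L, N, TT)
  mask <- matrix(FALSE, N, TT)
  for (i in seq_len(N)) {
    x[i, seq_len(Ts[i]), ] <- feature_seqs[[i]]
    lab[i, seq_len(Ts[i])] <- match(labs[[i]], cls)
    mask[i, seq_len(Ts[i])] <- TRUE
  }
  net <- bilstm_train(x, lab, K = 6L, hidden = hidden, epochs = epochs,
                      lr = lr, seed = seed, mask = mask,
                      batch_size = batch_size)
  structure(list(net = net, d = d, hidden = as.integer(hidden),
                 classes = cls, epochs = as.integer(epochs), lr = lr,
                 seed = as.integer(seed), fitted = TRUE),
            class = "seq_lstm")
}

#' Classify a movie with the assembled CNN+LSTM
#'
#' Extracts CNN features and runs the bidirectional LSTM over the whole
#' sequence; deterministic given the two fitted models.
#'
#' @param cnn a fitted `frame_cnn`.
#' @param lstm a fitted `seq_lstm`.
#' @param movie a [trap_movie()].
#' @return a [label_sequence()] with probabilities.
#' @export
classify_sequence <- function(cnn, lstm, movie) {
  if (!inherits(lstm, "seq_lstm") || !isTRUE(lstm$fitted))
    stop("not-fitted: lstm must be a fitted seq_lstm")
  feats <- extract_features(cnn, movie)
  if (ncol(feats) != lstm$d)
    stop("incompatible-models: feature width ", ncol(feats),
         " != LSTM input width ", lstm$d)
  probs <- bilstm_predict(lstm$net, feats)
  label_sequence(lstm$classes[max.col(probs, "first")], probs,
                 frame_interval_min = movie$frame_interval_min)
}

#' Relabel isolated dead frames (CNN post-processing)
#'
#' Implements the rule that two consecutive dead frames are needed to call
#' a death: every isolated dead frame (neither neighbour dead) is relabeled
#' to the nearest preceding non-dead label (for the first frame, the
#' nearest following non-dead label).  Runs of two or more dead frames are
#' untouched.  Idempotent.  Class probabilities are dropped from the
#' output since they no longer match the labels.
#'
#' @param labels a [label_sequence()].
#' @return a [label_sequence()].
#' @export
postprocess_cnn_labels <- function(labels) {
  stopifnot(inherits(labels, "label_sequence"))
  lab <- labels$labels
  T <- length(lab)
  if (T == 0L) return(labels)
  isd <- lab == "dead"
  iso <- isd &
    !c(FALSE, isd[-T]) &   # previous frame dead?
    !c(isd[-1L], FALSE)    # next frame dead?
  for (t in which(iso)) {
    repl <- NA_character_
    if (t > 1L) {
      prev <- lab[seq_len(t - 1L)]
      nd <- which(prev != "dead")
      if (length(nd)) repl <- prev[max(nd)]
    }
    if (is.na(repl)) {
      nxt <- lab[seq.int(t, T)]
      nd <- which(nxt != "dead")
      if (length(nd)) repl <- nxt[min(nd)]
    }
    if (!is.na(repl)) lab[t] <- repl
  }
  label_sequence(lab, frame_interval_min = labels$frame_interval_min)
}
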