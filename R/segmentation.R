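# Semantic segmentation of trap images: an encoder/decoder fully
# convolutional network (two scales with a skip connection, optional
# coordinate channels so the centred mother is positionally identifiable)
# emits per-pixel class probabilities for brightfield
# (background/mother/other) or fluorescence (background/nucleus) images.
# A probability threshold on the target class, selected by F1 on a
# validation set, converts probabilities into masks; per-cell quantities
# (areas, background-subtracted fluorescence) are then measured per frame.

#' Training configuration for the segmenter
#'
#' @param enc_channels channels of the full-, half- and quarter-resolution
#'   encoder convolutions.
#' @param use_coords append normalized (row, col) offset-from-centre
#'   channels to the input (the mother class is defined by its central
#'   position, which a small receptive field cannot see otherwise).
#' @param epochs,batch_size,lr Adam schedule.
#' @param seed integer seed.
#' @return named list.
#' @export
seg_config <- function(enc_channels = c(8L, 16L, 24L), use_coords = TRUE,
                       epochs = 12L, batch_size = 8L, lr = 2e-3, seed = 1L) {
  as.list(environment())
}

coord_channels <- function(H, W) {
  ry <- (seq_len(H) - 1 - (H - 1) / 2) / H
  cx <- (seq_len(W) - 1 - (W - 1) / 2) / W
  list(row = matrix(ry, H, W), col = matrix(cx, H, W, byrow = TRUE))
}

# (H, W, C, N) + coords -> (H, W, C+2, N)
add_coords <- function(X) {
  d <- dim(X)
  cc <- coord_channels(d[1], d[2])
  out <- array(0, dim = c(d[1], d[2], d[3] + 2L, d[4]))
  out[, , seq_len(d[3]), ] <- X
  for (n in seq_len(d[4])) {
    out[, , d[3] + 1L, n] <- cc$row
    out[, , d[3] + 2L, n] <- cc$col
  }
  out
}

# Channel-axis concatenation of two (H, W, C, N) tensors.
cat_channels <- function(a, b) {
  d <- dim(a)
  out <- array(0, dim = c(d[1], d[2], d[3] + dim(b)[3], d[4]))
  out[, , seq_len(d[3]), ] <- a
  out[, , d[3] + seq_len(dim(b)[3]), ] <- b
  out
}

# Three-scale encoder/decoder with skip connections (full, 1/2, 1/4
# resolution); the 1/4-res path gives a ~20 px receptive field so whole
# cell bodies are in view of every boundary decision.
seg_forward <- function(m, X) {
  r1 <- relu(a1 <- cpp_conv2d_forward_gemm(X, m$W1, m$b1, 1L))
  p1 <- cpp_avgpool2_forward(r1)
  r2 <- relu(a2 <- cpp_conv2d_forward_gemm(p1, m$W2, m$b2, 1L))
  p2 <- cpp_avgpool2_forward(r2)
  r3 <- relu(a3 <- cpp_conv2d_forward_gemm(p2, m$W3, m$b3, 1L))
  u3 <- cpp_upsample2_forward(r3)
  cat2 <- cat_channels(r2, u3)
  r4 <- relu(a4 <- cpp_conv2d_forward_gemm(cat2, m$W4, m$b4, 1L))
  u4 <- cpp_upsample2_forward(r4)
  cat1 <- cat_channels(r1, u4)
  logits <- cpp_conv2d_forward_gemm(cat1, m$W5, m$b5, 0L)
  list(logits = logits, X = X, a1 = a1, r1 = r1, p1 = p1, a2 = a2,
       r2 = r2, p2 = p2, a3 = a3, r3 = r3, a4 = a4, r4 = r4,
       cat2 = cat2, cat1 = cat1)
}

seg_backward <- function(m, fw, dlogits) {
  bk5 <- cpp_conv2d_backward_gemm(fw$cat1, m$W5, dlogits, 0L)
  c1 <- dim(fw$r1)[3]
  dr1 <- bk5$dx[, , seq_len(c1), , drop = FALSE]
  du4 <- bk5$dx[, , c1 + seq_len(dim(fw$r4)[3]), , drop = FALSE]
  dr4 <- cpp_upsample2_backward(du4, as.integer(dim(fw$r4)))
  da4 <- dr4 * (fw$a4 > 0)
  bk4 <- cpp_conv2d_backward_gemm(fw$cat2, m$W4, da4, 1L)
  c2 <- dim(fw$r2)[3]
  dr2 <- bk4$dx[, , seq_len(c2), , drop = FALSE]
  du3 <- bk4$dx[, , c2 + seq_len(dim(fw$r3)[3]), , drop = FALSE]
  dr3 <- cpp_upsample2_backward(du3, as.integer(dim(fw$r3)))
  da3 <- dr3 * (fw$a3 > 0)
  bk3 <- cpp_conv2d_backward_gemm(fw$p2, m$W3, da3, 1L)
  dr2 <- dr2 + cpp_avgpool2_backward(bk3$dx, as.integer(dim(fw$r2)))
  da2 <- dr2 * (fw$a2 > 0)
  bk2 <- cpp_conv2d_backward_gemm(fw$p1, m$W2, da2, 1L)
  dr1 <- dr1 + cpp_avgpool2_backward(bk2$dx, as.integer(dim(fw$r1)))
  da1 <- dr1 * (fw$a1 > 0)
  bk1 <- cpp_conv2d_backward_gemm(fw$X, m$W1, da1, 1L)
  list(W1 = bk1$dw, b1 = bk1$db, W2 = bk2$dw, b2 = bk2$db,
       W3 = bk3$dw, b3 = bk3$db, W4 = bk4$dw, b4 = bk4$db,
       W5 = bk5$dw, b5 = bk5$db)
}

masks_to_array <- function(masks) {
  cm <- lapply(masks, function(m)
    if (inherits(m, "segmentation_mask")) m$class_map else as.matrix(m))
  array(unlist(cm), dim = c(dim(cm[[1L]]), length(cm)))   # (H, W, N)
}

#' Train the encoder/decoder segmenter
#'
#' @param images numeric array (N, H, W, C) with H, W even.
#' @param masks list of [segmentation_mask()]s or H x W integer matrices
#'   (codes 0..K-1), one per image.
#' @param class_set character vector naming the codes
#'   (default background/mother/other; use background/nucleus for
#'   fluorescence).
#' @param config list from [seg_config()].
#' @return a fitted `seg_model` emitting per-pixel class probabilities;
#'   images of any (even) size are accepted at prediction time — the
#'   network is fully convolutional.
#' @export
train_segmenter <- function(images, masks,
                            class_set = c("background", "mother", "other"),
                            config = seg_config()) {
  cfg <- utils::modifyList(seg_config(), config)
  if (length(dim(images)) != 4L)
    stop("invalid-input: images must be (N, H, W, C)")
  N <- dim(images)[1]
  if (length(masks) != N) stop("invalid-input: one mask per image required")
  K <- length(class_set)
  Y <- masks_to_array(masks)
  if (any(Y < 0L | Y >= K))
    stop("invalid-label: mask codes outside the class set")
  if (length(unique(as.integer(Y))) < 2L)
    warning("degenerate-training: masks contain a single class")
  H <- dim(images)[2]; W <- dim(images)[3]; C <- dim(images)[4]
  if (H %% 4L || W %% 4L)
    stop("invalid-input: H and W must be divisible by 4")
  X <- to_hwcn(images) - 0.5      # centre intensities around zero
  if (isTRUE(cfg$use_coords)) X <- add_coords(X)
  cin <- dim(X)[3]
  c1 <- cfg$enc_channels[1]; c2 <- cfg$enc_channels[2]
  c3 <- cfg$enc_channels[3]
  with_seed(cfg$seed, {
    m <- list(W1 = he_init(c(3L, 3L, cin, c1), 9 * cin), b1 = numeric(c1),
              W2 = he_init(c(3L, 3L, c1, c2), 9 * c1), b2 = numeric(c2),
              W3 = he_init(c(3L, 3L, c2, c3), 9 * c2), b3 = numeric(c3),
              W4 = he_init(c(3L, 3L, c2 + c3, c2), 9 * (c2 + c3)),
              b4 = numeric(c2),
              W5 = he_init(c(1L, 1L, c1 + c2, K), c1 + c2), b5 = numeric(K))
    st <- adam_state()
    step <- 0L
    losses <- numeric(cfg$epochs)
    for (ep in seq_len(cfg$epochs)) {
      # step decay: halve the rate at 1/2 and again at 3/4 of the schedule
      lr_ep <- cfg$lr * 0.5^((ep > cfg$epochs / 2) + (ep > 3 * cfg$epochs / 4))
      ord <- sample.int(N)
      ep_loss <- 0; nb <- 0L
      for (b0 in seq(1L, N, by = cfg$batch_size)) {
        ii <- ord[b0:min(b0 + cfg$batch_size - 1L, N)]
        xb <- X[, , , ii, drop = FALSE]
        fw <- seg_forward(m, xb)
        dlg <- dim(fw$logits)
        # pixels x K, batch-flattened
        lg <- matrix(aperm(fw$logits, c(1L, 2L, 4L, 3L)), prod(dlg[-3]),
                     dlg[3])
        yb <- as.integer(Y[, , ii]) + 1L
        sm <- softmax_xent(lg, yb)
        dl <- aperm(array(sm$dlogits, dim = c(dlg[1], dlg[2], dlg[4], dlg[3])),
                    c(1L, 2L, 4L, 3L))
        gr <- seg_backward(m, fw, dl)
        step <- step + 1L
        for (p in names(gr))
          m[[p]] <- adam_update(st, p, m[[p]], gr[[p]], lr_ep, step)
        ep_loss <- ep_loss + sm$loss; nb <- nb + 1L
      }
      losses[ep] <- ep_loss / nb
    }
    structure(list(params = m, class_set = class_set, in_channels = C,
                   use_coords = cfg$use_coords, config = cfg,
                   loss_trajectory = losses, fitted = TRUE),
              class = "seg_model")
  })
}

#' @export
print.seg_model <- function(x, ...) {
  cat(sprintf("<seg_model> classes [%s], %d input channel(s)%s\n",
              paste(x$class_set, collapse = ", "), x$in_channels,
              if (x$use_coords) " + coords" else ""))
  invisible(x)
}

# Per-pixel class probabilities for one image (H x W x C or H x W).
seg_predict_probs <- function(model, image) {
  if (!inherits(model, "seg_model") || !isTRUE(model$fitted))
    stop("not-fitted: model must be a fitted seg_model")
  if (is.matrix(image)) image <- array(image, dim = c(dim(image), 1L))
  d <- dim(image)
  if (d[3] != model$in_channels)
    stop("invalid-input: expected ", model$in_channels, " channel(s)")
  # pad to a multiple of 4, crop back after
  ph <- (4L - d[1] %% 4L) %% 4L; pw <- (4L - d[2] %% 4L) %% 4L
  X <- array(0, dim = c(d[1] + ph, d[2] + pw, d[3], 1L))
  X[seq_len(d[1]), seq_len(d[2]), , 1L] <- image - 0.5
  if (isTRUE(model$use_coords)) X <- add_coords(X)
  fw <- seg_forward(model$params, X)
  K <- length(model$class_set)
  lg <- matrix(fw$logits, prod(dim(fw$logits)[1:2]), K)
  pr <- softmax_rows(lg)
  pm <- array(pr, dim = c(dim(fw$logits)[1:2], K))
  pm[seq_len(d[1]), seq_len(d[2]), , drop = FALSE]
}

#' Select the target-class probability threshold by F1
#'
#' Scores every threshold on the grid against the pooled validation pixels
#' and returns the one maximising the target-class F1 (ties resolved to
#' the larger threshold), with the full precision/recall/F1 table.
#'
#' @param model a fitted `seg_model`.
#' @param images validation array (N, H, W, C).
#' @param masks validation masks (list or matrices).
#' @param grid thresholds in (0, 1).
#' @param target_class code of the thresholded class (default 1: mother or
#'   nucleus).
#' @return list with `best` and `table`.
#' @export
select_threshold <- function(model, images, masks,
                             grid = seq(0.1, 0.9, by = 0.1),
                             target_class = 1L) {
  if (!length(grid) || any(grid <= 0 | grid >= 1))
    stop("invalid-input: grid must be a non-empty subset of (0,1)")
  if (!length(dim(images)) || dim(images)[1] < 1L || !length(masks))
    stop("invalid-input: empty validation set")
  N <- dim(images)[1]
  Y <- masks_to_array(masks)
  ptarget <- truth <- NULL
  for (i in seq_len(N)) {
    pm <- seg_predict_probs(model, array(images[i, , , ], dim(images)[2:4]))
    ptarget <- c(ptarget, as.numeric(pm[, , target_class + 1L]))
    truth <- c(truth, as.integer(Y[, , i]) == target_class)
  }
  grid <- sort(grid)
  tab <- do.call(rbind, lapply(grid, function(th) {
    pred <- ptarget >= th
    tp <- sum(pred & truth); fp <- sum(pred & !truth)
    fn <- sum(!pred & truth)
    pr <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    rc <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (!is.na(pr) && !is.na(rc) && pr + rc > 0)
      2 * pr * rc / (pr + rc) else NA_real_
    data.frame(threshold = th, precision = pr, recall = rc, f1 = f1)
  }))
  f1v <- ifelse(is.na(tab$f1), -Inf, tab$f1)
  best <- grid[max(which(f1v == max(f1v)))]   # ties -> larger threshold
  list(best = best, table = tab)
}

#' Predict a segmentation mask for one frame
#'
#' A pixel is assigned the target class iff its probability is at least
#' `threshold`; otherwise it takes the argmax of the remaining classes.
#' For brightfield (mother) masks, only the 8-connected mother component
#' whose centroid lies nearest the trap centre is kept; all other mother
#' components are relabeled `other` (the mother's conserved central
#' position is what identifies it).
#'
#' @param model a fitted `seg_model`.
#' @param image H x W x C array (or H x W matrix).
#' @param threshold target-class probability threshold in (0, 1).
#' @param target_class thresholded class code (default 1).
#' @param trap_center (row, col) 0-based; defaults to the image centre.
#' @return a [segmentation_mask()] with probability maps attached.
#' @export
predict_mask <- function(model, image, threshold = 0.9, target_class = 1L,
                         trap_center = NULL) {
  pm <- seg_predict_probs(model, image)
  mask_from_probs(pm, threshold, class_set = model$class_set,
                  target_class = target_class, trap_center = trap_center)
}

#' Convert per-pixel class probabilities into a mask
#'
#' The thresholding and mother-component selection used by
#' [predict_mask()], exposed so masks can be derived from any probability
#' source.
#'
#' @param prob_maps H x W x K probability array.
#' @param threshold target-class threshold in (0, 1).
#' @param class_set class names for the codes.
#' @param target_class thresholded class code.
#' @param trap_center (row, col) 0-based; defaults to the image centre.
#' @return a [segmentation_mask()].
#' @export
mask_from_probs <- function(prob_maps, threshold,
                            class_set = c("background", "mother", "other"),
                            target_class = 1L, trap_center = NULL) {
  if (threshold <= 0 || threshold >= 1)
    stop("invalid-parameter: threshold must lie in (0, 1)")
  pm <- prob_maps
  H <- dim(pm)[1]; W <- dim(pm)[2]; K <- dim(pm)[3]
  tcol <- target_class + 1L
  is_t <- pm[, , tcol] >= threshold
  rest <- seq_len(K)[-tcol]
  oth <- matrix(rest[max.col(matrix(pm[, , rest], H * W, K - 1L), "first")],
                H, W)
  cm <- matrix(0L, H, W)
  cm[] <- oth - 1L
  cm[is_t] <- as.integer(target_class)
  if ("mother" %in% class_set && target_class == 1L && any(cm == 1L)) {
    if (is.null(trap_center)) trap_center <- c((H - 1) / 2, (W - 1) / 2)
    lab <- cpp_label_components(cm == 1L)
    ncomp <- max(lab)
    if (ncomp > 1L) {
      d2 <- vapply(seq_len(ncomp), function(k) {
        ij <- which(lab == k, arr.ind = TRUE)
        (mean(ij[, 1]) - 1 - trap_center[1])^2 +
          (mean(ij[, 2]) - 1 - trap_center[2])^2
      }, numeric(1))
      keep <- which.min(d2)
      other_code <- which(class_set == "other") - 1L
      cm[lab > 0L & lab != keep] <- as.integer(other_code)
    }
  }
  segmentation_mask(cm, pm, class_set = class_set,
                    threshold_used = threshold)
}

#' Quantify per-cell geometry and fluorescence over a mask sequence
#'
#' Per frame: mother area (pixel count and square microns), nucleus area,
#' total nuclear fluorescence (sum of background-subtracted intensity over
#' nucleus pixels) and mean cytoplasmic fluorescence (mean
#' background-subtracted intensity over mother pixels).  The background is
#' the per-frame median intensity over the background-class pixels of the
#' nucleus mask.  Frames with an empty mother mask get area 0 and `NA`
#' fluorescence values.
#'
#' @param bf_masks list of brightfield [segmentation_mask()]s (codes 0/1/2)
#'   or `NULL`.
#' @param nuc_masks list of nucleus [segmentation_mask()]s (codes 0/1) or
#'   `NULL`.
#' @param fluo fluorescence movie: T x H x W array, or a [trap_movie()]
#'   (the `gfp` channel, else channel 2, is used).
#' @param pixel_size_um pixel side length in microns.
#' @param frame_interval_min minutes per frame (taken from `fluo` when it
#'   is a movie).
#' @return data.frame (`quant_trace`): `frame` (0-based), `time_min`,
#'   `mother_area_px`, `mother_area_um2`, `nucleus_area_px`,
#'   `total_nuclear_fluorescence`, `mean_cyto_fluorescence`.
#' @export
quantify <- function(bf_masks = NULL, nuc_masks = NULL, fluo = NULL,
                     pixel_size_um = 0.325, frame_interval_min = 5) {
  if (inherits(fluo, "trap_movie")) {
    ch <- match("gfp", fluo$channel_names)
    if (is.na(ch)) ch <- min(2L, dim(fluo$frames)[4])
    frame_interval_min <- fluo$frame_interval_min
    fluo <- array(fluo$frames[, , , ch],
                  dim = dim(fluo$frames)[1:3])
  }
  T <- max(length(bf_masks), length(nuc_masks),
           if (is.null(fluo)) 0L else dim(fluo)[1])
  if (T == 0L) stop("invalid-input: nothing to quantify")
  for (nm in c("bf_masks", "nuc_masks"))
    if (!is.null(get(nm)) && length(get(nm)) != T)
      stop("invalid-input: masks and movie must be aligned frame-by-frame")
  out <- data.frame(frame = seq_len(T) - 1L)
  out$time_min <- out$frame * frame_interval_min
  out$mother_area_px <- NA_real_
  out$mother_area_um2 <- NA_real_
  out$nucleus_area_px <- NA_real_
  out$total_nuclear_fluorescence <- NA_real_
  out$mean_cyto_fluorescence <- NA_real_
  for (t in seq_len(T)) {
    bm <- if (!is.null(bf_masks)) bf_masks[[t]]$class_map else NULL
    nm <- if (!is.null(nuc_masks)) nuc_masks[[t]]$class_map else NULL
    if (!is.null(bm)) {
      a <- sum(bm == 1L)
      out$mother_area_px[t] <- a
      out$mother_area_um2[t] <- a * pixel_size_um^2
    }
    if (!is.null(nm)) out$nucleus_area_px[t] <- sum(nm == 1L)
    if (!is.null(fluo) && !is.null(nm)) {
      fr <- matrix(fluo[t, , ], dim(fluo)[2], dim(fluo)[3])
      bg <- stats::median(fr[nm == 0L])
      if (any(nm == 1L))
        out$total_nuclear_fluorescence[t] <- sum(fr[nm == 1L] - bg)
      if (!is.null(bm) && any(bm == 1L)) {
        out$mean_cyto_fluorescence[t] <- mean(fr[bm == 1L] - bg)
      } else if (!is.null(bm)) {
        out$total_nuclear_fluorescence[t] <- NA_real_
      }
    }
  }
  class(out) <- c("quant_trace", "data.frame")
  out
}

#' Cross-validate the segmenter over random train/test draws
#'
#' Each draw samples `n_train` training and `n_test` test images without
#' replacement (draws are independent of each other), trains a fresh
#' segmenter, and scores target-class precision/recall/F1 on the held-out
#' pixels at the given threshold.
#'
#' @param images array (N, H, W, C); `masks` the matching list.
#' @param masks per-image masks.
#' @param n_draws number of random draws (the reference protocol uses 30
#'   draws of 200 training and 50 test images).
#' @param n_train,n_test draw sizes; their sum must not exceed N.
#' @param threshold target-class threshold applied at evaluation.
#' @param class_set,config passed to [train_segmenter()].
#' @param target_class evaluated class code.
#' @param seed integer seed.
#' @return list with `per_draw` (data.frame) and `summary` (mean and SD per
#'   metric).
#' @export
cross_validate_segmenter <- function(images, masks, n_draws = 30L,
                                     n_train = 200L, n_test = 50L,
                                     threshold = 0.5,
                                     class_set = c("background", "mother",
                                                   "other"),
                                     config = seg_config(),
                                     target_class = 1L, seed = 1L) {
  N <- dim(images)[1]
  if (n_train + n_test > N)
    stop("invalid-parameter: n_train + n_test exceeds the set size")
  draws <- with_seed(seed, {
    lapply(seq_len(n_draws), function(b)
      sample.int(N, n_train + n_test, replace = FALSE))
  })
  per_draw <- do.call(rbind, lapply(seq_len(n_draws), function(b) {
    idx <- draws[[b]]
    tr <- idx[seq_len(n_train)]
    te <- idx[n_train + seq_len(n_test)]
    cfg <- utils::modifyList(config, list(seed = seed + b))
    mod <- train_segmenter(images[tr, , , , drop = FALSE], masks[tr],
                           class_set = class_set, config = cfg)
    pred <- truth <- NULL
    for (i in te) {
      pm <- seg_predict_probs(mod, array(images[i, , , ], dim(images)[2:4]))
      pred <- c(pred, as.numeric(pm[, , target_class + 1L]) >= threshold)
      truth <- c(truth, as.integer(masks_to_array(masks[i])) == target_class)
    }
    tp <- sum(pred & truth); fp <- sum(pred & !truth); fn <- sum(!pred & truth)
    pr <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    rc <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    data.frame(draw = b, precision = pr, recall = rc,
               f1 = if (!is.na(pr) && !is.na(rc) && pr + rc > 0)
                 2 * pr * rc / (pr + rc) else NA_real_)
  }))
  list(per_draw = per_draw,
       summary = data.frame(
         metric = c("precision", "recall", "f1"),
         mean = vapply(per_draw[, -1L], mean, numeric(1), na.rm = TRUE),
         sd = vapply(per_draw[, -1L], stats::sd, numeric(1), na.rm = TRUE)))
}
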