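# Trap (ROI) detection in fields of view by normalized cross-correlation
# against a trap template, and extraction of fixed-position per-trap image
# time series.  Correlation is zero-mean/unit-variance so detection is
# invariant to illumination offset and gain.  Pixel coordinates are
# 0-based, row-major, origin top-left; boxes are half-open
# [r, r+h) x [c, c+w).

#' Detect trap positions by template cross-correlation
#'
#' Computes the normalized cross-correlation map of `template` over
#' `fov_image`, thresholds it, and keeps candidate positions greedily in
#' descending score order subject to a minimum centre distance
#' (non-maximum suppression).  Deterministic.
#'
#' @param fov_image 2-D intensity matrix.
#' @param template 2-D intensity matrix, strictly smaller than the image,
#'   with non-zero variance.
#' @param threshold correlation threshold in (0, 1] (default 0.5).
#' @param min_distance minimum Euclidean distance between kept centres in
#'   pixels; defaults to the template width.
#' @param max_count keep at most this many traps.
#' @return a `roi_set`: `centers` (n x 2 matrix of 0-based (row, col)),
#'   `scores`, `box_size` (h, w), `template_id`.
#' @export
detect_trap_rois <- function(fov_image, template, threshold = 0.5,
                             min_distance = NULL, max_count = Inf) {
  fov_image <- as.matrix(fov_image)
  template <- as.matrix(template)
  th <- nrow(template); tw <- ncol(template)
  if (th >= nrow(fov_image) || tw >= ncol(fov_image))
    stop("invalid-input: template must be strictly smaller than the image")
  if (threshold <= 0 || threshold > 1)
    stop("invalid-parameter: threshold must lie in (0, 1]")
  if (stats::sd(as.numeric(template)) == 0)
    stop("degenerate-template: zero variance")
  if (is.null(min_distance)) min_distance <- tw
  cc <- cpp_ncc(fov_image, template)
  cand <- which(cc >= threshold, arr.ind = TRUE)
  centers <- matrix(numeric(0), 0L, 2L)
  scores <- numeric(0)
  if (nrow(cand)) {
    sc <- cc[cand]
    ord <- order(-sc, cand[, 1L], cand[, 2L])
    cand <- cand[ord, , drop = FALSE]
    sc <- sc[ord]
    kept <- matrix(numeric(0), 0L, 2L)
    for (i in seq_len(nrow(cand))) {
      ctr <- c(cand[i, 1L] - 1 + (th - 1) / 2, cand[i, 2L] - 1 + (tw - 1) / 2)
      if (nrow(kept) == 0L ||
          all(sqrt((kept[, 1L] - ctr[1])^2 + (kept[, 2L] - ctr[2])^2) >=
                min_distance)) {
        kept <- rbind(kept, ctr)
        scores <- c(scores, sc[i])
        if (nrow(kept) >= max_count) break
      }
    }
    centers <- unname(kept)
  }
  structure(list(centers = centers, scores = scores,
                 box_size = c(th, tw), template_id = "template"),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> %d traps, box %dx%d\n", nrow(x$centers),
              x$box_size[1], x$box_size[2]))
  invisible(x)
}

#' Pick a template from a field of view by local contrast
#'
#' Fallback when no user template is available: scans frame 0 with a
#' half-box stride and returns the crop with the highest intensity
#' standard deviation.
#'
#' @param fov_image 2-D intensity matrix.
#' @param box_size (h, w) of the template.
#' @return list with `template` and `topleft` (0-based).
#' @export
autoselect_template <- function(fov_image, box_size = c(24L, 24L)) {
  h <- box_size[1]; w <- box_size[2]
  H <- nrow(fov_image); W <- ncol(fov_image)
  if (h > H || w > W) stop("invalid-input: box larger than image")
  best <- NULL; best_sd <- -Inf
  for (r in unique(c(seq(1L, H - h + 1L, by = max(1L, h %/% 2L)), H - h + 1L)))
    for (cc in unique(c(seq(1L, W - w + 1L, by = max(1L, w %/% 2L)),
                        W - w + 1L))) {
      crop <- fov_image[r:(r + h - 1L), cc:(cc + w - 1L)]
      s <- stats::sd(as.numeric(crop))
      if (s > best_sd) { best_sd <- s; best <- list(r = r, c = cc) }
    }
  list(template = fov_image[best$r:(best$r + h - 1L),
                            best$c:(best$c + w - 1L)],
       topleft = c(best$r - 1L, best$c - 1L))
}

#' Extract fixed-position per-trap time series from a FOV stack
#'
#' Boxes are centred on the frame-0 detections and kept fixed over time
#' (traps are stationary).
#'
#' @param fov_stack array (T, H, W) or (T, H, W, C).
#' @param rois a `roi_set` from [detect_trap_rois()].
#' @param frame_interval_min minutes per frame for the output movies.
#' @param channel_names passed to [trap_movie()].
#' @return list of [trap_movie()]s, one per ROI, ordered as `rois$centers`.
#' @export
extract_roi_timeseries <- function(fov_stack, rois, frame_interval_min = 5,
                                   channel_names = NULL) {
  if (length(dim(fov_stack)) == 3L) dim(fov_stack) <- c(dim(fov_stack), 1L)
  d <- dim(fov_stack)
  h <- rois$box_size[1]; w <- rois$box_size[2]
  out <- vector("list", nrow(rois$centers))
  for (i in seq_len(nrow(rois$centers))) {
    tl <- round(rois$centers[i, ] - c((h - 1) / 2, (w - 1) / 2))
    if (tl[1] < 0 || tl[2] < 0 || tl[1] + h > d[2] || tl[2] + w > d[3])
      stop("invalid-roi: box outside field-of-view bounds")
    out[[i]] <- trap_movie(
      fov_stack[, tl[1] + seq_len(h), tl[2] + seq_len(w), , drop = FALSE],
      frame_interval_min = frame_interval_min,
      channel_names = channel_names,
      roi_id = sprintf("roi%03d", i),
      origin = as.integer(tl))
  }
  out
}

#' Compose 1-3 z-planes into a 3-channel image
#'
#' Channel k is plane k in z order; with fewer than three planes the last
#' plane is replicated to fill the remaining channels.
#'
#' @param planes list of 1-3 single-channel H x W matrices of equal shape.
#' @return H x W x 3 array.
#' @export
compose_zstack_rgb <- function(planes) {
  if (!length(planes) || length(planes) > 3L)
    stop("invalid-input: need 1-3 planes")
  dims <- lapply(planes, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L)
    stop("invalid-input: planes must share H x W")
  while (length(planes) < 3L) planes[[length(planes) + 1L]] <-
      planes[[length(planes)]]
  array(c(planes[[1L]], planes[[2L]], planes[[3L]]),
        dim = c(dim(planes[[1L]]), 3L))
}
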