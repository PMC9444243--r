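# Core domain containers.  Lightweight S3 lists, in the style of survival's
# `Surv`/`survfit` objects: constructors validate invariants once, accessors
# and print methods keep the rest of the code honest.
#
# Frame indices are 0-based throughout the public records (frame 0 is the
# first acquired image), matching the pixel-coordinate convention.

#' Canonical cell/trap state classes
#'
#' The six per-frame states, in the fixed order used for every probability
#' matrix and confusion matrix in the package: unbudded mother, small-budded,
#' large-budded, dead, clogged trap, empty trap.
#'
#' @return character vector of the six class names, in canonical order.
#' @export
trap_classes <- function() {
  c("unbud", "small", "large", "dead", "clog", "empty")
}

#' Per-frame label sequence for one trap
#'
#' @param labels character vector of per-frame labels, each one of
#'   [trap_classes()].
#' @param probs optional T x 6 matrix of class probabilities (columns in
#'   canonical class order); each row must sum to 1 within 1e-6 and its
#'   argmax (ties broken by class order) must equal the label.
#' @param frame_interval_min acquisition interval in minutes.
#' @return a `label_sequence` object.
#' @export
label_sequence <- function(labels, probs = NULL, frame_interval_min = 5) {
  cls <- trap_classes()
  labels <- as.character(labels)
  if (length(labels) && !all(labels %in% cls))
    stop("invalid-input: unknown class label(s): ",
         paste(unique(setdiff(labels, cls)), collapse = ", "))
  if (!is.null(probs)) {
    probs <- as.matrix(probs)
    if (nrow(probs) != length(labels) || ncol(probs) != length(cls))
      stop("invalid-input: probs must be T x 6")
    if (any(abs(rowSums(probs) - 1) > 1e-6))
      stop("invalid-input: probability rows must sum to 1")
    am <- apply(probs, 1L, which.max)  # which.max breaks ties by first index
    if (length(labels) && !all(cls[am] == labels))
      stop("invalid-input: labels must equal argmax of probs")
    colnames(probs) <- cls
  }
  structure(list(labels = labels, probs = probs,
                 frame_interval_min = frame_interval_min),
            class = "label_sequence")
}

#' @export
length.label_sequence <- function(x) length(x$labels)

#' @export
print.label_sequence <- function(x, ...) {
  cat(sprintf("<label_sequence> %d frames @ %g min/frame\n",
              length(x$labels), x$frame_interval_min))
  tb <- table(factor(x$labels, levels = trap_classes()))
  print(tb)
  invisible(x)
}

#' One trap's image time series
#'
#' @param frames numeric array with dim (T, H, W, C); non-negative, finite.
#' @param frame_interval_min minutes between frames (> 0).
#' @param channel_names character vector of length C.
#' @param roi_id identifier string.
#' @param origin (row, col) of the ROI top-left in its parent field of view,
#'   0-based.
#' @return a `trap_movie` object.
#' @export
trap_movie <- function(frames, frame_interval_min = 5,
                       channel_names = NULL, roi_id = "roi",
                       origin = c(0L, 0L)) {
  if (length(dim(frames)) == 3L) dim(frames) <- c(dim(frames), 1L)
  if (length(dim(frames)) != 4L)
    stop("invalid-input: frames must be a T x H x W x C array")
  if (!all(is.finite(frames)))
    stop("invalid-input: non-finite intensities")
  if (dim(frames)[1] < 1L) stop("invalid-input: T must be >= 1")
  if (frame_interval_min <= 0)
    stop("invalid-parameter: frame_interval_min must be > 0")
  C <- dim(frames)[4]
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(C))
  if (length(channel_names) != C)
    stop("invalid-input: channel_names length must equal C")
  structure(list(frames = frames, frame_interval_min = frame_interval_min,
                 channel_names = channel_names, roi_id = roi_id,
                 origin = as.integer(origin)),
            class = "trap_movie")
}

#' @export
print.trap_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<trap_movie> %s: %d frames, %dx%d px, channels [%s], %g min/frame\n",
              x$roi_id, d[1], d[2], d[3],
              paste(x$channel_names, collapse = ", "),
              x$frame_interval_min))
  invisible(x)
}

# Pull one channel of one frame as an H x W matrix.
movie_frame <- function(movie, t, channel = 1L) {
  matrix(movie$frames[t, , , channel],
         dim(movie$frames)[2], dim(movie$frames)[3])
}

#' Per-pixel segmentation result for one frame
#'
#' @param class_map H x W integer matrix of class codes (0 = background;
#'   brightfield: 1 mother, 2 other; fluorescence: 1 nucleus).
#' @param prob_maps H x W x K array of per-class probabilities (canonical
#'   order of `class_set`), rows summing to 1 per pixel within 1e-6.
#' @param class_set character vector naming the codes, starting at 0.
#' @param threshold_used scalar in (0,1) used for the target class.
#' @return a `segmentation_mask` object.
#' @export
segmentation_mask <- function(class_map, prob_maps = NULL,
                              class_set = c("background", "mother", "other"),
                              threshold_used = NA_real_) {
  class_map <- as.matrix(class_map)
  storage.mode(class_map) <- "integer"
  if (any(class_map < 0L | class_map >= length(class_set)))
    stop("invalid-label: class_map contains codes outside the class set")
  if (!is.null(prob_maps)) {
    s <- apply(prob_maps, c(1, 2), sum)
    if (any(abs(s - 1) > 1e-6))
      stop("invalid-input: prob_maps must sum to 1 per pixel")
  }
  structure(list(class_map = class_map, prob_maps = prob_maps,
                 class_set = class_set, threshold_used = threshold_used),
            class = "segmentation_mask")
}

#' Per-cell lifespan record
#'
#' Produced by [reconstruct_lifespan()]; see that function for the stop
#' rules.  All frame indices are 0-based.
#'
#' @param roi_id identifier.
#' @param budding_frames strictly increasing 0-based frame indices of
#'   generation onsets.
#' @param death_frame frame of death, or `NA` if none observed.
#' @param end_reason one of dead, arrest, clog, empty, end_of_movie.
#' @param frame_interval_min minutes per frame.
#' @param skipped_small_events frames where a generation was counted from an
#'   unbud-to-large transition (the intermediate small state was not seen).
#' @return a `lifespan_record`; `rls` is the number of budding events,
#'   `cycle_durations_min` the successive inter-budding intervals in minutes,
#'   `censored` is `TRUE` iff the movie ended first, and `excluded` flags
#'   clog/empty records that must not enter survival analyses.
#' @export
lifespan_record <- function(roi_id, budding_frames, death_frame = NA_integer_,
                            end_reason = "end_of_movie",
                            frame_interval_min = 5,
                            skipped_small_events = integer(0)) {
  budding_frames <- as.integer(budding_frames)
  if (is.unsorted(budding_frames, strictly = TRUE))
    stop("invalid-input: budding_frames must be strictly increasing")
  reasons <- c("dead", "arrest", "clog", "empty", "end_of_movie")
  if (!end_reason %in% reasons)
    stop("invalid-input: unknown end_reason ", end_reason)
  if (!is.na(death_frame) && length(budding_frames) &&
      any(budding_frames >= death_frame))
    stop("invalid-input: budding_frames must precede death_frame")
  structure(list(
    roi_id = roi_id,
    budding_frames = budding_frames,
    cycle_durations_min = diff(budding_frames) * frame_interval_min,
    death_frame = as.integer(death_frame),
    end_reason = end_reason,
    censored = identical(end_reason, "end_of_movie"),
    excluded = end_reason %in% c("clog", "empty"),
    rls = length(budding_frames),
    frame_interval_min = frame_interval_min,
    skipped_small_events = as.integer(skipped_small_events)
  ), class = "lifespan_record")
}

#' @export
print.lifespan_record <- function(x, ...) {
  cat(sprintf("<lifespan_record> %s: RLS %d, end %s%s%s\n",
              x$roi_id, x$rls, x$end_reason,
              if (x$censored) " (censored)" else "",
              if (x$excluded) " [excluded]" else ""))
  invisible(x)
}
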