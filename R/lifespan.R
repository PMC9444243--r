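# Division counting and replicative-lifespan reconstruction from per-frame
# class label sequences.  A new generation starts when the mother re-enters
# the small-budded state from the large or unbudded state; the lifespan ends
# at the earliest of: a dead frame, a division arrest longer than the arrest
# window, a clogged-trap frame, or an empty-trap frame.  Frame indices are
# 0-based.

#' Detect budding events in a label sequence
#'
#' An event is scored at every frame `t` with label `small` whose
#' predecessor is `large` or `unbud` (the oscillation that marks entry into
#' a new cell cycle).  With `skipped_small = TRUE` (default) a direct
#' `unbud` to `large` transition, where the short small-budded phase fell
#' between two acquisitions, is also counted as one event at the `large`
#' frame; those frames are returned in attribute `skipped_small_events`.
#'
#' @param labels a [label_sequence()] or character vector of labels.
#' @param skipped_small enable the skipped-'small' fallback.
#' @return integer vector of 0-based event frames (attribute
#'   `skipped_small_events` marks fallback events).
#' @export
detect_budding_events <- function(labels, skipped_small = TRUE) {
  lab <- if (inherits(labels, "label_sequence")) labels$labels else labels
  T <- length(lab)
  if (T < 2L) {
    out <- integer(0)
    attr(out, "skipped_small_events") <- integer(0)
    return(out)
  }
  prev <- lab[-T]
  cur <- lab[-1L]
  ev <- which(cur == "small" & prev %in% c("large", "unbud"))  # 0-based frame
  skipped <- integer(0)
  if (isTRUE(skipped_small)) {
    skipped <- which(cur == "large" & prev == "unbud")
    ev <- sort(unique(c(ev, skipped)))
  }
  out <- as.integer(ev)
  attr(out, "skipped_small_events") <- as.integer(skipped)
  out
}

#' Reconstruct a replicative lifespan from a label sequence
#'
#' Applies the optional CNN post-processing first (`pp_mode = "cnn_pp"`
#' relabels isolated dead frames, so two consecutive dead frames are needed
#' to end the lifespan), then scans for the earliest stop condition among:
#' (1) a dead frame, (2) division arrest for more than `arrest_hours`
#' without a new budding event, (3) a clogged-trap frame, (4) an empty-trap
#' frame.  Clog/empty records are flagged `excluded` and must not enter
#' survival analyses; sequences reaching the last frame without a stop are
#' right-censored (`end_reason = "end_of_movie"`).
#'
#' For an arrest stop the death frame is set to the last budding event plus
#' the arrest window — the latest frame the cell was known to divide plus
#' the declared horizon.
#'
#' @param labels a [label_sequence()].
#' @param arrest_hours division-arrest window, hours (default 10).
#' @param pp_mode `"none"` or `"cnn_pp"`.
#' @param skipped_small passed to [detect_budding_events()].
#' @param roi_id identifier stored in the record.
#' @return a [lifespan_record()].
#' @export
reconstruct_lifespan <- function(labels, arrest_hours = 10,
                                 pp_mode = c("none", "cnn_pp"),
                                 skipped_small = TRUE, roi_id = "roi") {
  stopifnot(inherits(labels, "label_sequence"))
  pp_mode <- match.arg(pp_mode)
  if (is.null(labels$frame_interval_min) || labels$frame_interval_min <= 0)
    stop("invalid-parameter: frame_interval_min must be set and > 0")
  if (pp_mode == "cnn_pp") labels <- postprocess_cnn_labels(labels)
  lab <- labels$labels
  T <- length(lab)
  interval <- labels$frame_interval_min
  arrest_frames <- ceiling(arrest_hours * 60 / interval)

  events <- detect_budding_events(lab, skipped_small = skipped_small)
  skipped <- attr(events, "skipped_small_events")

  dead_at <- first_or_na(which(lab == "dead")) - 1L
  clog_at <- first_or_na(which(lab == "clog")) - 1L
  empty_at <- first_or_na(which(lab == "empty")) - 1L

  # arrest trigger: first frame more than arrest_frames after the last
  # budding event (frame 0 if none) with no new event in between
  anchors <- c(0L, events)
  # the event-free frames after anchor k run up to gap_last[k]
  gap_last <- c(events - 1L, T - 1L)
  arrest_at <- NA_integer_
  for (k in seq_along(anchors)) {
    trigger <- anchors[k] + arrest_frames + 1L
    if (trigger <= gap_last[k]) { arrest_at <- trigger; break }
  }

  stops <- c(dead = dead_at, arrest = arrest_at, clog = clog_at,
             empty = empty_at)
  if (all(is.na(stops))) {
    end_reason <- "end_of_movie"
    stop_frame <- T            # exclusive
    death_frame <- NA_integer_
  } else {
    w <- which.min(stops)      # earliest frame; ties broken in rule order
    end_reason <- names(stops)[w]
    stop_frame <- stops[[w]]
    death_frame <- switch(end_reason,
      dead = stop_frame,
      arrest = {
        last_ev <- if (any(events < stop_frame))
          max(events[events < stop_frame]) else 0L
        last_ev + arrest_frames
      },
      NA_integer_)
  }
  keep <- events[events < stop_frame]
  lifespan_record(roi_id, keep, death_frame = death_frame,
                  end_reason = end_reason, frame_interval_min = interval,
                  skipped_small_events = intersect(skipped, keep))
}

first_or_na <- function(x) if (length(x)) x[1L] else NA_integer_

#' Align per-cell trajectories on an anchor index
#'
#' Shifts each record's value trace so its anchor position maps to aligned
#' index 0, then computes the mean, standard error and count at every
#' aligned index over the records that cover it.  Used to average cycle
#' durations around the SEP or around birth.
#'
#' @param traces list of numeric vectors (e.g. per-generation cycle
#'   durations).
#' @param anchors integer vector, one per trace: the 1-based position within
#'   the trace that maps to aligned index 0 (`NA` anchors are skipped and
#'   counted in attribute `n_skipped`).
#' @return list with `index` (aligned indices), `matrix` (records x index),
#'   `mean`, `sem`, `n`.
#' @export
align_trajectories <- function(traces, anchors) {
  stopifnot(length(traces) == length(anchors))
  ok <- !is.na(anchors)
  n_skipped <- sum(!ok)
  if (n_skipped > 0)
    warning(sprintf("%d record(s) missing an anchor were skipped", n_skipped))
  traces <- traces[ok]
  anchors <- anchors[ok]
  if (!length(traces)) stop("invalid-input: no records with anchors")
  lo <- min(1 - anchors)
  hi <- max(lengths(traces) - anchors)
  idx <- seq.int(lo, hi)
  M <- matrix(NA_real_, length(traces), length(idx))
  for (i in seq_along(traces)) {
    pos <- seq_along(traces[[i]]) - anchors[i]     # aligned indices covered
    M[i, match(pos, idx)] <- traces[[i]]
  }
  n <- colSums(!is.na(M))
  mu <- colMeans(M, na.rm = TRUE)
  mu[n == 0] <- NA_real_
  sdv <- apply(M, 2L, stats::sd, na.rm = TRUE)
  sem <- ifelse(n > 0, sdv / sqrt(n), NA_real_)
  sem[n == 1] <- 0
  out <- list(index = idx, matrix = M, mean = mu, sem = sem, n = n)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Fraction of dead cells over time
#'
#' @param records list of [lifespan_record()]s sharing a frame interval;
#'   clog/empty (excluded) records are dropped.
#' @param T number of frames.
#' @return numeric vector of length `T`: at frame `t` (0-based), the
#'   fraction of cells with `death_frame <= t`; non-decreasing.
#' @export
death_fraction_trace <- function(records, T) {
  records <- Filter(function(r) !r$excluded, records)
  if (!length(records)) stop("empty-input: no non-excluded records")
  iv <- vapply(records, function(r) r$frame_interval_min, numeric(1))
  if (length(unique(iv)) != 1L)
    stop("invalid-input: records must share a frame interval")
  deaths <- vapply(records, function(r)
    if (is.na(r$death_frame)) Inf else as.numeric(r$death_frame), numeric(1))
  vapply(seq_len(T) - 1L, function(t) mean(deaths <= t), numeric(1))
}
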