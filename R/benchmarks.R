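# Classifier and division-detection benchmarking: confusion matrices,
# per-class precision/recall/F1, tolerance-bounded one-to-one pairing of
# generation events, and correlation metrics.  Undefined metrics (empty
# class, zero predictions) are reported as NA, never as 0.

#' Confusion matrix over the six canonical classes
#'
#' @param true_labels,pred_labels equal-length label vectors (or
#'   [label_sequence()]s); rows are truth, columns predictions, both in
#'   canonical class order.
#' @return 6 x 6 integer matrix of counts.
#' @export
confusion_matrix <- function(true_labels, pred_labels) {
  tl <- if (inherits(true_labels, "label_sequence")) true_labels$labels
        else true_labels
  pl <- if (inherits(pred_labels, "label_sequence")) pred_labels$labels
        else pred_labels
  if (length(tl) != length(pl))
    stop("invalid-input: label vectors must have equal length")
  cls <- trap_classes()
  tab <- table(factor(tl, levels = cls), factor(pl, levels = cls))
  m <- matrix(as.integer(tab), 6L, 6L, dimnames = list(truth = cls,
                                                       prediction = cls))
  m
}

#' Per-class precision, recall and F1 from a confusion matrix
#'
#' Precision is the fraction of correct predictions among all predictions
#' for a class, recall the fraction of detected observations among all
#' observations, and F1 their harmonic mean.  A class with zero predictions
#' has `NA` precision; zero observations give `NA` recall.
#'
#' @param confusion square count matrix (rows truth, columns prediction).
#' @return data.frame with columns `class`, `precision`, `recall`, `f1`.
#' @export
class_metrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (any(confusion < 0)) stop("invalid-input: negative counts")
  tp <- diag(confusion)
  pred <- colSums(confusion)
  truth <- rowSums(confusion)
  precision <- ifelse(pred > 0, tp / pred, NA_real_)
  recall <- ifelse(truth > 0, tp / truth, NA_real_)
  f1 <- ifelse(!is.na(precision) & !is.na(recall) & (precision + recall) > 0,
               2 * precision * recall / (precision + recall), NA_real_)
  data.frame(class = rownames(confusion) %||% as.character(seq_along(tp)),
             precision = unname(precision), recall = unname(recall),
             f1 = unname(f1))
}

#' Pair true and predicted generation events within a frame tolerance
#'
#' Finds the one-to-one matching between ascending true and predicted event
#' frames with `|offset| <= tolerance_frames` that first maximises the
#' number of matched pairs and then minimises the total absolute offset
#' (optimal assignment; for sorted inputs and absolute-difference costs the
#' optimum can be taken non-crossing, which the dynamic program exploits).
#' Unmatched predictions are false positives, unmatched truths false
#' negatives.
#'
#' @param true_events,pred_events ascending integer frame vectors.
#' @param tolerance_frames maximum |offset| for a valid pair (default 2:
#'   unambiguous at ~18 frames per cycle).
#' @return list with `tp`, `fp`, `fn`, `pairs` (data.frame of
#'   `true_frame`, `pred_frame`, `offset`), `precision`, `recall` (NA when
#'   undefined).
#' @export
pair_generation_events <- function(true_events, pred_events,
                                   tolerance_frames = 2L) {
  if (is.unsorted(true_events) || is.unsorted(pred_events))
    stop("invalid-input: event lists must be ascending")
  if (tolerance_frames < 0) stop("invalid-parameter: tolerance must be >= 0")
  n <- length(true_events); m <- length(pred_events)
  M <- matrix(0L, n + 1L, m + 1L)       # max matches
  Cst <- matrix(0, n + 1L, m + 1L)      # min cost at that match count
  for (i in seq_len(n)) for (j in seq_len(m)) {
    # skip true i or pred j
    best_m <- M[i, j + 1L]; best_c <- Cst[i, j + 1L]
    if (M[i + 1L, j] > best_m ||
        (M[i + 1L, j] == best_m && Cst[i + 1L, j] < best_c)) {
      best_m <- M[i + 1L, j]; best_c <- Cst[i + 1L, j]
    }
    off <- abs(true_events[i] - pred_events[j])
    if (off <= tolerance_frames) {
      cand_m <- M[i, j] + 1L
      cand_c <- Cst[i, j] + off
      if (cand_m > best_m || (cand_m == best_m && cand_c < best_c)) {
        best_m <- cand_m; best_c <- cand_c
      }
    }
    M[i + 1L, j + 1L] <- best_m
    Cst[i + 1L, j + 1L] <- best_c
  }
  # backtrack (prefer matching, then skipping the later-indexed list)
  pairs <- NULL
  i <- n; j <- m
  while (i > 0L && j > 0L) {
    off <- abs(true_events[i] - pred_events[j])
    if (off <= tolerance_frames && M[i + 1L, j + 1L] == M[i, j] + 1L &&
        abs(Cst[i + 1L, j + 1L] - (Cst[i, j] + off)) < 1e-9) {
      pairs <- rbind(c(true_events[i], pred_events[j]), pairs)
      i <- i - 1L; j <- j - 1L
    } else if (M[i + 1L, j + 1L] == M[i, j + 1L] &&
               Cst[i + 1L, j + 1L] == Cst[i, j + 1L]) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  tp <- M[n + 1L, m + 1L]
  pairs <- if (is.null(pairs))
    data.frame(true_frame = integer(0), pred_frame = integer(0),
               offset = integer(0))
  else
    data.frame(true_frame = pairs[, 1], pred_frame = pairs[, 2],
               offset = pairs[, 2] - pairs[, 1])
  list(tp = tp, fp = m - tp, fn = n - tp, pairs = pairs,
       total_offset = Cst[n + 1L, m + 1L],
       precision = if (m > 0) tp / m else NA_real_,
       recall = if (n > 0) tp / n else NA_real_)
}

#' Squared Pearson correlation
#'
#' @param x,y equal-length numeric vectors (length >= 2, non-constant).
#' @return scalar R-squared.
#' @export
correlation_r2 <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    stop("invalid-input: need equal lengths >= 2")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined-correlation: constant vector")
  stats::cor(x, y)^2
}

#' Benchmark a full set of predictions against groundtruth scenes
#'
#' Aggregates, over the ROIs common to both inputs: the frame-level
#' confusion matrix and per-class metrics, generation-event pairing
#' (TP/FP/FN, precision/recall), the correlation of paired cycle durations
#' and of per-cell RLS, a rank-sum test on the pooled cycle-duration
#' distributions, and a log-rank test on the two survival curves.
#'
#' @param truth named list (by roi_id) of `cell_history` objects or
#'   [label_sequence()]s.
#' @param predictions named list (by roi_id) of [label_sequence()]s.
#' @param tolerance_frames event-pairing tolerance.
#' @param pp_mode post-processing applied when reconstructing predicted
#'   lifespans (see [reconstruct_lifespan()]).
#' @param arrest_hours arrest window for lifespan reconstruction.
#' @return a `benchmark_report` list: `confusion`, `per_class`,
#'   `event_pairing`, `cycle_r2`, `rls_r2`, `ranksum`, `logrank`, `n_roi`.
#' @export
benchmark_pipeline <- function(truth, predictions, tolerance_frames = 2L,
                               pp_mode = "none", arrest_hours = 10) {
  ids <- intersect(names(truth), names(predictions))
  if (!length(ids)) stop("invalid-input: no common roi_ids")
  tl <- character(0); pl <- character(0)
  tp <- fp <- fn <- 0L
  t_dur <- p_dur <- numeric(0)
  t_rls <- p_rls <- numeric(0)
  t_rec <- list(); p_rec <- list()
  pair_true <- pair_pred <- numeric(0)
  for (id in ids) {
    tru <- truth[[id]]
    prd <- predictions[[id]]
    iv <- prd$frame_interval_min
    if (inherits(tru, "cell_history")) {
      t_lab <- tru$per_frame_labels
      t_ls <- label_sequence(t_lab, frame_interval_min = tru$frame_interval_min)
    } else {
      t_ls <- tru
      t_lab <- tru$labels
    }
    tl <- c(tl, t_lab)
    pl <- c(pl, prd$labels)
    rt <- reconstruct_lifespan(t_ls, arrest_hours = arrest_hours,
                               roi_id = id)
    rp <- reconstruct_lifespan(prd, arrest_hours = arrest_hours,
                               pp_mode = pp_mode, roi_id = id)
    t_rec[[id]] <- rt
    p_rec[[id]] <- rp
    pr <- pair_generation_events(rt$budding_frames, rp$budding_frames,
                                 tolerance_frames)
    tp <- tp + pr$tp; fp <- fp + pr$fp; fn <- fn + pr$fn
    # durations between consecutive events whose endpoints are both matched
    if (nrow(pr$pairs) >= 2) {
      it <- match(pr$pairs$true_frame, rt$budding_frames)
      consec <- which(diff(it) == 1L)
      if (length(consec)) {
        t_dur <- c(t_dur, diff(pr$pairs$true_frame)[consec] * iv)
        p_dur <- c(p_dur, diff(pr$pairs$pred_frame)[consec] * iv)
      }
    }
    if (!rt$excluded && !rp$excluded) {
      t_rls <- c(t_rls, rt$rls)
      p_rls <- c(p_rls, rp$rls)
    }
  }
  conf <- confusion_matrix(tl, pl)
  all_t_dur <- unlist(lapply(t_rec, function(r) r$cycle_durations_min))
  all_p_dur <- unlist(lapply(p_rec, function(r) r$cycle_durations_min))
  structure(list(
    confusion = conf,
    per_class = class_metrics(conf),
    event_pairing = list(tp = tp, fp = fp, fn = fn,
                         precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
                         recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_),
    cycle_r2 = if (length(t_dur) >= 2 && stats::sd(t_dur) > 0 &&
                   stats::sd(p_dur) > 0)
      correlation_r2(t_dur, p_dur) else NA_real_,
    rls_r2 = if (length(t_rls) >= 2 && stats::sd(t_rls) > 0 &&
                 stats::sd(p_rls) > 0)
      correlation_r2(t_rls, p_rls) else NA_real_,
    ranksum = if (length(all_t_dur) && length(all_p_dur))
      ranksum_test(all_t_dur, all_p_dur) else NULL,
    logrank = tryCatch(logrank_test(t_rec, p_rec), error = function(e) NULL),
    true_records = t_rec, pred_records = p_rec,
    n_roi = length(ids)
  ), class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf("<benchmark_report> %d ROIs\n", x$n_roi))
  print(x$per_class, digits = 3)
  ep <- x$event_pairing
  cat(sprintf("events: TP %d FP %d FN %d (precision %.3f recall %.3f)\n",
              ep$tp, ep$fp, ep$fn, ep$precision, ep$recall))
  cat(sprintf("cycle-duration R2 %.3f, RLS R2 %.3f\n", x$cycle_r2, x$rls_r2))
  if (!is.null(x$ranksum))
    cat(sprintf("rank-sum p %.3g; log-rank p %.3g\n", x$ranksum$p,
                if (!is.null(x$logrank)) x$logrank$p else NA))
  invisible(x)
}
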