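# Senescence Entry Point (SEP) detection: a sequence-to-sequence
# bidirectional LSTM assigns pre-SEP / post-SEP to every frame of a
# lifespan from the image classifier's class-probability sequence; the raw
# per-frame calls are then reduced to a single changepoint.  A rule-based
# detector on cycle durations serves as an independent oracle for testing.
# Generation indices are 0-based (generation 0 is the first cycle).

# Reduce raw per-frame binary states to the single changepoint minimising
# disagreement: predict pre for t < s, post for t >= s, over s in 0..T;
# ties -> earliest s.  Returns the 0-based first-post frame, or NA when the
# best split is the sequence end (no post phase).
sep_changepoint <- function(is_post) {
  T <- length(is_post)
  x <- as.integer(is_post)
  # cost(s) = #post before s + #pre from s on, s = 0..T
  post_before <- c(0L, cumsum(x))
  pre_after <- rev(c(0L, cumsum(rev(1L - x))))
  cost <- post_before + pre_after
  s <- which.min(cost) - 1L
  if (s >= T) NA_integer_ else s
}

new_sep_record <- function(sep_frame, T, method, budding_frames = NULL) {
  state <- rep("pre", T)
  if (!is.na(sep_frame) && sep_frame < T)
    state[(sep_frame + 1L):T] <- "post"
  sep_gen <- NA_integer_
  if (!is.na(sep_frame) && !is.null(budding_frames) && length(budding_frames))
    sep_gen <- sum(budding_frames <= sep_frame) - 1L
  structure(list(sep_frame = sep_frame, sep_generation = sep_gen,
                 per_frame_state = state, method = method),
            class = "sep_record")
}

#' @export
print.sep_record <- function(x, ...) {
  cat(sprintf("<sep_record> (%s) SEP frame %s, generation %s\n", x$method,
              ifelse(is.na(x$sep_frame), "-", x$sep_frame),
              ifelse(is.na(x$sep_generation), "-", x$sep_generation)))
  invisible(x)
}

# Extract the 4-column (unbud, small, large, dead) probability matrix and
# the clog/empty frame mask from a label_sequence.  One-hot when the
# sequence carries no probabilities.
probs4 <- function(ls) {
  cls <- trap_classes()
  T <- length(ls$labels)
  if (!is.null(ls$probs)) {
    p <- ls$probs[, 1:4, drop = FALSE]
    rs <- rowSums(p)
    p[rs > 1e-8, ] <- p[rs > 1e-8, , drop = FALSE] / rs[rs > 1e-8]
    p[rs <= 1e-8, ] <- 1 / 4
  } else {
    p <- matrix(0, T, 4L)
    ii <- match(ls$labels, cls)
    live <- ii <= 4L
    p[cbind(which(live), ii[live])] <- 1
    p[!live, ] <- 1 / 4
  }
  list(p = p, mask = !(ls$labels %in% c("clog", "empty")))
}

#' Train the SEP sequence-to-sequence classifier
#'
#' Fits a bidirectional LSTM that labels every frame of a lifespan as
#' pre-SEP or post-SEP from the 4-class (unbud/small/large/dead)
#' probability sequence produced by the image classifier.  Clogged/empty
#' frames are masked out of the loss.
#'
#' @param sequences list of [label_sequence()]s carrying class
#'   probabilities (one-hot is used when absent).
#' @param states list of character vectors (`"pre"`/`"post"`), one per
#'   frame per sequence.
#' @param hidden LSTM hidden width (default 150).
#' @param epochs,lr,batch_size Adam training schedule.
#' @param seed integer seed.
#' @return a fitted `sep_lstm` model.
#' @export
train_sep_lstm <- function(sequences, states, hidden = 150L, epochs = 40L,
                           lr = 5e-3, batch_size = 16L, seed = 1L) {
  stopifnot(length(sequences) == length(states))
  N <- length(sequences)
  if (N < 1L) stop("invalid-input: no training sequences")
  Ts <- vapply(sequences, function(s) length(s$labels), integer(1))
  if (!all(vapply(states, length, integer(1)) == Ts))
    stop("invalid-input: states and sequences must align per frame")
  if (any(vapply(states, function(s) length(unique(s)) == 1L, logical(1))))
    warning("degenerate-training: sequence(s) containing a single state kept")
  TT <- max(Ts)
  x <- array(0, dim = c(N, TT, 4L))
  lab <- matrix(1L, N, TT)
  mask <- matrix(FALSE, N, TT)
  for (i in seq_len(N)) {
    p4 <- probs4(sequences[[i]])
    x[i, seq_len(Ts[i]), ] <- p4$p
    lab[i, seq_len(Ts[i])] <- ifelse(states[[i]] == "post", 2L, 1L)
    mask[i, seq_len(Ts[i])] <- p4$mask
  }
  mod <- bilstm_train(x, lab, K = 2L, hidden = hidden, epochs = epochs,
                      lr = lr, seed = seed, mask = mask,
                      batch_size = batch_size)
  structure(list(net = mod, hidden = as.integer(hidden),
                 epochs = as.integer(epochs), lr = lr, seed = as.integer(seed),
                 classes = c("pre_sep", "post_sep"), fitted = TRUE),
            class = "sep_lstm")
}

#' Predict the SEP for one cell
#'
#' Runs the fitted model over the probability sequence, then reduces the
#' raw per-frame pre/post calls to a single changepoint (the split
#' minimising disagreement with the raw predictions; ties resolved to the
#' earliest frame, favouring sensitivity).  The SEP is absent when the
#' best split is the sequence end.
#'
#' @param model a fitted `sep_lstm`.
#' @param sequence a [label_sequence()] with class probabilities.
#' @param budding_frames optional 0-based budding event frames used to
#'   report `sep_generation`.
#' @return a `sep_record`.
#' @export
predict_sep <- function(model, sequence, budding_frames = NULL) {
  if (!inherits(model, "sep_lstm") || !isTRUE(model$fitted))
    stop("not-fitted: model must be a fitted sep_lstm")
  T <- length(sequence$labels)
  if (T < 1L) stop("invalid-input: empty sequence")
  p4 <- probs4(sequence)
  pr <- bilstm_predict(model$net, p4$p)
  raw_post <- pr[, 2L] > pr[, 1L]
  s <- sep_changepoint(raw_post)
  new_sep_record(s, T, "lstm", budding_frames)
}

#' Rule-based SEP oracle on cycle durations
#'
#' Flags the SEP at the first generation whose cycle duration exceeds
#' `factor` times the median of all prior durations and stays elevated
#' (same criterion) for at least 2 of the next 3 generations (all available
#' ones when fewer remain; at least 1 must remain).  Needs >= 3 cycles.
#'
#' @param cycle_durations per-generation cycle durations (minutes),
#'   generation 0 first.
#' @param factor threshold multiplier (default 1.5).
#' @param budding_frames optional, for `sep_frame` reporting.
#' @return a `sep_record` with `sep_generation` set (0-based); SEP absent
#'   when no generation qualifies or fewer than 3 cycles exist.
#' @export
sep_rule_oracle <- function(cycle_durations, factor = 1.5,
                            budding_frames = NULL) {
  G <- length(cycle_durations)
  T <- if (!is.null(budding_frames) && length(budding_frames))
    max(budding_frames) + 1L else G
  if (G < 3L) return(new_sep_record(NA_integer_, T, "rule", budding_frames))
  for (pos in 2:G) {
    med <- stats::median(cycle_durations[seq_len(pos - 1L)])
    if (cycle_durations[pos] <= factor * med) next
    nxt <- seq.int(pos + 1L, length.out = min(3L, G - pos))
    if (!length(nxt)) next
    need <- min(2L, length(nxt))
    if (sum(cycle_durations[nxt] > factor * med) >= need) {
      sep_gen <- pos - 1L   # 0-based generation index
      sep_frame <- if (!is.null(budding_frames) &&
                       length(budding_frames) >= pos)
        budding_frames[pos] else NA_integer_
      rec <- new_sep_record(if (is.na(sep_frame)) NA_integer_ else sep_frame,
                            T, "rule", budding_frames)
      rec$sep_generation <- sep_gen
      return(rec)
    }
  }
  new_sep_record(NA_integer_, T, "rule", budding_frames)
}
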