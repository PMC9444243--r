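# Independent oracles used across the suite.  These re-derive expected
# results by brute force or literal rule-following, sharing no code with
# the implementation paths they check.

# Literal frame-by-frame stop-rule scan (lifespan reconstruction oracle).
# Walks the sequence once, keeping its own event bookkeeping.
oracle_lifespan <- function(labels, interval, arrest_hours = 10,
                            skipped_small = TRUE) {
  T <- length(labels)
  arrest_frames <- ceiling(arrest_hours * 60 / interval)
  events <- integer(0)
  last_anchor <- 0L
  stop_frame <- NA_integer_
  end_reason <- "end_of_movie"
  for (t in seq_len(T) - 1L) {
    lab <- labels[t + 1L]
    is_event <- t >= 1L && lab == "small" &&
      labels[t] %in% c("large", "unbud")
    if (skipped_small && t >= 1L && lab == "large" && labels[t] == "unbud")
      is_event <- TRUE
    # stop rules in declared precedence at this frame
    if (lab == "dead") { stop_frame <- t; end_reason <- "dead"; break }
    if (!is_event && (t - last_anchor) > arrest_frames) {
      stop_frame <- t; end_reason <- "arrest"; break
    }
    if (lab == "clog") { stop_frame <- t; end_reason <- "clog"; break }
    if (lab == "empty") { stop_frame <- t; end_reason <- "empty"; break }
    if (is_event) { events <- c(events, t); last_anchor <- t }
  }
  if (is.na(stop_frame)) stop_frame <- T
  list(events = events[events < stop_frame], end_reason = end_reason,
       stop_frame = stop_frame)
}

# Exhaustive one-to-one event matching: maximise matches, then minimise
# total |offset|, over all subsets/injections (recursion over true events).
oracle_pairing <- function(true_events, pred_events, tol) {
  n <- length(true_events); m <- length(pred_events)
  best <- list(matches = -1L, cost = Inf)
  recurse <- function(i, used, matches, cost) {
    if (i > n) {
      if (matches > best$matches ||
          (matches == best$matches && cost < best$cost))
        best <<- list(matches = matches, cost = cost)
      return(invisible())
    }
    recurse(i + 1L, used, matches, cost)            # leave true i unmatched
    for (j in seq_len(m)) {
      if (used[j]) next
      off <- abs(true_events[i] - pred_events[j])
      if (off <= tol) {
        used[j] <- TRUE
        recurse(i + 1L, used, matches + 1L, cost + off)
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, m), 0L, 0)
  best
}

# Exhaustive changepoint search: best split s in 0..T by disagreement,
# ties to the earliest.
oracle_changepoint <- function(is_post) {
  T <- length(is_post)
  best_s <- NA_integer_; best_c <- Inf
  for (s in 0:T) {
    pred <- c(rep(FALSE, s), rep(TRUE, T - s))
    cost <- sum(pred != is_post)
    if (cost < best_c) { best_c <- cost; best_s <- s }
  }
  if (best_s >= T) NA_integer_ else best_s
}

# Random live-biased label sequence for stop-rule fuzzing.
random_labels <- function(T, seed) {
  withr::with_seed(seed, {
    sample(trap_classes(), T, replace = TRUE,
           prob = c(0.10, 0.30, 0.40, 0.10, 0.05, 0.05))
  })
}

# Small synthetic cohorts used by several files.
make_cohort <- function(n, seed0 = 1L, params = synth_params()) {
  lapply(seq_len(n), function(i)
    simulate_cell_history(params, seed = seed0 + i))
}

# Lifespan records drawn from a geometric law (death probability p per
# generation), built directly for survival-statistics tests.
geometric_records <- function(n, p, seed) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      k <- stats::rgeom(1L, p) + 1L     # RLS >= 1, mean 1/p
      lifespan_record(sprintf("g%04d", i),
                      budding_frames = seq_len(k) * 10L,
                      death_frame = (k + 1L) * 10L,
                      end_reason = "dead")
    })
  })
}
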