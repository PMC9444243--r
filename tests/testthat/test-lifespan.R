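# Budding-event detection, stop rules, trajectory alignment, death traces.

test_that("budding events follow the oscillation rule", {
  ev <- detect_budding_events(c("unbud", "unbud", "small", "small", "large",
                                "large", "small", "small", "large"))
  expect_equal(as.integer(ev), c(2L, 6L))
  expect_equal(detect_budding_events(rep("large", 20)), integer(0),
               ignore_attr = TRUE)
  # skipped-'small' fallback: unbud -> large counts one flagged event
  ev <- detect_budding_events(c("unbud", "large", "small"))
  expect_equal(as.integer(ev), c(1L, 2L))
  expect_equal(attr(ev, "skipped_small_events"), 1L)
  ev2 <- detect_budding_events(c("unbud", "large", "small"),
                               skipped_small = FALSE)
  expect_equal(as.integer(ev2), 2L)
})

test_that("stop rules fire at the earliest trigger", {
  # one event then 125 'large' frames at 5 min: > 10 h without an event
  lab <- c("unbud", "small", rep("large", 125))
  rec <- reconstruct_lifespan(label_sequence(lab, frame_interval_min = 5))
  expect_equal(rec$end_reason, "arrest")
  expect_equal(rec$rls, 1L)
  expect_equal(rec$death_frame, 1L + 120L)  # last event + arrest window
  expect_false(rec$censored)

  rec <- reconstruct_lifespan(label_sequence(
    c("unbud", "small", "large", "dead", "dead"), frame_interval_min = 5))
  expect_equal(rec$end_reason, "dead")
  expect_equal(rec$death_frame, 3L)
  expect_equal(rec$rls, 1L)

  rec <- reconstruct_lifespan(label_sequence(
    c("unbud", "small", "large", "clog", "clog"), frame_interval_min = 5))
  expect_equal(rec$end_reason, "clog")
  expect_true(rec$excluded)

  rec <- reconstruct_lifespan(label_sequence(
    rep(c("small", "large"), 10), frame_interval_min = 5))
  expect_equal(rec$end_reason, "end_of_movie")
  expect_true(rec$censored)
})

test_that("stop-rule precedence matches a brute-force frame scan", {
  for (i in 1:300) {
    lab <- random_labels(200L, seed = 5000L + i)
    rec <- reconstruct_lifespan(label_sequence(lab, frame_interval_min = 5))
    orc <- oracle_lifespan(lab, 5)
    expect_equal(rec$end_reason, orc$end_reason, info = paste("seed", i))
    expect_equal(rec$budding_frames, as.integer(orc$events),
                 info = paste("seed", i))
  }
  # short intervals exercise large arrest windows in frames
  for (i in 1:100) {
    lab <- random_labels(80L, seed = 9000L + i)
    rec <- reconstruct_lifespan(label_sequence(lab, frame_interval_min = 20))
    orc <- oracle_lifespan(lab, 20)
    expect_equal(rec$end_reason, orc$end_reason)
    expect_equal(rec$budding_frames, as.integer(orc$events))
  }
})

test_that("record conservation invariants hold", {
  for (i in 1:50) {
    lab <- random_labels(150L, seed = 300L + i)
    rec <- reconstruct_lifespan(label_sequence(lab, frame_interval_min = 5))
    expect_equal(rec$rls, length(rec$budding_frames))
    if (rec$rls >= 2)
      expect_equal(sum(rec$cycle_durations_min),
                   diff(range(rec$budding_frames)) * 5)
  }
})

test_that("generator round trip recovers truth exactly", {
  hists <- make_cohort(60, seed0 = 400L)
  for (h in hists) {
    rec <- reconstruct_lifespan(
      label_sequence(h$per_frame_labels, frame_interval_min = 5))
    expect_equal(rec$budding_frames, h$budding_frames)
    expect_equal(rec$rls, h$rls)
    expect_equal(rec$end_reason, h$end_reason)
    expect_equal(rec$cycle_durations_min, h$cycle_durations_min)
  }
})

test_that("trajectory alignment shifts anchors to index 0", {
  tr <- list(c(1, 2, 3, 4), c(1, 2, 3, 4))
  al <- align_trajectories(tr, c(2L, 2L))
  expect_equal(al$mean[al$index == 0], 2)
  expect_equal(al$sem, rep(0, length(al$index)))
  # anchors 2 and 5 -> positions 2 and 5 meet at index 0
  al <- align_trajectories(list(10 * (1:6), 100 * (1:6)), c(2L, 5L))
  expect_equal(al$matrix[1, al$index == 0], 20)
  expect_equal(al$matrix[2, al$index == 0], 500)
  expect_warning(align_trajectories(list(1:3, 1:3), c(1L, NA)), "skipped")
})

test_that("aligned post-SEP cycle durations exceed pre-SEP by >= 50%", {
  hists <- make_cohort(300, seed0 = 700L,
                       params = synth_params(T = 400L, clog_prob = 0,
                                             empty_prob = 0,
                                             arrest_prob = 0))
  keep <- Filter(function(h) !is.na(h$sep_generation) &&
                   h$sep_generation >= 3 && h$rls >= h$sep_generation + 4,
                 hists)
  traces <- lapply(keep, function(h) h$cycle_frames * 5)
  anchors <- vapply(keep, function(h) h$sep_generation + 1L, integer(1))
  al <- align_trajectories(traces, anchors)
  m3 <- al$mean[al$index == 3]
  mm3 <- al$mean[al$index == -3]
  expect_gt(m3, 1.5 * mm3)
})

test_that("death fraction trace is a proper CDF estimate", {
  rec_none <- lapply(1:5, function(i)
    lifespan_record(paste0("r", i), c(2L, 20L), end_reason = "end_of_movie"))
  expect_equal(death_fraction_trace(rec_none, 30L), rep(0, 30))
  rec_all <- lapply(1:4, function(i)
    lifespan_record(paste0("r", i), c(2L), death_frame = 10L,
                    end_reason = "dead"))
  tr <- death_fraction_trace(rec_all, 15L)
  expect_equal(tr, c(rep(0, 10), rep(1, 5)))
  # geometric death model vs analytic CDF within 3 binomial SE
  p <- 0.1
  recs <- geometric_records(2000, p, seed = 42)
  # death at generation k happens at frame (k+1)*10
  tr <- death_fraction_trace(recs, 200L)
  for (tt in c(50, 100, 150)) {
    k <- floor(tt / 10) - 1L            # deaths by frame tt have RLS <= k
    cdf <- 1 - (1 - p)^k                # P(RLS <= k)
    se <- sqrt(cdf * (1 - cdf) / 2000)
    expect_lt(abs(tr[tt + 1L] - cdf), 3 * se + 1e-9)
  }
  expect_true(all(diff(tr) >= 0))
})
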