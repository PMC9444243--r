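# Synthetic cell histories, rendering, fields of view, label corruption.

test_that("deterministic parameters give exactly spaced budding events", {
  p <- synth_params(T = 56L, cycle_cv = 0, sep_enabled = FALSE,
                    death_prob_per_gen = 0, clog_prob = 0, empty_prob = 0,
                    arrest_prob = 0, initial_unbud_range = c(2L, 2L))
  h <- simulate_cell_history(p, seed = 1)
  expect_equal(h$budding_frames, c(2L, 20L, 38L))   # 90 min / 5 min = 18
  expect_equal(diff(h$budding_frames), c(18L, 18L))
  expect_equal(h$rls, 3L)
})

test_that("same seed gives identical histories; different seeds differ", {
  p <- synth_params()
  h1 <- simulate_cell_history(p, seed = 7)
  h2 <- simulate_cell_history(p, seed = 7)
  expect_identical(h1, h2)
  h3 <- simulate_cell_history(p, seed = 8)
  expect_false(identical(h1$per_frame_labels, h3$per_frame_labels))
  expect_error(simulate_cell_history(synth_params(T = 0L)), "invalid-parameter")
  expect_error(simulate_cell_history(synth_params(frame_interval_min = 0)),
               "invalid-parameter")
})

test_that("constant death hazard gives geometric lifespans (mean 1/p)", {
  p <- synth_params(T = 2000L, sep_enabled = FALSE,
                    death_prob_per_gen = 0.1, clog_prob = 0,
                    empty_prob = 0, arrest_prob = 0)
  rls <- vapply(1:5000, function(i)
    simulate_cell_history(p, seed = 10000L + i)$rls, numeric(1))
  se <- sqrt((1 - 0.1) / 0.1^2 / 5000)
  expect_lt(abs(mean(rls) - 10), 3 * se)
})

test_that("label grammar holds: small before large within a cycle, dead absorbing", {
  hists <- make_cohort(40, seed0 = 600L)
  for (h in hists) {
    lab <- h$per_frame_labels
    for (k in seq_along(h$budding_frames)) {
      f0 <- h$budding_frames[k] + 1L
      f1 <- if (k < h$rls) h$budding_frames[k + 1L]
            else min(f0 + h$cycle_frames[k] - 1L, h$T)
      cyc <- lab[f0:f1]
      cyc <- cyc[cyc %in% c("small", "large")]
      if (length(cyc) > 1)
        expect_true(all(diff(match(cyc, c("small", "large"))) >= 0))
    }
    if (any(lab == "dead"))
      expect_true(all(lab[seq.int(which(lab == "dead")[1], h$T)] == "dead"))
  }
})

test_that("SEP raises mean cycle duration under defaults", {
  hists <- make_cohort(200, seed0 = 5000L,
                       params = synth_params(T = 300L, clog_prob = 0,
                                             empty_prob = 0, arrest_prob = 0))
  pre <- post <- numeric(0)
  for (h in hists) {
    if (is.na(h$sep_generation)) next
    g <- seq_along(h$cycle_frames) - 1L
    pre <- c(pre, h$cycle_frames[g < h$sep_generation])
    post <- c(post, h$cycle_frames[g >= h$sep_generation])
  }
  expect_gt(mean(post), mean(pre))
})

test_that("rendering respects masks, labels and geometry", {
  p <- synth_params(T = 30L, clog_prob = 0, empty_prob = 1, arrest_prob = 0)
  # force an empty-from-start movie by seed search
  h <- NULL
  for (s in 1:50) {
    cand <- simulate_cell_history(p, seed = s)
    if (all(cand$per_frame_labels == "empty")) { h <- cand; break }
  }
  expect_false(is.null(h))
  sc <- render_trap_movie(h, render_params(size = c(48L, 48L)), seed = 1)
  for (m in sc$bf_masks) expect_equal(sum(m$class_map == 1L), 0L)

  # noiseless disk area within perimeter tolerance of the analytic value
  p2 <- synth_params(T = 10L, clog_prob = 0, empty_prob = 0, arrest_prob = 0)
  h2 <- simulate_cell_history(p2, seed = 3)
  rp <- render_params(size = c(60L, 60L), noise_add_sd = 0,
                      noise_mult_sd = 0, mother_radius_jitter = 0,
                      mother_growth_per_gen = 0)
  sc2 <- render_trap_movie(h2, rp, seed = 2)
  r <- rp$mother_radius_frac * 60
  live <- which(!h2$per_frame_labels %in% c("dead", "empty", "clog"))
  for (t in live) {
    area <- sum(sc2$bf_masks[[t]]$class_map == 1L)
    expect_lt(abs(area - pi * r^2), 2 * pi * r + 4)
  }
  # groundtruth labels pass through unchanged
  expect_identical(sc2$truth$per_frame_labels, h2$per_frame_labels)
  expect_error(render_trap_movie(h2, render_params(size = c(16L, 16L))),
               "invalid-parameter")
})

test_that("dead frames look different and clogged frames are covered", {
  p <- synth_params(T = 80L, clog_prob = 0, empty_prob = 0, arrest_prob = 0,
                    post_sep_death_prob = 1, pre_sep_gens_mean = 0)
  h <- simulate_cell_history(p, seed = 5)
  expect_equal(h$end_reason, "dead")
  rp <- render_params(size = c(48L, 48L), noise_add_sd = 0, noise_mult_sd = 0)
  sc <- render_trap_movie(h, rp, seed = 1)
  t_dead <- h$death_frame + 1L
  t_live <- h$budding_frames[1] + 2L
  dead_px <- sc$movie$frames[t_dead, , , 1][sc$bf_masks[[t_dead]]$class_map == 1]
  live_px <- sc$movie$frames[t_live, , , 1][sc$bf_masks[[t_live]]$class_map == 1]
  # contrast inversion: the cell body flips dark; speckle adds bright grains
  expect_lt(stats::median(dead_px), 0.2)
  expect_gt(stats::median(live_px), 0.6)
  expect_gt(max(dead_px), 0.8)

  pc <- synth_params(T = 60L, clog_prob = 1, empty_prob = 0, arrest_prob = 0)
  hc <- simulate_cell_history(pc, seed = 2)
  expect_equal(hc$end_reason, "clog")
  scc <- render_trap_movie(hc, rp, seed = 3)
  t_clog <- which(hc$per_frame_labels == "clog")[1]
  cover <- mean(scc$bf_masks[[t_clog]]$class_map != 0L)
  expect_gte(cover, 0.5)
})

test_that("nuclear fluorescence rises after the SEP", {
  p <- synth_params(T = 300L, clog_prob = 0, empty_prob = 0, arrest_prob = 0)
  for (s in 1:20) {
    h <- simulate_cell_history(p, seed = 100 + s)
    if (!is.na(h$sep_frame) && !is.na(h$death_frame) &&
        h$death_frame - h$sep_frame > 30) break
  }
  sc <- render_trap_movie(h, render_params(size = c(48L, 48L)), seed = 9)
  tr <- sc$nuclear_intensity_trace
  pre <- tr[seq_len(h$sep_frame)]
  post <- tr[(h$sep_frame + 20):(h$death_frame - 1)]
  expect_gt(mean(post[post > 0]), 1.3 * mean(pre[pre > 0]))
})

test_that("field-of-view grids place templates at exact jitter-free nodes", {
  fov <- render_field_of_view(rows = 2, cols = 2, spacing_px = 40,
                              jitter_px = 0, noise_sd = 0, seed = 1)
  expect_equal(nrow(fov$centers), 4L)
  half <- (24 - 1) / 2
  expect_equal(sort(unique(fov$centers[, 1])), c(24 + half, 64 + half))
  blank <- render_field_of_view(rows = 0, cols = 0, seed = 1)
  expect_equal(nrow(blank$centers), 0L)
  expect_true(all(blank$image == blank$image[1, 1]))
  expect_error(render_field_of_view(spacing_px = 10, template_size = 24),
               "invalid-parameter")
})

test_that("corrupt_labels: identity, isolation and realized flip rate", {
  ls <- label_sequence(rep(c("small", "large"), 50), frame_interval_min = 5)
  out <- corrupt_labels(ls, list(flip_rate = 0, dead_rate = 0), seed = 1)
  expect_identical(out$labels, ls$labels)

  ls3 <- label_sequence(rep("large", 3), frame_interval_min = 5)
  out <- corrupt_labels(ls3, list(dead_rate = 1), seed = 2)
  isd <- out$labels == "dead"
  expect_false(any(isd[-1] & isd[-3]))
  expect_true(any(isd))

  big <- label_sequence(rep(c("small", "large"), 5e4),
                        frame_interval_min = 5)
  out <- corrupt_labels(big, list(flip_rate = 0.05), seed = 3)
  n <- attr(out, "n_flips")
  se <- sqrt(0.05 * 0.95 / 1e5)
  expect_lt(abs(n / 1e5 - 0.05), 3 * se)
  # reproducible
  out2 <- corrupt_labels(big, list(flip_rate = 0.05), seed = 3)
  expect_identical(out$labels, out2$labels)
  expect_error(corrupt_labels(ls, list(flip_rate = 1.2)), "invalid-parameter")
})

test_that("injected dead frames are never adjacent to real dead frames", {
  for (s in 1:20) {
    h <- simulate_cell_history(synth_params(clog_prob = 0, empty_prob = 0,
                                            arrest_prob = 0),
                               seed = 200 + s)
    ls <- label_sequence(h$per_frame_labels, frame_interval_min = 5)
    out <- corrupt_labels(ls, list(dead_rate = 0.1), seed = s)
    inj <- which(out$labels == "dead" & ls$labels != "dead")
    for (t in inj) {
      if (t > 1) expect_false(out$labels[t - 1] == "dead")
      if (t < length(out$labels))
        expect_false(ls$labels[t + 1] == "dead")
    }
  }
})
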