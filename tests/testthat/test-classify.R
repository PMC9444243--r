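# Frame classifier and sequence classifier contracts (post-processing,
# determinism, statelessness, feature extraction).  Models here are tiny
# and trained on miniature inputs; the statistical learning benchmarks
# live in test-acceptance.R.

mini_set <- function(n_per = 12, size = 16L, seed = 1L) {
  # distinguishable blobs per class on a flat background
  withr::with_seed(seed, {
    cls <- trap_classes()
    X <- array(0, c(n_per * 6, size, size, 1))
    y <- character(n_per * 6)
    k <- 0L
    for (ci in seq_along(cls)) for (j in seq_len(n_per)) {
      k <- k + 1L
      img <- matrix(0.3, size, size)
      cy <- size / 2 + stats::rnorm(1, 0, 0.5)
      r <- 2 + ci
      d2 <- outer((seq_len(size) - cy)^2, (seq_len(size) - cy)^2, "+")
      img[d2 <= r^2] <- 0.3 + 0.1 * ci
      X[k, , , 1] <- img + stats::rnorm(size^2, 0, 0.01)
      y[k] <- cls[ci]
    }
    list(X = X, y = y)
  })
}

tiny_cfg <- cnn_config(conv_channels = c(4L, 8L), feature_dim = 8L,
                       epochs = 30L, batch_size = 16L, seed = 3L)

test_that("training validates inputs and is seed-reproducible", {
  ms <- mini_set()
  expect_error(train_frame_cnn(ms$X, rep("large", nrow(ms$X) - 6),
                               tiny_cfg), "invalid-input")
  expect_error(train_frame_cnn(ms$X, rep("large", dim(ms$X)[1]), tiny_cfg),
               "degenerate-training")
  m1 <- train_frame_cnn(ms$X, ms$y, tiny_cfg)
  m2 <- train_frame_cnn(ms$X, ms$y, tiny_cfg)
  probe <- trap_movie(ms$X[1:8, , , , drop = FALSE])
  expect_identical(classify_frames(m1, probe)$probs,
                   classify_frames(m2, probe)$probs)
  expect_true(m1$final_train_accuracy > 0.5)
})

test_that("class relabelling permutes predictions identically", {
  ms <- mini_set()
  perm <- c(3L, 1L, 2L, 5L, 6L, 4L)       # fixed permutation of classes
  cls <- trap_classes()
  y_perm <- cls[perm[match(ms$y, cls)]]
  m0 <- train_frame_cnn(ms$X, ms$y, tiny_cfg)
  mp <- train_frame_cnn(ms$X, y_perm, tiny_cfg)
  probe <- trap_movie(ms$X[seq(1, 72, by = 7), , , , drop = FALSE])
  p0 <- classify_frames(m0, probe)$probs
  pp <- classify_frames(mp, probe)$probs
  expect_equal(pp[, perm], p0, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("frame classification is stateless and emits proper rows", {
  ms <- mini_set()
  m <- train_frame_cnn(ms$X, ms$y, tiny_cfg)
  fr <- ms$X[c(5, 5, 9), , , , drop = FALSE]
  ls <- classify_frames(m, trap_movie(fr))
  expect_equal(ls$probs[1, ], ls$probs[2, ])
  expect_true(all(abs(rowSums(ls$probs) - 1) < 1e-6))
  expect_identical(ls$labels, trap_classes()[max.col(ls$probs, "first")])
  # channel-count mismatch errors; resizing is recorded
  expect_error(classify_frames(m, trap_movie(array(0, c(2, 16, 16, 0)))),
               "invalid-input")
  big <- trap_movie(array(0.3, c(2, 32, 32, 1)))
  expect_true(attr(classify_frames(m, big), "resized"))
})

test_that("feature extraction is deterministic with declared width", {
  ms <- mini_set()
  m <- train_frame_cnn(ms$X, ms$y, tiny_cfg)
  fr <- ms$X[c(2, 2, 30), , , , drop = FALSE]
  ft <- extract_features(m, trap_movie(fr))
  expect_equal(dim(ft), c(3L, 8L))
  expect_equal(ft[1, ], ft[2, ])
  expect_error(extract_features(structure(list(fitted = FALSE),
                                          class = "frame_cnn"),
                                trap_movie(fr)), "not-fitted")
  # features of two visually distinct classes separate linearly:
  # a nearest-centroid probe reaches >= 0.95
  Xab <- ms$X[ms$y %in% c("unbud", "empty"), , , , drop = FALSE]
  yab <- ms$y[ms$y %in% c("unbud", "empty")]
  fa <- extract_features(m, trap_movie(Xab))
  mu <- stats::aggregate(fa, list(yab), mean)
  d <- as.matrix(stats::dist(rbind(as.matrix(mu[, -1]), fa)))[-(1:2), 1:2]
  pred <- mu[max.col(-d), 1]
  expect_gte(mean(pred == yab), 0.95)
})

test_that("sequence LSTM fits degenerate data and validates alignment", {
  # constant-label sequences whose features carry a class-dependent shift
  feats <- lapply(1:6, function(i)
    matrix(withr::with_seed(i, stats::rnorm(20 * 4, mean = 2 * (i %% 2))),
           20, 4))
  labs <- lapply(1:6, function(i) rep(c("large", "small")[1 + i %% 2], 20))
  m <- train_sequence_lstm(feats, labs, hidden = 8L, epochs = 60L, seed = 2)
  acc <- mean(unlist(Map(function(f, l) {
    p <- traplife:::bilstm_predict(m$net, f)
    trap_classes()[max.col(p, "first")] == l
  }, feats, labs)))
  expect_equal(acc, 1)
  m2 <- train_sequence_lstm(feats, labs, hidden = 8L, epochs = 60L, seed = 2)
  expect_identical(traplife:::bilstm_predict(m$net, feats[[1]]),
                   traplife:::bilstm_predict(m2$net, feats[[1]]))
  expect_error(train_sequence_lstm(feats, lapply(labs, `[`, 1:10)),
               "invalid-input")
})

test_that("assembled classification handles boundaries and mismatches", {
  ms <- mini_set()
  cnn <- train_frame_cnn(ms$X, ms$y, tiny_cfg)
  feats <- list(extract_features(cnn, trap_movie(ms$X[1:20, , , ,
                                                      drop = FALSE])))
  labs <- list(ms$y[1:20])
  lstm <- train_sequence_lstm(feats, labs, hidden = 6L, epochs = 5L,
                              seed = 1)
  one <- trap_movie(ms$X[3, , , , drop = FALSE])
  ls <- classify_sequence(cnn, lstm, one)
  expect_length(ls$labels, 1L)
  expect_true(all(abs(rowSums(ls$probs) - 1) < 1e-6))
  bad <- lstm; bad$d <- 99L
  expect_error(classify_sequence(cnn, bad, one), "incompatible-models")
})

test_that("isolated-dead post-processing follows the stated rule", {
  pp <- function(x) postprocess_cnn_labels(
    label_sequence(x, frame_interval_min = 5))$labels
  expect_equal(pp(c("large", "dead", "large")), rep("large", 3))
  expect_equal(pp(c("large", "dead", "dead", "dead")),
               c("large", "dead", "dead", "dead"))
  expect_equal(pp(c("dead", "large", "small")), c("large", "large", "small"))
  expect_equal(pp(c("small", "dead", "dead")), c("small", "dead", "dead"))
  # idempotence on random sequences
  for (i in 1:40) {
    lab <- random_labels(60, seed = 40 + i)
    once <- pp(lab)
    expect_identical(pp(once), once)
  }
})
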