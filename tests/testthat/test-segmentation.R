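# Threshold selection, mask derivation, quantification, cross-validation.
# Statistical segmentation quality is benchmarked in test-acceptance.R.

# A miniature training set: centred bright disk = mother, corner disk =
# other, on a dark background.
seg_mini <- function(n = 24, size = 24L, seed = 1L) {
  withr::with_seed(seed, {
    X <- array(0, c(n, size, size, 1))
    masks <- vector("list", n)
    for (i in seq_len(n)) {
      img <- matrix(0.3, size, size)
      cm <- matrix(0L, size, size)
      r <- stats::runif(1, 3, 5)
      ctr <- (size - 1) / 2 + stats::rnorm(2, 0, 0.5)
      d2 <- outer((seq_len(size) - 1 - ctr[1])^2,
                  (seq_len(size) - 1 - ctr[2])^2, "+")
      img[d2 <= r^2] <- 0.75
      cm[d2 <= r^2] <- 1L
      if (i %% 2 == 0) {
        d2c <- outer((seq_len(size) - 4)^2, (seq_len(size) - 4)^2, "+")
        img[d2c <= 9] <- 0.75
        cm[d2c <= 9 & cm == 0L] <- 2L
      }
      X[i, , , 1] <- img + stats::rnorm(size^2, 0, 0.02)
      masks[[i]] <- cm
    }
    list(X = X, masks = masks)
  })
}

tiny_seg <- seg_config(enc_channels = c(4L, 6L, 8L), epochs = 6L,
                       batch_size = 8L, seed = 2L)

test_that("segmenter training validates inputs and reproduces with a seed", {
  sm <- seg_mini()
  expect_error(train_segmenter(sm$X, sm$masks[1:3], config = tiny_seg),
               "invalid-input")
  bad <- sm$masks; bad[[1]][1, 1] <- 7L
  expect_error(train_segmenter(sm$X, bad, config = tiny_seg),
               "invalid-label")
  m1 <- train_segmenter(sm$X, sm$masks, config = tiny_seg)
  m2 <- train_segmenter(sm$X, sm$masks, config = tiny_seg)
  p1 <- traplife:::seg_predict_probs(m1, sm$X[1, , , , drop = TRUE])
  p2 <- traplife:::seg_predict_probs(m2, sm$X[1, , , , drop = TRUE])
  expect_identical(p1, p2)
  expect_true(all(abs(apply(p1, c(1, 2), sum) - 1) < 1e-6))
})

test_that("all-background training yields a background-everywhere model", {
  sm <- seg_mini(n = 10)
  blank <- lapply(sm$masks, function(m) m * 0L)
  expect_warning(
    m <- train_segmenter(sm$X, blank,
                         config = utils::modifyList(tiny_seg,
                                                    list(epochs = 30L,
                                                         lr = 5e-3))),
    "degenerate-training")
  pm <- traplife:::seg_predict_probs(m, sm$X[2, , , , drop = TRUE])
  cm <- apply(pm, c(1, 2), which.max)
  expect_true(all(cm == 1L))
})

test_that("the segmenter accepts arbitrary (padded) input sizes", {
  sm <- seg_mini()
  m <- train_segmenter(sm$X, sm$masks, config = tiny_seg)
  odd <- matrix(0.3, 25, 27)
  pm <- traplife:::seg_predict_probs(m, odd)
  expect_equal(dim(pm)[1:2], c(25L, 27L))
})

test_that("threshold selection maximises F1 with ties to larger values", {
  # perfect fake model: build probability maps directly via the mask rule
  sm <- seg_mini(n = 6)
  probs <- lapply(sm$masks, function(cm) {
    pm <- array(0, c(dim(cm), 3))
    pm[, , 1][cm == 0] <- 1
    pm[, , 2][cm == 1] <- 1
    pm[, , 3][cm == 2] <- 1
    pm
  })
  # verify the perfect-prediction contract via a hand grid search
  grid <- c(0.2, 0.5, 0.8)
  f1_at <- function(th) {
    tp <- fp <- fn <- 0
    for (k in seq_along(probs)) {
      pred <- probs[[k]][, , 2] >= th
      tru <- sm$masks[[k]] == 1
      tp <- tp + sum(pred & tru); fp <- fp + sum(pred & !tru)
      fn <- fn + sum(!pred & tru)
    }
    2 * tp / (2 * tp + fp + fn)
  }
  expect_equal(vapply(grid, f1_at, numeric(1)), rep(1, 3))

  # real model: selected threshold equals an independent grid recomputation
  m <- train_segmenter(sm$X, sm$masks, config = tiny_seg)
  st <- select_threshold(m, sm$X, sm$masks, grid = seq(0.2, 0.8, 0.2))
  f1 <- ifelse(is.na(st$table$f1), -Inf, st$table$f1)
  expect_equal(st$best, max(st$table$threshold[f1 == max(f1)]))
  brute <- vapply(st$table$threshold, function(th) {
    tp <- fp <- fn <- 0
    for (i in seq_len(dim(sm$X)[1])) {
      pm <- traplife:::seg_predict_probs(m, sm$X[i, , , , drop = TRUE])
      pred <- pm[, , 2] >= th
      tru <- sm$masks[[i]] == 1
      tp <- tp + sum(pred & tru); fp <- fp + sum(pred & !tru)
      fn <- fn + sum(!pred & tru)
    }
    if (tp + fp == 0) NA_real_ else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  expect_equal(st$table$f1, brute, tolerance = 1e-12)
  st1 <- select_threshold(m, sm$X, sm$masks, grid = 0.5)
  expect_equal(st1$best, 0.5)
  expect_error(select_threshold(m, sm$X[integer(0), , , , drop = FALSE],
                                list(), grid = 0.5), "invalid-input")
})

test_that("mask derivation thresholds and keeps the central component", {
  H <- 20L
  pm <- array(1 / 3, c(H, H, 3))
  mk <- mask_from_probs(pm, 0.9)
  expect_equal(sum(mk$class_map == 1L), 0L)
  expect_error(mask_from_probs(pm, 1.2), "invalid-parameter")

  # one centred blob, one corner blob: only the centred one stays mother
  pm <- array(0, c(H, H, 3))
  pm[, , 1] <- 1
  blob <- function(cy, cx, r) {
    outer((seq_len(H) - 1 - cy)^2, (seq_len(H) - 1 - cx)^2, "+") <= r^2
  }
  ctr <- blob(9.5, 9.5, 3); cor <- blob(2, 2, 2)
  pm[, , 1][ctr | cor] <- 0.05
  pm[, , 2][ctr | cor] <- 0.9
  pm[, , 3][ctr | cor] <- 0.05
  mk <- mask_from_probs(pm, 0.5)
  expect_true(all(mk$class_map[ctr] == 1L))
  expect_true(all(mk$class_map[cor] == 2L))
  # single central blob is kept as-is
  pm2 <- array(0, c(H, H, 3)); pm2[, , 1] <- 1
  pm2[, , 1][ctr] <- 0.1; pm2[, , 2][ctr] <- 0.9
  mk2 <- mask_from_probs(pm2, 0.5)
  expect_equal(which(mk2$class_map == 1L), which(ctr))
})

test_that("target-class pixel count is non-increasing in the threshold", {
  withr::with_seed(5, {
    pm <- array(stats::runif(16 * 16 * 3), c(16, 16, 3))
    s <- apply(pm, c(1, 2), sum)
    for (k in 1:3) pm[, , k] <- pm[, , k] / s
  })
  counts <- vapply(seq(0.05, 0.95, 0.05), function(th)
    sum(mask_from_probs(pm, th, class_set = c("background", "x", "y"))$
          class_map == 1L), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("quantification implements background-subtracted sums", {
  H <- 20L
  nuc <- matrix(0L, H, H); nuc[5:8, 5:8] <- 1L           # 16 px nucleus
  bf <- matrix(0L, H, H); bf[9:14, 9:14] <- 1L           # 36 px mother
  nm <- segmentation_mask(nuc, class_set = c("background", "nucleus"))
  bm <- segmentation_mask(bf)
  # uniform image: background = b, so total nuclear fluorescence is 0
  fl <- array(7, c(2, H, H))
  qt <- quantify(list(bm, bm), list(nm, nm), fl, pixel_size_um = 0.5)
  expect_equal(qt$total_nuclear_fluorescence, c(0, 0))
  expect_equal(qt$mother_area_px, c(36, 36))
  expect_equal(qt$mother_area_um2, c(9, 9))
  # 100 px at b+5 over background b -> total 500
  nuc2 <- matrix(0L, H, H); nuc2[5:14, 5:14] <- 1L       # 100 px
  nm2 <- segmentation_mask(nuc2, class_set = c("background", "nucleus"))
  img <- matrix(2, H, H); img[5:14, 5:14] <- 7
  qt2 <- quantify(NULL, list(nm2), array(img, c(1, H, H)))
  expect_equal(qt2$total_nuclear_fluorescence, 500)
  # empty mother mask -> area 0 and absent fluorescence values
  empty_bm <- segmentation_mask(matrix(0L, H, H))
  qt3 <- quantify(list(empty_bm), list(nm2), array(img, c(1, H, H)))
  expect_equal(qt3$mother_area_px, 0)
  expect_true(is.na(qt3$mean_cyto_fluorescence))
  expect_true(is.na(qt3$total_nuclear_fluorescence))
})

test_that("cross-validation draws are reproducible and well-formed", {
  sm <- seg_mini(n = 20)
  cfg <- utils::modifyList(tiny_seg, list(epochs = 2L))
  cv1 <- cross_validate_segmenter(sm$X, sm$masks, n_draws = 2, n_train = 12,
                                  n_test = 4, threshold = 0.5,
                                  config = cfg, seed = 9)
  cv2 <- cross_validate_segmenter(sm$X, sm$masks, n_draws = 2, n_train = 12,
                                  n_test = 4, threshold = 0.5,
                                  config = cfg, seed = 9)
  expect_identical(cv1$per_draw, cv2$per_draw)
  expect_equal(nrow(cv1$per_draw), 2L)
  expect_true(all(cv1$per_draw$f1 >= 0 & cv1$per_draw$f1 <= 1, na.rm = TRUE))
  expect_error(cross_validate_segmenter(sm$X, sm$masks, n_draws = 1,
                                        n_train = 18, n_test = 5),
               "invalid-parameter")
})
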