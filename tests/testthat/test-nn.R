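# Numerical core: analytic gradients against central differences, and the
# GEMM convolution against the straightforward loop implementation.

tl <- function(name) get(name, envir = asNamespace("traplife"))

test_that("GEMM convolution equals the reference loop kernels", {
  withr::with_seed(1, {
    x <- array(stats::rnorm(9 * 7 * 3 * 2), c(9, 7, 3, 2))
    w <- array(stats::rnorm(3 * 3 * 3 * 4), c(3, 3, 3, 4))
    b <- stats::rnorm(4)
  })
  for (pad in 0:1) {
    y1 <- tl("cpp_conv2d_forward")(x, w, b, pad)
    y2 <- tl("cpp_conv2d_forward_gemm")(x, w, b, pad)
    expect_equal(y1, y2, tolerance = 1e-12)
    dy <- array(stats::rnorm(length(y1)), dim(y1))
    b1 <- tl("cpp_conv2d_backward")(x, w, dy, pad)
    b2 <- tl("cpp_conv2d_backward_gemm")(x, w, dy, pad)
    expect_equal(b1$dx, b2$dx, tolerance = 1e-12)
    expect_equal(b1$dw, b2$dw, tolerance = 1e-12)
    expect_equal(b1$db, b2$db, tolerance = 1e-12)
  }
})

test_that("conv-net gradients match central differences", {
  withr::with_seed(2, {
    layers <- list(tl("layer_conv")(3, 3, 2, 3, pad = 1), tl("layer_relu")(),
                   tl("layer_maxpool")(), tl("layer_flatten")(),
                   tl("layer_dense")(4 * 4 * 3, 5), tl("layer_relu")(),
                   tl("layer_dense")(5, 4))
    x <- array(stats::rnorm(8 * 8 * 2 * 3), c(8, 8, 2, 3))
  })
  y <- c(1L, 3L, 2L)
  lossfn <- function(ly) {
    fw <- tl("net_forward")(ly, x)
    tl("softmax_xent")(fw$out, y)$loss
  }
  fw <- tl("net_forward")(layers, x)
  sm <- tl("softmax_xent")(fw$out, y)
  bk <- tl("net_backward")(layers, fw$caches, sm$dlogits)
  eps <- 1e-5
  for (li in c(1, 5, 7)) for (p in c("W", "b")) {
    g <- bk$grads[[li]][[p]]
    idx <- withr::with_seed(li, sample(length(g), min(4, length(g))))
    for (i in idx) {
      l2 <- layers
      l2[[li]][[p]][i] <- l2[[li]][[p]][i] + eps
      lp <- lossfn(l2)
      l2[[li]][[p]][i] <- l2[[li]][[p]][i] - 2 * eps
      lm <- lossfn(l2)
      expect_equal(g[i], (lp - lm) / (2 * eps), tolerance = 1e-4)
    }
  }
})

test_that("biLSTM gradients match central differences", {
  N <- 2L; TT <- 5L; d <- 3L; h <- 4L; K <- 3L
  withr::with_seed(3, {
    mod <- tl("bilstm_new")(d, h, K)
    x <- array(stats::rnorm(N * TT * d), c(N, TT, d))
    lab <- matrix(sample(seq_len(K), N * TT, TRUE), N, TT)
  })
  mask <- matrix(TRUE, N, TT); mask[1, 5] <- FALSE
  lossfn <- function(m) {
    fw <- tl("bilstm_forward")(m, x)
    tl("softmax_xent")(matrix(fw$logits, N * TT, K), as.integer(lab),
                       as.numeric(mask))$loss
  }
  fw <- tl("bilstm_forward")(mod, x)
  sm <- tl("softmax_xent")(matrix(fw$logits, N * TT, K), as.integer(lab),
                           as.numeric(mask))
  gr <- tl("bilstm_backward")(mod, fw, x, array(sm$dlogits, c(N, TT, K)))
  eps <- 1e-5
  for (dir in c("fwd", "bwd")) for (p in c("Wx", "Wh", "b")) {
    g <- gr[[dir]][[paste0("d", p)]]
    idx <- withr::with_seed(nchar(p), sample(length(g), 4))
    for (i in idx) {
      m2 <- mod
      m2[[dir]][[p]][i] <- m2[[dir]][[p]][i] + eps
      lp <- lossfn(m2)
      m2[[dir]][[p]][i] <- m2[[dir]][[p]][i] - 2 * eps
      lm <- lossfn(m2)
      expect_equal(g[i], (lp - lm) / (2 * eps), tolerance = 1e-4)
    }
  }
})

test_that("segmenter gradients match central differences", {
  H <- 8L; W <- 8L; Cin <- 3L; c1 <- 3L; c2 <- 4L; c3 <- 5L; K <- 3L; N <- 2L
  withr::with_seed(4, {
    m <- list(W1 = array(stats::rnorm(3 * 3 * Cin * c1, sd = .3),
                         c(3, 3, Cin, c1)), b1 = stats::rnorm(c1),
              W2 = array(stats::rnorm(3 * 3 * c1 * c2, sd = .3),
                         c(3, 3, c1, c2)), b2 = stats::rnorm(c2),
              W3 = array(stats::rnorm(3 * 3 * c2 * c3, sd = .3),
                         c(3, 3, c2, c3)), b3 = stats::rnorm(c3),
              W4 = array(stats::rnorm(3 * 3 * (c2 + c3) * c2, sd = .3),
                         c(3, 3, c2 + c3, c2)), b4 = stats::rnorm(c2),
              W5 = array(stats::rnorm((c1 + c2) * K, sd = .3),
                         c(1, 1, c1 + c2, K)), b5 = stats::rnorm(K))
    X <- array(stats::rnorm(H * W * Cin * N), c(H, W, Cin, N))
    Y <- array(sample(0:(K - 1), H * W * N, TRUE), c(H, W, N))
  })
  lossfn <- function(m) {
    fw <- tl("seg_forward")(m, X)
    dlg <- dim(fw$logits)
    lg <- matrix(aperm(fw$logits, c(1, 2, 4, 3)), prod(dlg[-3]), dlg[3])
    tl("softmax_xent")(lg, as.integer(Y) + 1L)$loss
  }
  fw <- tl("seg_forward")(m, X)
  dlg <- dim(fw$logits)
  lg <- matrix(aperm(fw$logits, c(1, 2, 4, 3)), prod(dlg[-3]), dlg[3])
  sm <- tl("softmax_xent")(lg, as.integer(Y) + 1L)
  dl <- aperm(array(sm$dlogits, c(dlg[1], dlg[2], dlg[4], dlg[3])),
              c(1, 2, 4, 3))
  gr <- tl("seg_backward")(m, fw, dl)
  eps <- 1e-5
  for (p in names(gr)) {
    g <- gr[[p]]
    idx <- withr::with_seed(nchar(p) + 7, sample(length(g),
                                                 min(4, length(g))))
    for (i in idx) {
      m2 <- m
      m2[[p]][i] <- m2[[p]][i] + eps
      lp <- lossfn(m2)
      m2[[p]][i] <- m2[[p]][i] - 2 * eps
      lm <- lossfn(m2)
      expect_equal(g[i], (lp - lm) / (2 * eps), tolerance = 1e-4)
    }
  }
})

test_that("pooling and upsampling round-trip shapes and values", {
  withr::with_seed(6, x <- array(stats::rnorm(6 * 4 * 2 * 2), c(6, 4, 2, 2)))
  mp <- tl("cpp_maxpool2_forward")(x)
  expect_equal(dim(mp$y), c(3L, 2L, 2L, 2L))
  expect_equal(mp$y[1, 1, 1, 1], max(x[1:2, 1:2, 1, 1]))
  av <- tl("cpp_avgpool2_forward")(x)
  expect_equal(av[1, 1, 1, 1], mean(x[1:2, 1:2, 1, 1]))
  up <- tl("cpp_upsample2_forward")(av)
  expect_equal(dim(up), dim(x))
  expect_equal(up[1, 1, 1, 1], up[2, 2, 1, 1])
})
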