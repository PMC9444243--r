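# Tiny neural-network core: sequential conv/dense nets and a bidirectional
# LSTM, trained with Adam.  Deliberately minimal — just what the frame
# classifier, sequence classifiers and segmenter need — with explicit seeds
# and no global state.  Batched image tensors use dim (H, W, C, N).

#' Evaluate an expression with a temporary RNG seed
#'
#' All stochastic operations in the package take an explicit integer seed and
#' run under this helper so the caller's RNG state is never disturbed.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("invalid-parameter: seed must be a single integer")
  withr::with_seed(as.integer(seed), code)
}

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

## ---- sequential conv/dense network -------------------------------------

# Layer constructors: each layer is a list with $type and parameter arrays.
layer_conv <- function(kh, kw, cin, cout, pad = 1L) {
  list(type = "conv",
       W = he_init(c(kh, kw, cin, cout), kh * kw * cin),
       b = numeric(cout), pad = as.integer(pad))
}
layer_dense <- function(din, dout) {
  list(type = "dense", W = he_init(c(din, dout), din), b = numeric(dout))
}
layer_relu    <- function() list(type = "relu")
layer_maxpool <- function() list(type = "maxpool")
layer_avgpool <- function() list(type = "avgpool")
layer_flatten <- function() list(type = "flatten")

net_forward <- function(layers, x, train = TRUE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$type == "conv") {
      caches[[i]] <- list(x = x)
      x <- cpp_conv2d_forward_gemm(x, ly$W, ly$b, ly$pad)
    } else if (ly$type == "relu") {
      x <- relu(x)
      caches[[i]] <- list(y = x)
    } else if (ly$type == "maxpool") {
      caches[[i]] <- list(xdim = dim(x))
      mp <- cpp_maxpool2_forward(x)
      caches[[i]]$argmax <- mp$argmax
      x <- mp$y
    } else if (ly$type == "avgpool") {
      caches[[i]] <- list(xdim = dim(x))
      x <- cpp_avgpool2_forward(x)
    } else if (ly$type == "flatten") {
      caches[[i]] <- list(xdim = dim(x))
      d <- dim(x)
      x <- t(matrix(x, prod(d[1:3]), d[4]))
    } else if (ly$type == "dense") {
      caches[[i]] <- list(x = x)
      x <- sweep(x %*% ly$W, 2L, ly$b, "+")
    } else stop("unknown layer type: ", ly$type)
  }
  list(out = x, caches = caches)
}

net_backward <- function(layers, caches, dout) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]
    cc <- caches[[i]]
    if (ly$type == "conv") {
      bk <- cpp_conv2d_backward_gemm(cc$x, ly$W, dout, ly$pad)
      grads[[i]] <- list(W = bk$dw, b = bk$db)
      dout <- bk$dx
    } else if (ly$type == "relu") {
      dout <- dout * (cc$y > 0)
    } else if (ly$type == "maxpool") {
      dout <- cpp_maxpool2_backward(dout, cc$argmax, as.integer(cc$xdim))
    } else if (ly$type == "avgpool") {
      dout <- cpp_avgpool2_backward(dout, as.integer(cc$xdim))
    } else if (ly$type == "flatten") {
      dout <- array(t(dout), dim = cc$xdim)
    } else if (ly$type == "dense") {
      grads[[i]] <- list(W = crossprod(cc$x, dout), b = colSums(dout))
      dout <- tcrossprod(dout, ly$W)
    }
  }
  list(grads = grads, dx = dout)
}

# Softmax cross-entropy on logits (N x K); labels are integers 1..K.
# Returns loss and dlogits (already divided by N).
softmax_xent <- function(logits, labels, weight = NULL) {
  p <- softmax_rows(logits)
  n <- nrow(logits)
  idx <- cbind(seq_len(n), labels)
  if (is.null(weight)) weight <- rep(1, n)
  wsum <- sum(weight)
  loss <- -sum(weight * log(pmax(p[idx], 1e-12))) / wsum
  d <- p
  d[idx] <- d[idx] - 1
  d <- d * (weight / wsum)
  list(loss = loss, dlogits = d, probs = p)
}

## ---- Adam optimiser -----------------------------------------------------

adam_state <- function() new.env(parent = emptyenv())

adam_update <- function(state, key, param, grad, lr, t,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  m <- state[[paste0(key, ".m")]]
  v <- state[[paste0(key, ".v")]]
  if (is.null(m)) { m <- param * 0; v <- param * 0 }
  m <- beta1 * m + (1 - beta1) * grad
  v <- beta2 * v + (1 - beta2) * grad^2
  state[[paste0(key, ".m")]] <- m
  state[[paste0(key, ".v")]] <- v
  mhat <- m / (1 - beta1^t)
  vhat <- v / (1 - beta2^t)
  param - lr * mhat / (sqrt(vhat) + eps)
}

# Apply Adam to every W/b in a layer list given matching grads.
net_adam_step <- function(layers, grads, state, lr, t) {
  for (i in seq_along(layers)) {
    if (is.null(grads[[i]])) next
    for (p in names(grads[[i]])) {
      key <- paste0("L", i, ".", p)
      layers[[i]][[p]] <- adam_update(state, key, layers[[i]][[p]],
                                      grads[[i]][[p]], lr, t)
    }
  }
  layers
}

## ---- bidirectional LSTM -------------------------------------------------

# One direction's parameters; gate order along columns is (i, f, g, o).
lstm_params <- function(d, h) {
  list(Wx = he_init(c(d, 4 * h), d),
       Wh = he_init(c(h, 4 * h), h),
       b  = c(numeric(h), rep(1, h), numeric(2 * h)))  # forget bias 1
}

sigm <- function(x) 1 / (1 + exp(-x))

# x: array (N, T, d).  Returns H (N, T, h) and per-step caches.
lstm_forward <- function(par, x, reverse = FALSE) {
  N <- dim(x)[1]; TT <- dim(x)[2]
  h <- ncol(par$Wh)
  h <- h / 4
  steps <- if (reverse) rev(seq_len(TT)) else seq_len(TT)
  H <- array(0, dim = c(N, TT, h))
  hp <- matrix(0, N, h); cp <- matrix(0, N, h)
  caches <- vector("list", TT)
  ih <- seq_len(h)
  for (t in steps) {
    xt <- matrix(x[, t, ], N)
    A <- xt %*% par$Wx + hp %*% par$Wh
    A <- sweep(A, 2L, par$b, "+")
    i <- sigm(A[, ih, drop = FALSE])
    f <- sigm(A[, h + ih, drop = FALSE])
    g <- tanh(A[, 2 * h + ih, drop = FALSE])
    o <- sigm(A[, 3 * h + ih, drop = FALSE])
    ct <- f * cp + i * g
    tc <- tanh(ct)
    ht <- o * tc
    caches[[t]] <- list(xt = xt, hp = hp, cp = cp, i = i, f = f, g = g,
                        o = o, tc = tc)
    H[, t, ] <- ht
    hp <- ht; cp <- ct
  }
  list(H = H, caches = caches, steps = steps)
}

# dH: (N, T, h) gradient w.r.t. the direction's hidden outputs.
lstm_backward <- function(par, fw, x, dH) {
  N <- dim(x)[1]; TT <- dim(x)[2]
  h <- ncol(par$Wh) / 4
  dWx <- par$Wx * 0; dWh <- par$Wh * 0; db <- par$b * 0
  dx <- array(0, dim = dim(x))
  dh_next <- matrix(0, N, h); dc_next <- matrix(0, N, h)
  for (t in rev(fw$steps)) {
    cc <- fw$caches[[t]]
    dh <- matrix(dH[, t, ], N) + dh_next
    do_ <- dh * cc$tc
    dc <- dc_next + dh * cc$o * (1 - cc$tc^2)
    di <- dc * cc$g
    df <- dc * cc$cp
    dg <- dc * cc$i
    dc_next <- dc * cc$f
    dA <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do_ * cc$o * (1 - cc$o))
    dWx <- dWx + crossprod(cc$xt, dA)
    dWh <- dWh + crossprod(cc$hp, dA)
    db <- db + colSums(dA)
    dx[, t, ] <- dx[, t, ] + tcrossprod(dA, par$Wx)
    dh_next <- tcrossprod(dA, par$Wh)
  }
  list(dWx = dWx, dWh = dWh, db = db, dx = dx)
}

# Bidirectional sequence-to-sequence classifier head: biLSTM + shared dense.
bilstm_new <- function(d, hidden, K) {
  list(fwd = lstm_params(d, hidden), bwd = lstm_params(d, hidden),
       Wd = he_init(c(2 * hidden, K), 2 * hidden), bd = numeric(K),
       d = d, hidden = hidden, K = K)
}

# x (N, T, d); returns per-frame logits (N, T, K) plus caches.
bilstm_forward <- function(mod, x) {
  f <- lstm_forward(mod$fwd, x, reverse = FALSE)
  b <- lstm_forward(mod$bwd, x, reverse = TRUE)
  N <- dim(x)[1]; TT <- dim(x)[2]; h <- mod$hidden
  Hcat <- array(0, dim = c(N, TT, 2 * h))
  Hcat[, , seq_len(h)] <- f$H
  Hcat[, , h + seq_len(h)] <- b$H
  Hm <- matrix(Hcat, N * TT, 2 * h)
  logits <- sweep(Hm %*% mod$Wd, 2L, mod$bd, "+")
  list(logits = array(logits, dim = c(N, TT, mod$K)),
       f = f, b = b, Hm = Hm)
}

# dlogits (N, T, K) -> parameter grads.
bilstm_backward <- function(mod, fw, x, dlogits) {
  N <- dim(x)[1]; TT <- dim(x)[2]; h <- mod$hidden
  dl <- matrix(dlogits, N * TT, mod$K)
  dWd <- crossprod(fw$Hm, dl)
  dbd <- colSums(dl)
  dH <- tcrossprod(dl, mod$Wd)
  dHa <- array(dH, dim = c(N, TT, 2 * h))
  gf <- lstm_backward(mod$fwd, fw$f, x, dHa[, , seq_len(h), drop = FALSE])
  gb <- lstm_backward(mod$bwd, fw$b, x, dHa[, , h + seq_len(h), drop = FALSE])
  list(fwd = gf, bwd = gb, Wd = dWd, bd = dbd)
}

# Train a biLSTM on sequences: x (N, T, d), labels (N, T) integers 1..K,
# mask (N, T) logical frames that contribute to the loss.
bilstm_train <- function(x, labels, K, hidden = 150L, epochs = 30L,
                         lr = 5e-3, seed = 1L, mask = NULL,
                         batch_size = 16L, verbose = FALSE) {
  N <- dim(x)[1]; TT <- dim(x)[2]; d <- dim(x)[3]
  if (is.null(mask)) mask <- matrix(TRUE, N, TT)
  batch_size <- min(batch_size, N)
  with_seed(seed, {
    mod <- bilstm_new(d, as.integer(hidden), as.integer(K))
    st <- adam_state()
    step <- 0L
    losses <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(N)
      ep_loss <- 0; nb <- 0L
      for (b0 in seq(1L, N, by = batch_size)) {
        ii <- ord[b0:min(b0 + batch_size - 1L, N)]
        xb <- x[ii, , , drop = FALSE]
        nB <- length(ii)
        fw <- bilstm_forward(mod, xb)
        sm <- softmax_xent(matrix(fw$logits, nB * TT, K),
                           as.integer(labels[ii, , drop = FALSE]),
                           as.numeric(mask[ii, , drop = FALSE]))
        dlog <- array(sm$dlogits, dim = c(nB, TT, K))
        gr <- bilstm_backward(mod, fw, xb, dlog)
        step <- step + 1L
        for (dir in c("fwd", "bwd")) {
          for (p in c("Wx", "Wh", "b")) {
            key <- paste0(dir, ".", p)
            mod[[dir]][[p]] <- adam_update(st, key, mod[[dir]][[p]],
                                           gr[[dir]][[paste0("d", p)]],
                                           lr, step)
          }
        }
        mod$Wd <- adam_update(st, "Wd", mod$Wd, gr$Wd, lr, step)
        mod$bd <- adam_update(st, "bd", mod$bd, gr$bd, lr, step)
        ep_loss <- ep_loss + sm$loss; nb <- nb + 1L
      }
      losses[ep] <- ep_loss / nb
      if (verbose) message(sprintf("epoch %d loss %.4f", ep, losses[ep]))
    }
    mod$loss_trajectory <- losses
    mod
  })
}

# Per-frame class probabilities for one sequence (T x d) -> (T x K).
bilstm_predict <- function(mod, xseq) {
  x <- array(xseq, dim = c(1L, nrow(xseq), ncol(xseq)))
  fw <- bilstm_forward(mod, x)
  softmax_rows(matrix(fw$logits, nrow(xseq), mod$K))
}
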