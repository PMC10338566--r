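# Minimal dense/convolutional/recurrent layer kernels.
#
# The classifier is small enough that plain BLAS-backed matrix ops are fast
# on one CPU core; everything is deterministic given the R RNG state, which
# the training loop seeds explicitly.

# ---- convolution via im2col -------------------------------------------------

pad_hwc <- function(x, p) {
  if (p == 0) {
    return(x)
  }
  d <- dim(x)
  out <- array(0, c(d[1] + 2 * p, d[2] + 2 * p, d[3]))
  out[p + seq_len(d[1]), p + seq_len(d[2]), ] <- x
  out
}

# x: H x W x Cin array; W_mat: (k*k*Cin) x Cout, rows ordered (di, dj, c)
# with di fastest. Returns H_out x W_out x Cout.
conv_forward <- function(x, W_mat, b, k, stride = 1, pad = 0) {
  d <- dim(x)
  xp <- pad_hwc(x, pad)
  h_out <- (d[1] + 2 * pad - k) %/% stride + 1
  w_out <- (d[2] + 2 * pad - k) %/% stride + 1
  rows0 <- seq(0, by = stride, length.out = h_out)
  cols0 <- seq(0, by = stride, length.out = w_out)
  col <- matrix(0, h_out * w_out, k * k * d[3])
  idx <- 1L
  for (c in seq_len(d[3])) {
    for (dj in seq_len(k)) {
      for (di in seq_len(k)) {
        col[, idx] <- xp[rows0 + di, cols0 + dj, c]
        idx <- idx + 1L
      }
    }
  }
  out <- col %*% W_mat
  out <- sweep(out, 2, b, "+")
  array(out, c(h_out, w_out, ncol(W_mat)))
}

# mean pooling over non-overlapping p x p blocks (H, W divisible by p)
pool_mean <- function(x, p) {
  d <- dim(x)
  h2 <- d[1] %/% p
  w2 <- d[2] %/% p
  ph <- matrix(0, h2, d[1])
  for (i in seq_len(h2)) ph[i, ((i - 1) * p + 1):(i * p)] <- 1 / p
  pw <- matrix(0, d[2], w2)
  for (j in seq_len(w2)) pw[((j - 1) * p + 1):(j * p), j] <- 1 / p
  out <- array(0, c(h2, w2, d[3]))
  for (c in seq_len(d[3])) out[, , c] <- ph %*% x[, , c] %*% pw
  out
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- dropout ----------------------------------------------------------------

# inverted dropout: scales kept units by 1/(1-p) so eval mode is the identity
dropout_mask <- function(dim_, p) {
  if (p <= 0) {
    return(NULL)
  }
  array(stats::rbinom(prod(dim_), 1, 1 - p) / (1 - p), dim_)
}

# ---- LSTM (single layer, unidirectional, stateless) -------------------------

# X: B x L x D array. Returns list(H = B x L x nh, cache) with h0 = c0 = 0:
# the hidden state never crosses sequence boundaries.
lstm_forward <- function(X, par, keep_cache = FALSE) {
  d <- dim(X)
  B <- d[1]
  L <- d[2]
  nh <- nrow(par$Wh)
  H <- array(0, c(B, L, nh))
  h <- matrix(0, B, nh)
  cc <- matrix(0, B, nh)
  cache <- if (keep_cache) vector("list", L) else NULL
  for (t in seq_len(L)) {
    xt <- matrix(X[, t, ], B)
    z <- xt %*% par$Wx + h %*% par$Wh
    z <- sweep(z, 2, par$b, "+")
    i <- sigmoid(z[, 1:nh, drop = FALSE])
    f <- sigmoid(z[, nh + 1:nh, drop = FALSE])
    g <- tanh(z[, 2 * nh + 1:nh, drop = FALSE])
    o <- sigmoid(z[, 3 * nh + 1:nh, drop = FALSE])
    c_prev <- cc
    cc <- f * cc + i * g
    tc <- tanh(cc)
    h_new <- o * tc
    if (keep_cache) {
      cache[[t]] <- list(
        xt = xt, h_prev = h, c_prev = c_prev, i = i, f = f, g = g, o = o,
        tc = tc
      )
    }
    h <- h_new
    H[, t, ] <- h
  }
  list(H = H, cache = cache)
}

# dH: B x L x nh gradient on the hidden outputs
lstm_backward <- function(dH, par, cache) {
  L <- length(cache)
  B <- nrow(cache[[1]]$xt)
  nh <- nrow(par$Wh)
  din <- nrow(par$Wx)
  dWx <- matrix(0, din, 4 * nh)
  dWh <- matrix(0, nh, 4 * nh)
  db <- numeric(4 * nh)
  dX <- array(0, c(B, L, din))
  dh_next <- matrix(0, B, nh)
  dc_next <- matrix(0, B, nh)
  for (t in rev(seq_len(L))) {
    ca <- cache[[t]]
    dh <- matrix(dH[, t, ], B) + dh_next
    dc <- dc_next + dh * ca$o * (1 - ca$tc^2)
    do_ <- dh * ca$tc
    di <- dc * ca$g
    df <- dc * ca$c_prev
    dg <- dc * ca$i
    dz <- cbind(
      di * ca$i * (1 - ca$i),
      df * ca$f * (1 - ca$f),
      dg * (1 - ca$g^2),
      do_ * ca$o * (1 - ca$o)
    )
    dWx <- dWx + crossprod(ca$xt, dz)
    dWh <- dWh + crossprod(ca$h_prev, dz)
    db <- db + colSums(dz)
    dX[, t, ] <- dz %*% t(par$Wx)
    dh_next <- dz %*% t(par$Wh)
    dc_next <- dc * ca$f
  }
  list(dWx = dWx, dWh = dWh, db = db, dX = dX)
}

# ---- Adam optimizer ---------------------------------------------------------

adam_init <- function(params) {
  rapply(params, function(p) list(m = p * 0, v = p * 0), how = "list")
}

adam_step <- function(params, grads, state, step, lr = 1e-4, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  upd <- function(p, g, s) {
    s$m <- beta1 * s$m + (1 - beta1) * g
    s$v <- beta2 * s$v + (1 - beta2) * g^2
    mhat <- s$m / (1 - beta1^step)
    vhat <- s$v / (1 - beta2^step)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), s = s)
  }
  walk <- function(p, g, s) {
    if (is.list(p) && !is.null(names(p)) && !("m" %in% names(s))) {
      for (nm in names(p)) {
        res <- walk(p[[nm]], g[[nm]], s[[nm]])
        p[[nm]] <- res$p
        s[[nm]] <- res$s
      }
      return(list(p = p, s = s))
    }
    upd(p, g, s)
  }
  walk(params, grads, state)
}
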