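# Differentiable layer primitives in base R matrix algebra.
#
# Every *_fwd returns list(out, cache); the paired *_bwd takes the upstream
# gradient and the cache and returns list(dx, <parameter gradients>).
# Token sequences are T x d matrices, one row per token. The analytic
# backward passes are validated against central finite differences in the
# test suite.

linear_fwd <- function(x, W, b) {
  out <- x %*% W
  out <- sweep(out, 2, b, "+")
  list(out = out, cache = list(x = x))
}

linear_bwd <- function(dout, cache, W) {
  list(dx = dout %*% t(W),
       dW = t(cache$x) %*% dout,
       db = colSums(dout))
}

layernorm_fwd <- function(x, g, b, eps = 1e-6) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  out <- sweep(xhat, 2, g, "*")
  out <- sweep(out, 2, b, "+")
  list(out = out, cache = list(xhat = xhat, inv = inv))
}

layernorm_bwd <- function(dout, cache, g) {
  xhat <- cache$xhat
  dxhat <- sweep(dout, 2, g, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- cache$inv * (dxhat - m1 - xhat * m2)
  list(dx = dx, dg = colSums(dout * xhat), db = colSums(dout))
}

gelu_fwd <- function(x) {
  list(out = x * stats::pnorm(x), cache = list(x = x))
}

gelu_bwd <- function(dout, cache) {
  x <- cache$x
  dout * (stats::pnorm(x) + x * stats::dnorm(x))
}

softmax_rows <- function(x) {
  m <- apply(x, 1, max)
  e <- exp(x - m)
  e / rowSums(e)
}

# Multi-head scaled dot-product self-attention. Attention weights over each
# query row sum to 1; scale is 1/sqrt(head width).
mhsa_fwd <- function(x, p, n_heads) {
  d <- ncol(x)
  dh <- d %/% n_heads
  check_that(dh * n_heads == d, "embed dim not divisible by n_heads")
  q <- sweep(x %*% p$Wq, 2, p$bq, "+")
  k <- sweep(x %*% p$Wk, 2, p$bk, "+")
  v <- sweep(x %*% p$Wv, 2, p$bv, "+")
  O <- matrix(0, nrow(x), d)
  A_list <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1L) * dh + 1L):(h * dh)
    S <- (q[, idx, drop = FALSE] %*% t(k[, idx, drop = FALSE])) / sqrt(dh)
    A <- softmax_rows(S)
    A_list[[h]] <- A
    O[, idx] <- A %*% v[, idx, drop = FALSE]
  }
  out <- sweep(O %*% p$Wo, 2, p$bo, "+")
  list(out = out,
       cache = list(x = x, q = q, k = k, v = v, O = O, A = A_list,
                    n_heads = n_heads, dh = dh))
}

mhsa_bwd <- function(dout, cache, p) {
  x <- cache$x; dh <- cache$dh
  dO <- dout %*% t(p$Wo)
  dWo <- t(cache$O) %*% dout
  dbo <- colSums(dout)
  dq <- matrix(0, nrow(x), ncol(x))
  dk <- dq; dv <- dq
  for (h in seq_len(cache$n_heads)) {
    idx <- ((h - 1L) * dh + 1L):(h * dh)
    A <- cache$A[[h]]
    dOh <- dO[, idx, drop = FALSE]
    Vh <- cache$v[, idx, drop = FALSE]
    dA <- dOh %*% t(Vh)
    dv[, idx] <- t(A) %*% dOh
    dS <- A * (dA - rowSums(dA * A))
    dq[, idx] <- (dS %*% cache$k[, idx, drop = FALSE]) / sqrt(dh)
    dk[, idx] <- (t(dS) %*% cache$q[, idx, drop = FALSE]) / sqrt(dh)
  }
  list(dx = dq %*% t(p$Wq) + dk %*% t(p$Wk) + dv %*% t(p$Wv),
       dWq = t(x) %*% dq, dbq = colSums(dq),
       dWk = t(x) %*% dk, dbk = colSums(dk),
       dWv = t(x) %*% dv, dbv = colSums(dv),
       dWo = dWo, dbo = dbo)
}

# Depthwise (per-channel) 2-D convolution over a token grid.
# tokens: N x d matrix whose rows sit on a grid_h x grid_w grid in row-major
# order; kern: k x k x d; bias: length d. Stride 1, zero same-padding.
dwconv_fwd <- function(tokens, kern, bias, grid_h, grid_w) {
  k <- dim(kern)[1]
  check_that(dim(kern)[2] == k && k %% 2 == 1, "kernel must be square, odd")
  d <- ncol(tokens)
  check_that(nrow(tokens) == grid_h * grid_w,
             "tokens not arrangeable on a ", grid_h, "x", grid_w, " grid")
  pad <- (k - 1L) %/% 2L
  # row-major token order -> grid array [gh, gw, d]
  X <- array(0, dim = c(grid_h, grid_w, d))
  for (c_ in seq_len(d)) {
    X[, , c_] <- matrix(tokens[, c_], grid_h, grid_w, byrow = TRUE)
  }
  Xp <- array(0, dim = c(grid_h + 2L * pad, grid_w + 2L * pad, d))
  Xp[pad + seq_len(grid_h), pad + seq_len(grid_w), ] <- X
  out <- array(0, dim = c(grid_h, grid_w, d))
  for (u in seq_len(k)) {
    for (v in seq_len(k)) {
      slice <- Xp[(u - 1L) + seq_len(grid_h), (v - 1L) + seq_len(grid_w), ,
                  drop = FALSE]
      out <- out + sweep(slice, 3, kern[u, v, ], "*")
    }
  }
  out <- sweep(out, 3, bias, "+")
  res <- matrix(0, nrow(tokens), d)
  for (c_ in seq_len(d)) {
    res[, c_] <- as.vector(t(out[, , c_]))  # back to row-major token order
  }
  list(out = res, cache = list(Xp = Xp, grid_h = grid_h, grid_w = grid_w,
                               k = k, pad = pad))
}

dwconv_bwd <- function(dout, cache, kern) {
  gh <- cache$grid_h; gw <- cache$grid_w
  k <- cache$k; pad <- cache$pad
  d <- ncol(dout)
  dY <- array(0, dim = c(gh, gw, d))
  for (c_ in seq_len(d)) {
    dY[, , c_] <- matrix(dout[, c_], gh, gw, byrow = TRUE)
  }
  dXp <- array(0, dim = dim(cache$Xp))
  dk <- array(0, dim = dim(kern))
  for (u in seq_len(k)) {
    for (v in seq_len(k)) {
      ri <- (u - 1L) + seq_len(gh)
      ci <- (v - 1L) + seq_len(gw)
      slice <- cache$Xp[ri, ci, , drop = FALSE]
      dk[u, v, ] <- apply(slice * dY, 3, sum)
      dXp[ri, ci, ] <- dXp[ri, ci, , drop = FALSE] +
        sweep(dY, 3, kern[u, v, ], "*")
    }
  }
  dX <- dXp[pad + seq_len(gh), pad + seq_len(gw), , drop = FALSE]
  dx <- matrix(0, nrow(dout), d)
  for (c_ in seq_len(d)) {
    dx[, c_] <- as.vector(t(dX[, , c_]))
  }
  list(dx = dx, dk = dk, db = apply(dY, 3, sum))
}

# 1x1 convolution over an H x W x Cin array == pixelwise linear map.
conv1x1_fwd <- function(x, W, b) {
  dm <- dim(x)
  xm <- matrix(x, dm[1] * dm[2], dm[3])
  out <- sweep(xm %*% W, 2, b, "+")
  list(out = array(out, dim = c(dm[1], dm[2], ncol(W))),
       cache = list(xm = xm, dm = dm))
}

conv1x1_bwd <- function(dout, cache, W) {
  dm <- dim(dout)
  dm_out <- matrix(dout, dm[1] * dm[2], dm[3])
  list(dx = array(dm_out %*% t(W),
                  dim = c(cache$dm[1], cache$dm[2], nrow(W))),
       dW = t(cache$xm) %*% dm_out,
       db = colSums(dm_out))
}

# Depthwise 2-D convolution directly on an H x W x C image array (used by
# the inverted-residual stem); same padding, stride 1.
dwconv_img_fwd <- function(x, kern, bias) {
  dm <- dim(x)
  tok <- matrix(0, dm[1] * dm[2], dm[3])
  for (c_ in seq_len(dm[3])) tok[, c_] <- as.vector(t(x[, , c_]))
  r <- dwconv_fwd(tok, kern, bias, dm[1], dm[2])
  out <- array(0, dim = dm)
  for (c_ in seq_len(dm[3])) out[, , c_] <- matrix(r$out[, c_], dm[1], dm[2], byrow = TRUE)
  list(out = out, cache = r$cache)
}

dwconv_img_bwd <- function(dout, cache, kern) {
  dm <- dim(dout)
  dtok <- matrix(0, dm[1] * dm[2], dm[3])
  for (c_ in seq_len(dm[3])) dtok[, c_] <- as.vector(t(dout[, , c_]))
  r <- dwconv_bwd(dtok, cache, kern)
  dx <- array(0, dim = dm)
  for (c_ in seq_len(dm[3])) dx[, , c_] <- matrix(r$dx[, c_], dm[1], dm[2], byrow = TRUE)
  list(dx = dx, dk = r$dk, db = r$db)
}
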