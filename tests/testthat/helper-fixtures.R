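# Shared fixtures and oracles for the test suite.

# Lazily generated 6-class imbalanced fixture set (32 px, separable hues),
# created once per test run and reused.
fixture_dir_small <- local({
  dir <- NULL
  function() {
    if (is.null(dir) || !dir.exists(dir)) {
      dir <<- file.path(tempdir(), "hybridmae_fixtures_small")
      spec <- fixture_spec(n_classes = 6,
                          counts_per_class = c(40, 35, 30, 25, 20, 15),
                          image_size = 32, seed = 101)
      generate_dataset(spec, dir)
    }
    dir
  }
})

random_rgb <- function(h, w = h, scale = 255) {
  array(stats::runif(h * w * 3, 0, scale), dim = c(h, w, 3))
}

# Nested-list accessors for gradient checks.
get_in <- function(x, path) {
  for (k in path) x <- x[[k]]
  x
}
set_in <- function(x, path, val) {
  if (length(path) == 1) {
    x[[path[[1]]]] <- val
    return(x)
  }
  x[[path[[1]]]] <- set_in(x[[path[[1]]]], path[-1], val)
  x
}

# Independent minimal masked-autoencoder forward pass, written with explicit
# per-token loops and its own softmax/layernorm code. Used as the oracle for
# the ablation-reducibility check: with every switch off, the package's
# forward pass must agree with this one on shared weights.
ref_mae_forward <- function(params, cfg, image, partition) {
  P <- cfg$patch_size
  gh <- cfg$grid_h; gw <- cfg$grid_w
  N <- cfg$N
  pd <- P * P * 3
  # patchify, row-major
  patches <- matrix(0, N, pd)
  for (gi in 1:gh) for (gj in 1:gw) {
    block <- image[((gi - 1) * P + 1):(gi * P), ((gj - 1) * P + 1):(gj * P), ]
    patches[(gi - 1) * gw + gj, ] <- as.vector(block)
  }
  ref_ln <- function(v, g, b, eps = 1e-6) {
    mu <- mean(v)
    s <- sqrt(mean((v - mu)^2) + eps)
    ((v - mu) / s) * g + b
  }
  ref_softmax <- function(v) {
    e <- exp(v - max(v))
    e / sum(e)
  }
  ref_block <- function(x, p, n_heads) {
    Tn <- nrow(x); d <- ncol(x); dh <- d / n_heads
    xl <- t(apply(x, 1, ref_ln, g = p$ln1_g, b = p$ln1_b))
    q <- xl %*% p$Wq + matrix(p$bq, Tn, d, byrow = TRUE)
    k <- xl %*% p$Wk + matrix(p$bk, Tn, d, byrow = TRUE)
    v <- xl %*% p$Wv + matrix(p$bv, Tn, d, byrow = TRUE)
    O <- matrix(0, Tn, d)
    for (h in 1:n_heads) {
      idx <- ((h - 1) * dh + 1):(h * dh)
      for (i in 1:Tn) {
        scores <- numeric(Tn)
        for (j in 1:Tn) {
          scores[j] <- sum(q[i, idx] * k[j, idx]) / sqrt(dh)
        }
        a <- ref_softmax(scores)
        for (j in 1:Tn) O[i, idx] <- O[i, idx] + a[j] * v[j, idx]
      }
    }
    z <- x + O %*% p$Wo + matrix(p$bo, Tn, d, byrow = TRUE)
    zl <- t(apply(z, 1, ref_ln, g = p$ln2_g, b = p$ln2_b))
    h1 <- zl %*% p$W1 + matrix(p$b1, Tn, ncol(p$W1), byrow = TRUE)
    h1 <- h1 * stats::pnorm(h1)
    f <- z + h1 %*% p$W2 + matrix(p$b2, Tn, d, byrow = TRUE)
    t(apply(f, 1, ref_ln, g = p$ln3_g, b = p$ln3_b))
  }
  vis <- partition$visible_indices
  d <- cfg$embed_dim
  tok <- matrix(0, 1 + length(vis), d)
  tok[1, ] <- params$cls_token + params$E_pos[1, ]
  for (r in seq_along(vis)) {
    tok[r + 1, ] <- patches[vis[r] + 1, ] %*% params$W_embed + params$b_embed +
      params$E_pos[vis[r] + 2, ]
  }
  for (l in seq_len(cfg$encoder_depth)) {
    tok <- ref_block(tok, params$enc[[l]], cfg$n_heads)
  }
  enc_out <- tok
  # decoder
  dd <- cfg$decoder_dim
  demb <- enc_out %*% params$W_dec_embed +
    matrix(params$b_dec_embed, nrow(enc_out), dd, byrow = TRUE)
  full <- matrix(0, N + 1, dd)
  full[1, ] <- demb[1, ]
  for (r in seq_along(vis)) full[vis[r] + 2, ] <- demb[r + 1, ]
  for (mi in partition$masked_indices) full[mi + 2, ] <- params$mask_token
  full <- full + params$dec_pos
  for (l in seq_len(cfg$decoder_depth)) {
    full <- ref_block(full, params$dec[[l]], cfg$n_heads)
  }
  full <- t(apply(full, 1, ref_ln, g = params$dec_ln_g, b = params$dec_ln_b))
  recon <- full[-1, , drop = FALSE] %*% params$W_dec_head +
    matrix(params$b_dec_head, N, pd, byrow = TRUE)
  list(encoder_tokens = enc_out, reconstruction = recon)
}
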