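make_tiny_model <- function(..., seed = 7) {
  cfg <- tiny_model_config(n_classes = 3, image_size = 16L, patch_size = 8L,
                           embed_dim = 8L, encoder_depth = 1L, n_heads = 2L,
                           decoder_dim = 8L, decoder_depth = 1L, ...)
  init_model(cfg, seed = seed)
}

test_that("attention rows are normalized and match a scalar brute-force oracle", {
  # softmax rows sum to 1 on a random sequence
  set.seed(5)
  x <- matrix(stats::rnorm(6 * 8), 6, 8)
  p <- hybridmae:::make_block_params(8, FALSE, 3L)
  att <- hybridmae:::mhsa_fwd(x, p, 2)
  for (A in att$cache$A) {
    expect_equal(rowSums(A), rep(1, nrow(A)), tolerance = 1e-6)
  }
  # single token: attention output equals the V row through the output proj
  x1 <- matrix(stats::rnorm(8), 1, 8)
  att1 <- hybridmae:::mhsa_fwd(x1, p, 2)
  v1 <- sweep(x1 %*% p$Wv, 2, p$bv, "+")
  expect_equal(att1$out, sweep(v1 %*% p$Wo, 2, p$bo, "+"), tolerance = 1e-12)
  # 2 tokens, head width 1: hand-computed softmax average
  p1 <- list(Wq = matrix(1), bq = 0, Wk = matrix(1), bk = 0,
             Wv = matrix(1), bv = 0, Wo = matrix(1), bo = 0)
  x2 <- matrix(c(0.3, -0.9), 2, 1)
  att2 <- hybridmae:::mhsa_fwd(x2, p1, 1)
  brute <- vapply(1:2, function(i) {
    s <- x2[i, 1] * x2[, 1] / 1  # q_i * k_j / sqrt(1)
    a <- exp(s - max(s)); a <- a / sum(a)
    sum(a * x2[, 1])
  }, numeric(1))
  expect_equal(as.vector(att2$out), brute, tolerance = 1e-12)
})

test_that("depthwise refinement equals a direct 2-D convolution oracle", {
  set.seed(6)
  gh <- 3; gw <- 3; d <- 1
  tokens <- matrix(stats::rnorm(9), 9, 1)
  kern <- array(stats::rnorm(9), dim = c(3, 3, 1))
  bias <- 0.37
  out <- hybridmae:::dwconv_fwd(tokens, kern, bias, gh, gw)$out
  X <- matrix(tokens[, 1], gh, gw, byrow = TRUE)
  direct <- matrix(0, gh, gw)
  for (i in 1:gh) for (j in 1:gw) {
    s <- 0
    for (u in -1:1) for (v in -1:1) {
      ii <- i + u; jj <- j + v
      if (ii >= 1 && ii <= gh && jj >= 1 && jj <= gw) {
        s <- s + kern[u + 2, v + 2, 1] * X[ii, jj]
      }
    }
    direct[i, j] <- s + bias
  }
  expect_equal(matrix(out[, 1], gh, gw, byrow = TRUE), direct, tolerance = 1e-12)
  # identity kernel (center 1) with zero bias leaves tokens unchanged
  ik <- array(0, dim = c(3, 3, 4))
  ik[2, 2, ] <- 1
  tk <- matrix(stats::rnorm(16 * 4), 16, 4)
  expect_equal(hybridmae:::dwconv_fwd(tk, ik, rep(0, 4), 4, 4)$out, tk)
  # constant field under an averaging kernel stays constant in the interior
  ak <- array(1 / 9, dim = c(3, 3, 1))
  cf <- matrix(2.5, 25, 1)
  outc <- hybridmae:::dwconv_fwd(cf, ak, 0, 5, 5)$out
  expect_equal(matrix(outc, 5, 5, byrow = TRUE)[2:4, 2:4],
               matrix(2.5, 3, 3))
  expect_error(hybridmae:::dwconv_fwd(tk, ik, rep(0, 4), 3, 4),
               class = "hybridmae_validation_error")
})

test_that("decoder restores order, shares the mask token, covers all patches", {
  m <- make_tiny_model()
  set.seed(1)
  img <- random_rgb(16, scale = 1)
  part <- random_mask(4, 0.5)
  fw <- model_forward(m, img, part)
  expect_equal(nrow(fw$reconstruction), m$cfg$N)  # all N patches predicted
  expect_equal(ncol(fw$reconstruction), 8 * 8 * 3)
  # shared mask token: before position addition every masked slot holds the
  # same vector -- verify via the forward internals
  emb <- fw$cache$dec$emb$out
  # reconstruct the pre-position decoder input
  full <- matrix(0, m$cfg$N + 1, m$cfg$decoder_dim)
  full[1, ] <- emb[1, ]
  full[part$visible_indices + 2, ] <- emb[-1, , drop = FALSE]
  for (mi in part$masked_indices) {
    full[mi + 2, ] <- m$params$mask_token
  }
  # all masked rows identical
  msk_rows <- full[part$masked_indices + 2, , drop = FALSE]
  expect_true(all(apply(msk_rows, 2, function(col) diff(range(col)) == 0)))
  expect_error(model_forward(m, img,
                             structure(list(masked_indices = 0L,
                                            visible_indices = 1:7, N = 8L,
                                            mask_ratio = 0.1),
                                       class = "mask_partition")),
               class = "hybridmae_validation_error")
})

test_that("masked-decoder interpolation: uniform attention yields the mean of visible rows", {
  # closed-form oracle: a decoder attention layer whose weights are uniform
  # over a set U returns, for every query, the mean of the rows in U.
  set.seed(10)
  d <- 4
  V <- matrix(stats::rnorm(6 * d), 6, d)
  U <- c(2, 3, 5)
  a <- rep(1 / length(U), length(U))
  interp <- colSums(V[U, ] * a)
  expect_equal(interp, colMeans(V[U, ]))
  # realized in-attention: identical keys force uniform weights over all rows
  p <- hybridmae:::make_block_params(d, FALSE, 3L)
  p$Wk <- matrix(0, d, d)  # keys collapse -> softmax uniform
  x <- matrix(stats::rnorm(5 * d), 5, d)
  att <- hybridmae:::mhsa_fwd(x, p, 1)
  v <- sweep(x %*% p$Wv, 2, p$bv, "+")
  expected <- matrix(colMeans(v), 5, d, byrow = TRUE)
  expect_equal(sweep(att$cache$O, 2, rep(0, d), "+"), expected,
               tolerance = 1e-12)
})

test_that("classification head: zero weights give uniform softmax; logits length matches", {
  m <- make_tiny_model()
  m$params$W_head <- m$params$W_head * 0
  m$params$b_head <- m$params$b_head * 0
  set.seed(2)
  img <- random_rgb(16, scale = 1)
  fw <- model_forward(m, img, NULL, with_decoder = FALSE)
  expect_equal(fw$logits, rep(0, 3))
  expect_equal(hybridmae:::softmax_vec(fw$logits), rep(1 / 3, 3))
  # 14-class configuration mirrors the published class count
  cfg14 <- tiny_model_config(n_classes = 14L)
  m14 <- init_model(cfg14, seed = 1)
  img32 <- random_rgb(32, scale = 1)
  expect_length(model_forward(m14, img32, NULL, FALSE)$logits, 14)
  # disabled branch refuses prediction
  moff <- init_model(tiny_model_config(n_classes = 3, use_cls_branch = FALSE),
                     seed = 1)
  expect_error(model_predict(moff, list(img32)),
               class = "hybridmae_validation_error")
})

test_that("with all switches off the forward pass matches the reference MAE", {
  cfg <- tiny_model_config(n_classes = 3, use_depthwise_conv = FALSE,
                           use_conv_stem = FALSE, use_cls_branch = FALSE)
  m <- init_model(cfg, seed = 21)
  set.seed(22)
  img <- random_rgb(32, scale = 1)
  part <- random_mask(cfg$N, 0.75)
  fw <- model_forward(m, img, part)
  ref <- ref_mae_forward(m$params, cfg, img, part)
  expect_lt(max(abs(fw$encoder_tokens - ref$encoder_tokens)), 1e-5)
  expect_lt(max(abs(fw$reconstruction - ref$reconstruction)), 1e-5)
})

test_that("analytic gradients match finite differences across the model", {
  m <- make_tiny_model()
  set.seed(31)
  img <- random_rgb(16, scale = 1)
  part <- random_mask(4, 0.5)
  lc <- loss_config(n_classes = 3)
  fw <- model_forward(m, img, part)
  bw <- model_backward(m, fw, 1L, lc)
  loss_at <- function(params) {
    mm <- m; mm$params <- params
    model_backward(mm, model_forward(mm, img, part), 1L, lc)$loss_total
  }
  h <- 1e-5
  paths <- list(list("W_embed"), list("cls_token"), list("E_pos"),
                list("enc", 1L, "Wq"), list("enc", 1L, "W1"),
                list("enc", 1L, "ln1_g"), list("mask_token"),
                list("dec", 1L, "Wv"), list("dec", 1L, "dw_k"),
                list("dec_pos"), list("W_dec_head"), list("W_head"),
                list("head_ln_g"))
  set.seed(32)
  for (path in paths) {
    x <- get_in(m$params, path)
    idx <- sample(length(x), 1)
    xp <- x; xp[idx] <- xp[idx] + h
    xm <- x; xm[idx] <- xm[idx] - h
    num <- (loss_at(set_in(m$params, path, xp)) -
            loss_at(set_in(m$params, path, xm))) / (2 * h)
    ana <- get_in(bw$grads, path)[idx]
    expect_equal(ana, num, tolerance = 1e-4,
                 label = paste(unlist(path), collapse = "/"))
  }
})

test_that("classification loss sends gradient into the shared encoder", {
  m <- make_tiny_model()
  set.seed(41)
  img <- random_rgb(16, scale = 1)
  lc <- loss_config(n_classes = 3, w_mse = 0, w_cls = 1)
  fw <- model_forward(m, img, NULL, with_decoder = FALSE)
  bw <- model_backward(m, fw, 0L, lc)
  expect_gt(sum(abs(bw$grads$enc[[1]]$Wq)), 0)
  expect_gt(sum(abs(bw$grads$W_embed)), 0)
})

test_that("forward pass is deterministic and mask-ratio 0 sees all tokens", {
  m <- make_tiny_model()
  set.seed(51)
  img <- random_rgb(16, scale = 1)
  fw1 <- model_forward(m, img, NULL, with_decoder = TRUE)
  fw2 <- model_forward(m, img, NULL, with_decoder = TRUE)
  expect_identical(fw1$encoder_tokens, fw2$encoder_tokens)
  expect_equal(nrow(fw1$encoder_tokens), 1 + m$cfg$N)
})

test_that("checkpoints round-trip parameters and validate their header", {
  m <- make_tiny_model()
  path <- file.path(tempdir(), "ckpt_test.rds")
  save_checkpoint(m, path, extra = list(phase = "pretrain", epoch = 2))
  expect_true(file.exists(paste0(path, ".json")))
  m2 <- load_checkpoint(path)
  expect_equal(m2$params, m$params)
  expect_equal(m2$cfg$embed_dim, m$cfg$embed_dim)
  hdr <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(hdr$phase, "pretrain")
  bad <- file.path(tempdir(), "ckpt_bad.rds")
  saveRDS(list(header = list(config = list(image_size = 16)), params = list()),
          bad)
  expect_error(load_checkpoint(bad), class = "hybridmae_validation_error")
})
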