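#' Model configuration for the hybrid masked autoencoder
#'
#' Defines the encoder/decoder geometry and the three ablation switches:
#' `use_conv_stem` (inverted-residual convolution stem before patch
#' projection), `use_depthwise_conv` (depthwise-convolution refinement of
#' transformer blocks) and `use_cls_branch` (parallel supervised
#' classification head). With all three off the model reduces to a plain
#' masked autoencoder.
#'
#' @param image_size input side in pixels; must be divisible by `patch_size`.
#' @param patch_size patch side P in pixels.
#' @param embed_dim encoder token dimension d; divisible by `n_heads`.
#' @param encoder_depth number of encoder transformer blocks.
#' @param n_heads attention heads.
#' @param decoder_dim,decoder_depth decoder geometry (default dim d/2).
#' @param n_classes number of target classes.
#' @param mask_ratio fraction of patches masked during pre-training.
#' @param use_depthwise_conv,use_conv_stem,use_cls_branch ablation switches.
#' @param dw_kernel odd side of the depthwise kernel.
#' @return a `model_config` list.
#' @export
model_config <- function(image_size = 224L, patch_size = 16L, embed_dim = 192L,
                         encoder_depth = 4L, n_heads = 3L,
                         decoder_dim = embed_dim %/% 2L, decoder_depth = 4L,
                         n_classes = 14L, mask_ratio = 0.75,
                         use_depthwise_conv = TRUE, use_conv_stem = FALSE,
                         use_cls_branch = TRUE, dw_kernel = 3L) {
  check_that(image_size %% patch_size == 0, "image_size must be divisible by patch_size")
  check_that(embed_dim %% n_heads == 0, "embed_dim must be divisible by n_heads")
  check_that(dw_kernel %% 2 == 1, "dw_kernel must be odd")
  check_that(mask_ratio >= 0 && mask_ratio < 1, "mask_ratio must be in [0,1)")
  grid <- image_size %/% patch_size
  structure(list(image_size = as.integer(image_size),
                 patch_size = as.integer(patch_size),
                 embed_dim = as.integer(embed_dim),
                 encoder_depth = as.integer(encoder_depth),
                 n_heads = as.integer(n_heads),
                 decoder_dim = as.integer(decoder_dim),
                 decoder_depth = as.integer(decoder_depth),
                 n_classes = as.integer(n_classes),
                 mask_ratio = mask_ratio,
                 use_depthwise_conv = isTRUE(use_depthwise_conv),
                 use_conv_stem = isTRUE(use_conv_stem),
                 use_cls_branch = isTRUE(use_cls_branch),
                 dw_kernel = as.integer(dw_kernel),
                 grid_h = grid, grid_w = grid,
                 N = grid * grid),
            class = "model_config")
}

#' Desk-scale model configuration
#'
#' A small configuration (32x32 input, 8-pixel patches, 64-dim tokens,
#' depth-2 encoder) that trains in minutes on one CPU; used throughout the
#' tests and examples.
#'
#' @param n_classes number of classes.
#' @param ... overrides passed to [model_config()].
#' @export
tiny_model_config <- function(n_classes = 6L, ...) {
  args <- list(image_size = 32L, patch_size = 8L, embed_dim = 64L,
               encoder_depth = 2L, n_heads = 4L, decoder_dim = 32L,
               decoder_depth = 2L, n_classes = n_classes)
  override <- list(...)
  args[names(override)] <- override
  do.call(model_config, args)
}

make_block_params <- function(d, with_dw, dw_kernel, mlp_ratio = 4L) {
  hidden <- d * mlp_ratio
  p <- list(
    ln1_g = rep(1, d), ln1_b = rep(0, d),
    Wq = matrix(trunc_normal(d * d), d, d), bq = rep(0, d),
    Wk = matrix(trunc_normal(d * d), d, d), bk = rep(0, d),
    Wv = matrix(trunc_normal(d * d), d, d), bv = rep(0, d),
    Wo = matrix(trunc_normal(d * d), d, d), bo = rep(0, d),
    ln2_g = rep(1, d), ln2_b = rep(0, d),
    W1 = matrix(trunc_normal(d * hidden), d, hidden), b1 = rep(0, hidden),
    W2 = matrix(trunc_normal(hidden * d), hidden, d), b2 = rep(0, d),
    ln3_g = rep(1, d), ln3_b = rep(0, d))
  if (with_dw) {
    # zero kernel => refinement starts as identity (residual form)
    p$dw_k <- array(0, dim = c(dw_kernel, dw_kernel, d))
    p$dw_b <- rep(0, d)
  }
  p
}

make_stem_block_params <- function(channels = 3L, expansion = 4L, k = 3L) {
  mid <- channels * expansion
  list(We = matrix(trunc_normal(channels * mid), channels, mid), be = rep(0, mid),
       dw_k = matrix_to_dwkern(k, mid), dw_b = rep(0, mid),
       # zero projection => stem starts as identity (residual form)
       Wp = matrix(0, mid, channels), bp = rep(0, channels))
}

matrix_to_dwkern <- function(k, channels) {
  kern <- array(trunc_normal(k * k * channels, sd = 0.1), dim = c(k, k, channels))
  kern
}

#' Initialize model parameters
#'
#' Truncated-normal weights (sd 0.02), zero biases, unit layer-norm gains.
#' Depthwise refinement kernels and the stem's projection start at zero so
#' both residual refinements begin as identity maps.
#'
#' @param cfg a [model_config()].
#' @param seed integer seed.
#' @return a `hybridmae_model`: list with `cfg` and nested `params`.
#' @export
init_model <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "model_config"))
  d <- cfg$embed_dim; dd <- cfg$decoder_dim
  pd <- cfg$patch_size^2 * 3L
  N <- cfg$N
  params <- with_seed(seed, {
    p <- list(
      W_embed = matrix(trunc_normal(pd * d), pd, d), b_embed = rep(0, d),
      cls_token = matrix(trunc_normal(d), 1, d),
      E_pos = matrix(trunc_normal((N + 1L) * d), N + 1L, d),
      enc = lapply(seq_len(cfg$encoder_depth), function(i)
        make_block_params(d, cfg$use_depthwise_conv, cfg$dw_kernel)),
      W_dec_embed = matrix(trunc_normal(d * dd), d, dd), b_dec_embed = rep(0, dd),
      mask_token = matrix(trunc_normal(dd), 1, dd),
      dec_pos = matrix(trunc_normal((N + 1L) * dd), N + 1L, dd),
      dec = lapply(seq_len(cfg$decoder_depth), function(i)
        make_block_params(dd, cfg$use_depthwise_conv, cfg$dw_kernel)),
      dec_ln_g = rep(1, dd), dec_ln_b = rep(0, dd),
      W_dec_head = matrix(trunc_normal(dd * pd), dd, pd), b_dec_head = rep(0, pd),
      head_ln_g = rep(1, d), head_ln_b = rep(0, d),
      W_head = matrix(trunc_normal(d * cfg$n_classes), d, cfg$n_classes),
      b_head = rep(0, cfg$n_classes))
    if (cfg$use_conv_stem) {
      p$stem <- list(make_stem_block_params(), make_stem_block_params())
    }
    p
  })
  structure(list(cfg = cfg, params = params), class = "hybridmae_model")
}

# --- transformer block ------------------------------------------------------

# Pre-norm residual attention, residual FFN with outer layer norm, optional
# depthwise-convolution refinement of the (full) token grid:
#   Z  = x + MHSA(LN(x))
#   y' = LN(Z + FFN(LN(Z)))
#   y  = y' + DepthConv(y')        (refinement; class token bypasses)
block_fwd <- function(x, p, n_heads, refine, grid_h, grid_w) {
  ln1 <- layernorm_fwd(x, p$ln1_g, p$ln1_b)
  att <- mhsa_fwd(ln1$out, p, n_heads)
  z1 <- x + att$out
  ln2 <- layernorm_fwd(z1, p$ln2_g, p$ln2_b)
  ff1 <- linear_fwd(ln2$out, p$W1, p$b1)
  ge <- gelu_fwd(ff1$out)
  ff2 <- linear_fwd(ge$out, p$W2, p$b2)
  f <- z1 + ff2$out
  ln3 <- layernorm_fwd(f, p$ln3_g, p$ln3_b)
  y <- ln3$out
  dwc <- NULL
  if (refine) {
    body <- y[-1, , drop = FALSE]
    dwc <- dwconv_fwd(body, p$dw_k, p$dw_b, grid_h, grid_w)
    y[-1, ] <- body + dwc$out
  }
  list(out = y,
       cache = list(ln1 = ln1, att = att, ln2 = ln2, ff1 = ff1, ge = ge,
                    ff2 = ff2, ln3 = ln3, dwc = dwc, refine = refine))
}

block_bwd <- function(dy, cache, p) {
  g <- list()
  if (cache$refine) {
    dbody <- dy[-1, , drop = FALSE]
    r <- dwconv_bwd(dbody, cache$dwc$cache, p$dw_k)
    g$dw_k <- r$dk; g$dw_b <- r$db
    dy[-1, ] <- dbody + r$dx
  }
  l3 <- layernorm_bwd(dy, cache$ln3$cache, p$ln3_g)
  g$ln3_g <- l3$dg; g$ln3_b <- l3$db
  df <- l3$dx
  dz1 <- df
  f2 <- linear_bwd(df, cache$ff2$cache, p$W2)
  g$W2 <- f2$dW; g$b2 <- f2$db
  dge <- gelu_bwd(f2$dx, cache$ge$cache)
  f1 <- linear_bwd(dge, cache$ff1$cache, p$W1)
  g$W1 <- f1$dW; g$b1 <- f1$db
  l2 <- layernorm_bwd(f1$dx, cache$ln2$cache, p$ln2_g)
  g$ln2_g <- l2$dg; g$ln2_b <- l2$db
  dz1 <- dz1 + l2$dx
  at <- mhsa_bwd(dz1, cache$att$cache, p)
  g$Wq <- at$dWq; g$bq <- at$dbq; g$Wk <- at$dWk; g$bk <- at$dbk
  g$Wv <- at$dWv; g$bv <- at$dbv; g$Wo <- at$dWo; g$bo <- at$dbo
  l1 <- layernorm_bwd(at$dx, cache$ln1$cache, p$ln1_g)
  g$ln1_g <- l1$dg; g$ln1_b <- l1$db
  list(dx = dz1 + l1$dx, grads = g)
}

# --- inverted-residual stem -------------------------------------------------

stem_block_fwd <- function(x, p) {
  e <- conv1x1_fwd(x, p$We, p$be)
  g1 <- gelu_fwd(e$out)
  dw <- dwconv_img_fwd(g1$out, p$dw_k, p$dw_b)
  g2 <- gelu_fwd(dw$out)
  pr <- conv1x1_fwd(g2$out, p$Wp, p$bp)
  list(out = x + pr$out,
       cache = list(e = e, g1 = g1, dw = dw, g2 = g2, pr = pr))
}

stem_block_bwd <- function(dout, cache, p) {
  pr <- conv1x1_bwd(dout, cache$pr$cache, p$Wp)
  dg2 <- gelu_bwd(pr$dx, cache$g2$cache)
  dw <- dwconv_img_bwd(dg2, cache$dw$cache, p$dw_k)
  dg1 <- gelu_bwd(dw$dx, cache$g1$cache)
  e <- conv1x1_bwd(dg1, cache$e$cache, p$We)
  list(dx = dout + e$dx,
       grads = list(We = e$dW, be = e$db, dw_k = dw$dk, dw_b = dw$db,
                    Wp = pr$dW, bp = pr$db))
}

# --- full forward -----------------------------------------------------------

#' Forward pass of the hybrid masked autoencoder on one image
#'
#' Runs (optional stem) -> patchify -> mask -> embed -> encoder blocks,
#' then the reconstruction decoder (mask token inserted at every masked
#' index, sequence unshuffled, positions re-added) and, if enabled, the
#' parallel classification head on the encoder's class token. Depthwise
#' refinement acts where a full token grid exists: inside decoder blocks
#' during masked pre-training, inside encoder blocks when all patches are
#' visible.
#'
#' @param model a `hybridmae_model`.
#' @param image `H x W x 3` array with values in `[0, 1]`.
#' @param partition a `mask_partition`, or `NULL` to treat all patches as
#'   visible.
#' @param with_decoder run the reconstruction decoder (TRUE for
#'   pre-training; finetuning and prediction skip it).
#' @param keep_cache retain intermediate activations for [model_backward()].
#' @return list with `logits` (or NULL), `reconstruction` (`N x P^2*3` or
#'   NULL), `target_patches`, `partition`, `encoder_tokens`, and `cache`.
#' @export
model_forward <- function(model, image, partition = NULL,
                          with_decoder = TRUE, keep_cache = TRUE) {
  cfg <- model$cfg; pp <- model$params
  check_that(all(dim(image)[1:2] == cfg$image_size),
             "image size mismatch: expected ", cfg$image_size)
  if (is.null(partition)) {
    partition <- structure(list(masked_indices = integer(0),
                                visible_indices = seq_len(cfg$N) - 1L,
                                N = cfg$N, mask_ratio = 0),
                           class = "mask_partition")
  }
  check_that(partition$N == cfg$N, "partition/token mismatch: N differs")
  target_grid <- patchify(image, cfg$patch_size)

  stem_caches <- NULL
  x_img <- image
  if (cfg$use_conv_stem) {
    stem_caches <- vector("list", length(pp$stem))
    for (i in seq_along(pp$stem)) {
      s <- stem_block_fwd(x_img, pp$stem[[i]])
      stem_caches[[i]] <- s$cache
      x_img <- s$out
    }
  }
  grid <- if (cfg$use_conv_stem) patchify(x_img, cfg$patch_size) else target_grid

  tokens <- embed_tokens(grid, partition, pp$W_embed, pp$b_embed,
                         pp$cls_token, pp$E_pos)
  all_visible <- length(partition$visible_indices) == cfg$N
  enc_refine <- cfg$use_depthwise_conv && all_visible
  enc_caches <- vector("list", cfg$encoder_depth)
  for (l in seq_len(cfg$encoder_depth)) {
    b <- block_fwd(tokens, pp$enc[[l]], cfg$n_heads, enc_refine,
                   cfg$grid_h, cfg$grid_w)
    enc_caches[[l]] <- b$cache
    tokens <- b$out
  }
  enc_out <- tokens

  logits <- NULL; cls_cache <- NULL
  if (cfg$use_cls_branch) {
    cls_cache <- list()
    cls_cache$ln <- layernorm_fwd(enc_out[1, , drop = FALSE],
                                  pp$head_ln_g, pp$head_ln_b)
    cls_cache$lin <- linear_fwd(cls_cache$ln$out, pp$W_head, pp$b_head)
    logits <- as.vector(cls_cache$lin$out)
  }

  recon <- NULL; dec_cache <- NULL
  if (with_decoder) {
    dec_cache <- list()
    dec_cache$emb <- linear_fwd(enc_out, pp$W_dec_embed, pp$b_dec_embed)
    dd <- cfg$decoder_dim
    full <- matrix(0, cfg$N + 1L, dd)
    full[1L, ] <- dec_cache$emb$out[1L, ]
    vis <- partition$visible_indices
    if (length(vis) > 0) full[vis + 2L, ] <- dec_cache$emb$out[-1L, , drop = FALSE]
    msk <- partition$masked_indices
    if (length(msk) > 0) {
      full[msk + 2L, ] <- matrix(pp$mask_token, length(msk), dd, byrow = TRUE)
    }
    full <- full + pp$dec_pos
    dec_refine <- cfg$use_depthwise_conv
    dec_cache$blocks <- vector("list", cfg$decoder_depth)
    dtok <- full
    for (l in seq_len(cfg$decoder_depth)) {
      b <- block_fwd(dtok, pp$dec[[l]], cfg$n_heads, dec_refine,
                     cfg$grid_h, cfg$grid_w)
      dec_cache$blocks[[l]] <- b$cache
      dtok <- b$out
    }
    dec_cache$ln <- layernorm_fwd(dtok, pp$dec_ln_g, pp$dec_ln_b)
    body <- dec_cache$ln$out[-1L, , drop = FALSE]
    dec_cache$head <- linear_fwd(body, pp$W_dec_head, pp$b_dec_head)
    recon <- dec_cache$head$out
  }

  cache <- NULL
  if (keep_cache) {
    cache <- list(grid = grid, partition = partition, enc = enc_caches,
                  cls = cls_cache, dec = dec_cache, stem = stem_caches,
                  enc_out = enc_out, image = image)
  }
  list(logits = logits, reconstruction = recon,
       target_patches = target_grid$patch_vectors,
       partition = partition, encoder_tokens = enc_out, cache = cache)
}

#' Backward pass: gradients of the combined loss for one image
#'
#' Seeds the chain with the analytic gradients of the reconstruction MSE
#' (`d recon = 2 w_mse (recon - target) / n_selected_values`) and the
#' label-smoothed cross entropy (`d logits = w_cls (softmax(logits) - y)`),
#' then backpropagates through decoder, classification head, encoder,
#' embedding and (optionally) the stem.
#'
#' @param model a `hybridmae_model`.
#' @param fw result of [model_forward()] with `keep_cache = TRUE`.
#' @param label 0-based true class, or `NULL` to skip the classification term.
#' @param loss_cfg a [loss_config()].
#' @return list with `grads` (same shape as `model$params`), `loss_mse`,
#'   `loss_cls`, `loss_total`.
#' @export
model_backward <- function(model, fw, label, loss_cfg) {
  cfg <- model$cfg; pp <- model$params
  cache <- fw$cache
  check_that(!is.null(cache), "forward pass was run with keep_cache = FALSE")
  part <- fw$partition
  g <- list()

  l_mse <- 0; l_cls <- 0
  denc_out <- matrix(0, nrow(cache$enc_out), ncol(cache$enc_out))

  # decoder branch
  if (!is.null(fw$reconstruction) && loss_cfg$w_mse > 0) {
    sel <- mse_selected_rows(part, loss_cfg$recon_scope)
    diff <- fw$reconstruction - fw$target_patches
    n_val <- length(sel) * ncol(diff)
    l_mse <- sum(diff[sel, , drop = FALSE]^2) / n_val
    dpred <- matrix(0, nrow(diff), ncol(diff))
    dpred[sel, ] <- 2 * loss_cfg$w_mse * diff[sel, , drop = FALSE] / n_val

    hd <- linear_bwd(dpred, cache$dec$head$cache, pp$W_dec_head)
    g$W_dec_head <- hd$dW; g$b_dec_head <- hd$db
    dln_out <- rbind(0, hd$dx)
    ln <- layernorm_bwd(dln_out, cache$dec$ln$cache, pp$dec_ln_g)
    g$dec_ln_g <- ln$dg; g$dec_ln_b <- ln$db
    dtok <- ln$dx
    g$dec <- vector("list", cfg$decoder_depth)
    for (l in rev(seq_len(cfg$decoder_depth))) {
      b <- block_bwd(dtok, cache$dec$blocks[[l]], pp$dec[[l]])
      g$dec[[l]] <- b$grads
      dtok <- b$dx
    }
    g$dec_pos <- dtok
    msk <- part$masked_indices
    g$mask_token <- if (length(msk) > 0) {
      matrix(colSums(dtok[msk + 2L, , drop = FALSE]), 1)
    } else matrix(0, 1, cfg$decoder_dim)
    ddemb <- matrix(0, nrow(cache$enc_out), cfg$decoder_dim)
    ddemb[1L, ] <- dtok[1L, ]
    vis <- part$visible_indices
    if (length(vis) > 0) ddemb[-1L, ] <- dtok[vis + 2L, , drop = FALSE]
    de <- linear_bwd(ddemb, cache$dec$emb$cache, pp$W_dec_embed)
    g$W_dec_embed <- de$dW; g$b_dec_embed <- de$db
    denc_out <- denc_out + de$dx
  }

  # classification branch
  if (!is.null(fw$logits) && !is.null(label) && loss_cfg$w_cls > 0) {
    y <- smooth_labels(label, loss_cfg$n_classes, loss_cfg$epsilon)
    p <- softmax_vec(fw$logits)
    l_cls <- -sum(y * log(p))
    dlogits <- matrix(loss_cfg$w_cls * (p - y), 1)
    lin <- linear_bwd(dlogits, cache$cls$lin$cache, pp$W_head)
    g$W_head <- lin$dW; g$b_head <- lin$db
    ln <- layernorm_bwd(lin$dx, cache$cls$ln$cache, pp$head_ln_g)
    g$head_ln_g <- ln$dg; g$head_ln_b <- ln$db
    denc_out[1L, ] <- denc_out[1L, ] + ln$dx
  }

  # encoder
  dtok <- denc_out
  g$enc <- vector("list", cfg$encoder_depth)
  for (l in rev(seq_len(cfg$encoder_depth))) {
    b <- block_bwd(dtok, cache$enc[[l]], pp$enc[[l]])
    g$enc[[l]] <- b$grads
    dtok <- b$dx
  }
  g$cls_token <- dtok[1L, , drop = FALSE]
  g$E_pos <- matrix(0, cfg$N + 1L, cfg$embed_dim)
  g$E_pos[1L, ] <- dtok[1L, ]
  vis <- part$visible_indices
  dvis <- dtok[-1L, , drop = FALSE]
  if (length(vis) > 0) g$E_pos[vis + 2L, ] <- dvis
  xv <- cache$grid$patch_vectors[vis + 1L, , drop = FALSE]
  g$W_embed <- t(xv) %*% dvis
  g$b_embed <- colSums(dvis)

  # stem
  if (cfg$use_conv_stem) {
    dpatch <- matrix(0, cfg$N, ncol(cache$grid$patch_vectors))
    dpatch[vis + 1L, ] <- dvis %*% t(pp$W_embed)
    dimg <- unpatchify(cache$grid, dpatch)
    g$stem <- vector("list", length(pp$stem))
    for (i in rev(seq_along(pp$stem))) {
      s <- stem_block_bwd(dimg, cache$stem[[i]], pp$stem[[i]])
      g$stem[[i]] <- s$grads
      dimg <- s$dx
    }
  }

  list(grads = g, loss_mse = l_mse, loss_cls = l_cls,
       loss_total = loss_cfg$w_mse * l_mse + loss_cfg$w_cls * l_cls)
}

softmax_vec <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

#' Class logits for a batch of images
#'
#' Full-visibility forward pass through the encoder and classification head.
#'
#' @param model a `hybridmae_model` with `use_cls_branch = TRUE`.
#' @param images list of `H x W x 3` arrays in `[0, 1]`.
#' @return `length(images) x n_classes` matrix of logits.
#' @export
model_predict <- function(model, images) {
  check_that(model$cfg$use_cls_branch,
             "classification branch is disabled in this model")
  out <- matrix(0, length(images), model$cfg$n_classes)
  for (i in seq_along(images)) {
    fw <- model_forward(model, images[[i]], partition = NULL,
                        with_decoder = FALSE, keep_cache = FALSE)
    out[i, ] <- fw$logits
  }
  out
}
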