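# Parameter trees are nested named lists of numeric arrays. These helpers
# walk two trees in lockstep; `path` accumulates dotted names such as
# "enc.1.Wq" so the optimizer can select parameter groups.

tree_map2 <- function(a, b, f, path = "") {
  if (is.list(a)) {
    out <- a
    for (nm in names(a)) {
      key <- if (is.null(names(a))) "" else nm
      out[[nm]] <- tree_map2(a[[nm]], b[[nm]], f, paste0(path, ".", key))
    }
    if (is.null(names(a))) {
      for (i in seq_along(a)) {
        out[[i]] <- tree_map2(a[[i]], b[[i]], f, paste0(path, ".", i))
      }
    }
    out
  } else {
    f(a, b, sub("^\\.", "", path))
  }
}

tree_map <- function(a, f, path = "") {
  if (is.list(a)) {
    out <- a
    if (is.null(names(a))) {
      for (i in seq_along(a)) out[[i]] <- tree_map(a[[i]], f, paste0(path, ".", i))
    } else {
      for (nm in names(a)) out[[nm]] <- tree_map(a[[nm]], f, paste0(path, ".", nm))
    }
    out
  } else {
    f(a, sub("^\\.", "", path))
  }
}

tree_zero_like <- function(a) tree_map(a, function(x, p) x * 0)

tree_add <- function(a, b) tree_map2(a, b, function(x, y, p) x + y)

# Add a possibly-incomplete gradient tree `g` into a complete accumulator
# `acc` (entries absent from `g` — e.g. decoder gradients when the decoder
# was skipped — are left unchanged).
tree_add_partial <- function(acc, g) {
  if (is.null(g)) return(acc)
  if (!is.list(acc)) return(acc + g)
  if (is.null(names(acc))) {
    for (i in seq_along(acc)) {
      if (i <= length(g)) acc[[i]] <- tree_add_partial(acc[[i]], g[[i]])
    }
  } else {
    for (nm in names(acc)) {
      if (!is.null(g[[nm]])) acc[[nm]] <- tree_add_partial(acc[[nm]], g[[nm]])
    }
  }
  acc
}

tree_scale <- function(a, s) tree_map(a, function(x, p) x * s)

tree_sq_sum <- function(a) {
  tot <- 0
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk) else tot <<- tot + sum(x^2)
    invisible(NULL)
  }
  walk(a)
  tot
}

#' Clip a gradient tree to a global norm
#'
#' @param grads nested gradient list.
#' @param max_norm positive clipping threshold.
#' @return list with `grads` (possibly rescaled) and `norm` (pre-clip value).
#' @export
clip_global_norm <- function(grads, max_norm = 1.0) {
  norm <- sqrt(tree_sq_sum(grads))
  if (is.finite(norm) && norm > max_norm) {
    grads <- tree_scale(grads, max_norm / norm)
  }
  list(grads = grads, norm = norm)
}

# Weight decay applies only to 2-D projection matrices (names starting with
# "W"); biases, gains, tokens and positional tables are exempt (standard
# transformer practice).
decay_param <- function(path) {
  leaf <- sub(".*\\.", "", path)
  startsWith(leaf, "W")
}

#' Initialize AdamW optimizer state
#'
#' @param params model parameter tree.
#' @param lr learning rate (default 1e-3).
#' @param betas length-2 vector of moment decay rates.
#' @param eps numerical floor.
#' @param weight_decay decoupled weight decay applied to projection matrices.
#' @return an `adamw_state` list.
#' @export
adamw_init <- function(params, lr = 1e-3, betas = c(0.9, 0.999), eps = 1e-8,
                       weight_decay = 0.05) {
  structure(list(m = tree_zero_like(params), v = tree_zero_like(params),
                 t = 0L, lr = lr, betas = betas, eps = eps,
                 weight_decay = weight_decay),
            class = "adamw_state")
}

#' One AdamW update
#'
#' Decoupled weight decay; `trainable` is a predicate on dotted parameter
#' paths — parameters for which it returns FALSE are left untouched (used to
#' freeze the encoder or skip the unused decoder during fine-tuning).
#'
#' @param params parameter tree.
#' @param grads matching gradient tree.
#' @param state an `adamw_state`.
#' @param lr learning rate for this step (schedules pass it per epoch).
#' @param trainable predicate `function(path) -> logical`.
#' @return list with updated `params` and `state`.
#' @export
adamw_step <- function(params, grads, state, lr = state$lr,
                       trainable = function(path) TRUE) {
  state$t <- state$t + 1L
  b1 <- state$betas[1]; b2 <- state$betas[2]
  bc1 <- 1 - b1^state$t
  bc2 <- 1 - b2^state$t
  state$m <- tree_map2(state$m, grads, function(m, g, p) {
    if (!trainable(p)) m else b1 * m + (1 - b1) * g
  })
  state$v <- tree_map2(state$v, grads, function(v, g, p) {
    if (!trainable(p)) v else b2 * v + (1 - b2) * g^2
  })
  mhat <- state$m; vhat <- state$v
  params <- tree_map2(params, tree_map2(mhat, vhat, function(m, v, p) {
    list(m = m, v = v)
  }), function(w, mv, p) {
    if (!trainable(p)) return(w)
    upd <- (mv$m / bc1) / (sqrt(mv$v / bc2) + state$eps)
    if (decay_param(p)) upd <- upd + state$weight_decay * w
    w - lr * upd
  })
  list(params = params, state = state)
}

#' Learning-rate schedules
#'
#' `schedule_steplr`: multiplies the base rate by `gamma` at each milestone
#' (defaults: 50% and 75% of the run). `schedule_cosine`: cosine annealing
#' from `lr` to ~0 over `total_epochs`.
#'
#' @param lr base learning rate.
#' @param epoch 1-based current epoch.
#' @param total_epochs run length.
#' @param gamma decay factor (default 0.1).
#' @param milestones epochs after which decay applies.
#' @return learning rate for `epoch`.
#' @export
schedule_steplr <- function(lr, epoch, total_epochs, gamma = 0.1,
                            milestones = NULL) {
  if (is.null(milestones)) {
    milestones <- unique(pmax(1L, floor(total_epochs * c(0.5, 0.75))))
  }
  lr * gamma^sum(epoch > milestones)
}

#' @rdname schedule_steplr
#' @export
schedule_cosine <- function(lr, epoch, total_epochs) {
  lr * 0.5 * (1 + cos(pi * (epoch - 1) / max(1L, total_epochs)))
}
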