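#' Loss configuration
#'
#' The combined objective is `w_mse * Loss_MSE + w_cls * Loss_LS`: a
#' reconstruction mean-squared-error plus a label-smoothed cross entropy,
#' optimized jointly. The smoothed target puts `1 - epsilon + epsilon/n` on
#' the true class and `epsilon/n` elsewhere, so it always sums to 1.
#'
#' @param epsilon smoothing factor in `[0, 1)`; default 0.25.
#' @param n_classes number of classes.
#' @param recon_scope `"all_patches"` (default: the reconstruction error is
#'   computed for every patch, visible ones included) or `"masked_only"`
#'   (classic masked-autoencoder scope).
#' @param w_mse,w_cls nonnegative term weights; defaults `(1, 1)` give the
#'   plain unweighted sum.
#' @return a `loss_config` list.
#' @export
loss_config <- function(epsilon = 0.25, n_classes = 14L,
                        recon_scope = c("all_patches", "masked_only"),
                        w_mse = 1, w_cls = 1) {
  recon_scope <- match.arg(recon_scope)
  check_that(epsilon >= 0 && epsilon < 1, "epsilon must be in [0,1)")
  check_that(w_mse >= 0 && w_cls >= 0, "loss weights must be nonnegative")
  structure(list(epsilon = epsilon, n_classes = as.integer(n_classes),
                 recon_scope = recon_scope, w_mse = w_mse, w_cls = w_cls),
            class = "loss_config")
}

mse_selected_rows <- function(partition, scope) {
  if (scope == "masked_only") {
    check_that(length(partition$masked_indices) > 0,
               "masked_only scope with an empty masked set")
    partition$masked_indices + 1L
  } else {
    seq_len(partition$N)
  }
}

#' Reconstruction mean squared error
#'
#' Mean over the selected patches (all patches, or masked only) and all
#' their pixel values of the squared reconstruction error. Zero exactly when
#' the selected reconstruction equals the target.
#'
#' @param reconstruction,target `N x (P^2*C)` matrices.
#' @param partition a `mask_partition` (needed for `masked_only`).
#' @param scope `"all_patches"` or `"masked_only"`.
#' @return nonnegative scalar.
#' @export
loss_mse <- function(reconstruction, target, partition = NULL,
                     scope = c("all_patches", "masked_only")) {
  scope <- match.arg(scope)
  check_that(all(dim(reconstruction) == dim(target)),
             "reconstruction/target shape mismatch")
  if (scope == "masked_only") {
    check_that(!is.null(partition), "masked_only scope requires a partition")
    sel <- partition$masked_indices + 1L
  } else {
    sel <- seq_len(nrow(target))
  }
  diff <- reconstruction[sel, , drop = FALSE] - target[sel, , drop = FALSE]
  sum(diff^2) / length(diff)
}

#' Label-smoothed target distribution
#'
#' @param target_class 0-based true class index.
#' @param n number of classes.
#' @param epsilon smoothing factor in `[0, 1)`.
#' @return probability vector of length `n` summing to 1:
#'   `epsilon/n` off-target, `1 - epsilon + epsilon/n` on target.
#' @export
smooth_labels <- function(target_class, n, epsilon = 0.25) {
  check_that(epsilon >= 0 && epsilon < 1, "epsilon must be in [0,1)")
  check_that(target_class >= 0 && target_class < n,
             "target_class out of range [0, ", n, ")")
  y <- rep(epsilon / n, n)
  y[target_class + 1L] <- 1 - epsilon + epsilon / n
  y
}

#' Label-smoothing cross entropy
#'
#' `-sum_i y(i) log p(x_i)` with `p = softmax(logits)` and `y` the smoothed
#' target. By Gibbs' inequality the value is at least the entropy of `y`,
#' with equality exactly when `p = y`.
#'
#' @param logits numeric vector of length `n_classes`.
#' @param target_class 0-based true class.
#' @param cfg a [loss_config()].
#' @return nonnegative scalar.
#' @export
loss_label_smooth <- function(logits, target_class, cfg) {
  check_that(all(is.finite(logits)), "non-finite logits")
  check_that(length(logits) == cfg$n_classes, "logits length != n_classes")
  y <- smooth_labels(target_class, cfg$n_classes, cfg$epsilon)
  p <- softmax_vec(logits)
  -sum(y * log(p))
}

#' Combined training objective
#'
#' @param mse_term,cls_term finite scalar loss terms.
#' @param weights length-2 nonnegative vector `(w_mse, w_cls)`.
#' @return `w_mse * mse_term + w_cls * cls_term`.
#' @export
loss_total <- function(mse_term, cls_term, weights = c(1, 1)) {
  check_that(is.finite(mse_term) && is.finite(cls_term),
             "loss terms must be finite")
  check_that(all(weights >= 0), "weights must be nonnegative")
  weights[1] * mse_term + weights[2] * cls_term
}
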