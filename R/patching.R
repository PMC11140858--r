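#' Tokenize an image into non-overlapping patches
#'
#' Splits an `h x w x C` image into `N = h * w / P^2` square patches of side
#' `P` and flattens each to a `P^2 * C` vector. Patches are ordered
#' row-major (left to right, then top to bottom) with 0-based indices; the
#' operation is lossless — [unpatchify()] reproduces the image bit-exactly.
#'
#' @param image `H x W x 3` numeric array.
#' @param P patch side in pixels; must divide both image dimensions.
#' @return a `patch_grid`: list with `patch_vectors` (`N x (P^2*C)` matrix),
#'   `P`, `grid_h`, `grid_w`, `N`, `channels`.
#' @export
patchify <- function(image, P) {
  check_that(is_rgb_array(image) || (is.array(image) && length(dim(image)) == 3L),
             "image must be an H x W x C array")
  h <- dim(image)[1]; w <- dim(image)[2]; C <- dim(image)[3]
  check_that(h %% P == 0 && w %% P == 0,
             "image dimensions (", h, "x", w, ") not divisible by patch size ",
             P, "; pad to ", P * ceiling(h / P), "x", P * ceiling(w / P))
  gh <- h %/% P; gw <- w %/% P
  N <- gh * gw
  vecs <- matrix(0, N, P * P * C)
  for (gi in seq_len(gh)) {
    for (gj in seq_len(gw)) {
      idx <- (gi - 1L) * gw + gj  # row-major
      block <- image[((gi - 1L) * P + 1L):(gi * P),
                     ((gj - 1L) * P + 1L):(gj * P), , drop = FALSE]
      vecs[idx, ] <- as.vector(block)
    }
  }
  structure(list(patch_vectors = vecs, P = as.integer(P),
                 grid_h = as.integer(gh), grid_w = as.integer(gw),
                 N = as.integer(N), channels = as.integer(C)),
            class = "patch_grid")
}

#' Reassemble an image from a patch grid
#'
#' Inverse of [patchify()]; `patch_vectors` may be replaced (e.g. by decoder
#' reconstructions) as long as the shape is unchanged.
#'
#' @param grid a `patch_grid`.
#' @param patch_vectors optional `N x (P^2*C)` replacement matrix.
#' @return `H x W x C` array.
#' @export
unpatchify <- function(grid, patch_vectors = NULL) {
  v <- if (is.null(patch_vectors)) grid$patch_vectors else patch_vectors
  check_that(nrow(v) == grid$N && ncol(v) == grid$P^2 * grid$channels,
             "patch_vectors shape mismatch")
  P <- grid$P; C <- grid$channels
  img <- array(0, dim = c(grid$grid_h * P, grid$grid_w * P, C))
  for (gi in seq_len(grid$grid_h)) {
    for (gj in seq_len(grid$grid_w)) {
      idx <- (gi - 1L) * grid$grid_w + gj
      img[((gi - 1L) * P + 1L):(gi * P),
          ((gj - 1L) * P + 1L):(gj * P), ] <- array(v[idx, ], dim = c(P, P, C))
    }
  }
  img
}

#' Draw a random visible/masked patch partition
#'
#' Samples `round(mask_ratio * N)` masked indices uniformly without
#' replacement. The masked and visible sets are disjoint and jointly cover
#' all `N` indices — the partition invariant every downstream stage relies
#' on.
#'
#' @param N total patch count.
#' @param mask_ratio fraction in `[0, 1)` of patches to mask.
#' @return a `mask_partition`: list with 0-based `masked_indices`,
#'   `visible_indices` (both sorted), `N`, `mask_ratio`.
#' @export
random_mask <- function(N, mask_ratio = 0.75) {
  check_that(mask_ratio >= 0 && mask_ratio < 1, "mask_ratio must be in [0,1)")
  check_that(N >= 1, "N must be >= 1")
  n_masked <- round(mask_ratio * N)
  masked <- if (n_masked > 0) sort(sample.int(N, n_masked)) - 1L else integer(0)
  visible <- setdiff(seq_len(N) - 1L, masked)
  structure(list(masked_indices = masked, visible_indices = visible,
                 N = as.integer(N), mask_ratio = mask_ratio),
            class = "mask_partition")
}

#' Embed visible patches into a token sequence
#'
#' Projects each visible patch vector through `W` (plus bias `b`), adds the
#' positional embedding row of the patch's original grid index (position
#' binding survives any shuffling), and prepends the class token with its
#' own positional slot (row 1 of `E_pos`).
#'
#' @param grid a `patch_grid`.
#' @param partition a `mask_partition` over `grid$N` patches.
#' @param W projection matrix, `(P^2*C) x d`.
#' @param b bias vector, length `d`.
#' @param cls_token `1 x d` class-token row.
#' @param E_pos `(1 + N) x d` positional embeddings; row 1 belongs to the
#'   class token, row `i + 2` to patch index `i`.
#' @return `(1 + N_v) x d` token matrix, class token first, visible patches
#'   in ascending index order.
#' @export
embed_tokens <- function(grid, partition, W, b, cls_token, E_pos) {
  d <- ncol(W)
  check_that(nrow(W) == ncol(grid$patch_vectors),
             "projection rows (", nrow(W), ") != patch vector length (",
             ncol(grid$patch_vectors), ")")
  check_that(length(b) == d && ncol(cls_token) == d && ncol(E_pos) == d,
             "embedding dimension mismatch")
  check_that(nrow(E_pos) == grid$N + 1L,
             "E_pos must have 1 + N rows")
  vis <- partition$visible_indices
  tok <- grid$patch_vectors[vis + 1L, , drop = FALSE] %*% W
  tok <- sweep(tok, 2, b, "+")
  tok <- tok + E_pos[vis + 2L, , drop = FALSE]
  rbind(cls_token + E_pos[1L, , drop = FALSE], tok)
}
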