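#' Run an expression under a temporary RNG state
#'
#' Seeds the R random number generator, evaluates `expr`, and restores the
#' caller's RNG state afterwards, so seeded operations never perturb the
#' global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("hybridmae_validation_error", "error")))
}

check_that <- function(ok, ...) {
  if (!isTRUE(ok)) stop_validation(...)
}

#' @keywords internal
is_rgb_array <- function(x) {
  is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 3L && is.numeric(x)
}

# Truncated-normal initializer used for all learnable weights (ViT-style),
# sd 0.02, truncated at 2 sd.
trunc_normal <- function(n, sd = 0.02) {
  x <- stats::rnorm(n, 0, sd)
  bad <- abs(x) > 2 * sd
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), 0, sd)
    bad <- abs(x) > 2 * sd
  }
  x
}

# Vectorized HSV -> RGB on [0,1] vectors; returns list(r, g, b).
hsv_to_rgb <- function(h, s, v) {
  h <- (h %% 1) * 6
  i <- floor(h)
  f <- h - i
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t <- v * (1 - s * (1 - f))
  r <- g <- b <- numeric(length(h))
  idx <- i %% 6
  sel <- idx == 0; r[sel] <- v[sel]; g[sel] <- t[sel]; b[sel] <- p[sel]
  sel <- idx == 1; r[sel] <- q[sel]; g[sel] <- v[sel]; b[sel] <- p[sel]
  sel <- idx == 2; r[sel] <- p[sel]; g[sel] <- v[sel]; b[sel] <- t[sel]
  sel <- idx == 3; r[sel] <- p[sel]; g[sel] <- q[sel]; b[sel] <- v[sel]
  sel <- idx == 4; r[sel] <- t[sel]; g[sel] <- p[sel]; b[sel] <- v[sel]
  sel <- idx == 5; r[sel] <- v[sel]; g[sel] <- p[sel]; b[sel] <- q[sel]
  list(r = r, g = g, b = b)
}
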