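#' Specification for a synthetic class-structured image dataset
#'
#' Describes a small, deterministic image dataset that emulates the relevant
#' properties of a real herbarium-style collection: each class has a distinct
#' base hue, background texture frequency and "fruit" (ellipse) shape, and
#' per-class counts can be imbalanced. The same spec (including `seed`)
#' always regenerates byte-identical PNG files.
#'
#' @param n_classes number of classes (>= 1).
#' @param counts_per_class integer vector of per-class image counts,
#'   length `n_classes`, all >= 1.
#' @param image_size side of the square images in pixels.
#' @param seed integer seed controlling every random draw.
#' @param class_params optional data.frame with columns `base_hue` in [0,1),
#'   `texture_freq` (cycles per image) and `blob_eccentricity` in [0,1),
#'   one row per class. Defaults spread hues evenly around the color wheel,
#'   which guarantees classes are separable by mean color.
#' @return an object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_classes = 6L,
                         counts_per_class = c(120L, 100L, 80L, 60L, 40L, 30L),
                         image_size = 64L,
                         seed = 1L,
                         class_params = NULL) {
  n_classes <- as.integer(n_classes)
  check_that(n_classes >= 1L, "n_classes must be >= 1")
  check_that(length(counts_per_class) == n_classes,
             "counts_per_class must have length n_classes")
  check_that(all(counts_per_class >= 1), "counts_per_class must all be >= 1")
  check_that(image_size >= 16, "image_size must be >= 16")
  if (is.null(class_params)) {
    class_params <- data.frame(
      base_hue = (seq_len(n_classes) - 1) / n_classes,
      texture_freq = 2 + (seq_len(n_classes) - 1) %% 6,
      blob_eccentricity = 0.2 + 0.5 * ((seq_len(n_classes) - 1) / max(1, n_classes - 1))
    )
  }
  check_that(nrow(class_params) == n_classes,
             "class_params must have one row per class")
  check_that(all(class_params$base_hue >= 0 & class_params$base_hue < 1),
             "base_hue must lie in [0,1)")
  structure(list(
    n_classes = n_classes,
    counts_per_class = as.integer(counts_per_class),
    image_size = as.integer(image_size),
    seed = as.integer(seed),
    class_params = class_params
  ), class = "fixture_spec")
}

# One synthetic image: sinusoidal textured background in the class hue plus a
# filled ellipse ("fruit") with jittered center, rotation and scale. Returns
# an image_size x image_size x 3 array of integer values in [0, 255].
render_fixture_image <- function(size, hue, freq, ecc) {
  cx <- size / 2 + stats::runif(1, -size / 8, size / 8)
  cy <- size / 2 + stats::runif(1, -size / 8, size / 8)
  theta <- stats::runif(1, 0, pi)
  scale <- stats::runif(1, 0.25, 0.4) * size
  phase <- stats::runif(1, 0, 2 * pi)
  tex_angle <- stats::runif(1, 0, pi)

  xs <- matrix(rep(seq_len(size), each = size), size, size)   # column index
  ys <- matrix(rep(seq_len(size), times = size), size, size)  # row index

  # background: hue-tinted sinusoidal texture
  wave <- sin(2 * pi * freq * (xs * cos(tex_angle) + ys * sin(tex_angle)) / size + phase)
  bg_v <- 0.55 + 0.15 * wave
  bg <- hsv_to_rgb(rep(hue, length(bg_v)), rep(0.85, length(bg_v)), as.vector(bg_v))

  # elliptical blob with class-specific eccentricity, slightly shifted hue
  dx <- xs - cx
  dy <- ys - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  b_axis <- scale * sqrt(1 - ecc^2)
  inside <- (u / scale)^2 + (v / b_axis)^2 <= 1
  fg <- hsv_to_rgb(rep((hue + 0.07) %% 1, sum(inside)), rep(0.95, sum(inside)),
                   rep(0.9, sum(inside)))

  img <- array(0, dim = c(size, size, 3))
  img[, , 1] <- bg$r; img[, , 2] <- bg$g; img[, , 3] <- bg$b
  ch1 <- img[, , 1]; ch2 <- img[, , 2]; ch3 <- img[, , 3]
  ch1[inside] <- fg$r; ch2[inside] <- fg$g; ch3[inside] <- fg$b
  img[, , 1] <- ch1; img[, , 2] <- ch2; img[, , 3] <- ch3

  noise <- array(stats::rnorm(size * size * 3, 0, 0.02), dim = dim(img))
  img <- pmin(pmax(img + noise, 0), 1)  # first arg keeps the dim attribute
  round(img * 255)
}

#' Generate a synthetic image dataset on disk
#'
#' Writes one subdirectory per class (`class_00`, `class_01`, ...) under
#' `out_dir`, each containing exactly `counts_per_class[c]` PNG images of
#' side `image_size`. Classes differ in mean hue by construction, so a
#' trivial mean-color classifier separates them — this guarantees that
#' training tests run on genuinely learnable data.
#'
#' @param spec a [fixture_spec()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, a manifest: named list mapping class name to the vector
#'   of written file paths.
#' @export
generate_dataset <- function(spec, out_dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  check_that(dir.exists(out_dir), "cannot create output directory ", out_dir)
  if (file.access(out_dir, 2) != 0) {
    stop(errorCondition(paste0("output directory not writable: ", out_dir),
                        class = c("hybridmae_io_error", "error")))
  }
  manifest <- list()
  with_seed(spec$seed, {
    for (c_idx in seq_len(spec$n_classes)) {
      cls <- sprintf("class_%02d", c_idx - 1)
      cls_dir <- file.path(out_dir, cls)
      dir.create(cls_dir, showWarnings = FALSE)
      p <- spec$class_params[c_idx, ]
      paths <- character(spec$counts_per_class[c_idx])
      for (i in seq_len(spec$counts_per_class[c_idx])) {
        img <- render_fixture_image(spec$image_size, p$base_hue,
                                    p$texture_freq, p$blob_eccentricity)
        paths[i] <- file.path(cls_dir, sprintf("%04d.png", i - 1))
        png::writePNG(img / 255, paths[i])
      }
      manifest[[cls]] <- paths
    }
  })
  invisible(manifest)
}

#' Per-class proportions of a dataset manifest
#'
#' The proportion vector A with A\[c\] = count_c / total feeds the
#' imbalance-aware crop threshold: minority classes (small A) receive crop
#' windows that deviate more from the nominal size.
#'
#' @param manifest either the list returned by [generate_dataset()] or a
#'   [scan_dataset()] manifest.
#' @return named numeric vector summing to 1.
#' @export
class_proportions <- function(manifest) {
  counts <- manifest_counts(manifest)
  check_that(length(counts) > 0 && sum(counts) > 0, "empty manifest")
  counts / sum(counts)
}

# Accepts either a generate_dataset() list or a dataset_manifest.
manifest_counts <- function(manifest) {
  if (inherits(manifest, "dataset_manifest")) {
    tab <- table(factor(manifest$items$class_index,
                        levels = seq_along(manifest$class_names) - 1L))
    stats::setNames(as.numeric(tab), manifest$class_names)
  } else {
    vapply(manifest, length, numeric(1))
  }
}
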