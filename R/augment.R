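#' Random shadow configuration
#'
#' @param shadow_size side of the square shadow region in pixels.
#' @param shadow_intensity integer channel decrement applied inside the
#'   shadow region (all three channels, clamped below at 0).
#' @param dark_rate probability in `[0, 1]` that an image receives a shadow.
#' @return a `shadow_config` list.
#' @export
shadow_config <- function(shadow_size = 32L, shadow_intensity = 30L,
                          dark_rate = 0.3) {
  check_that(dark_rate >= 0 && dark_rate <= 1, "dark_rate must be in [0,1]")
  check_that(shadow_intensity >= 0, "shadow_intensity must be >= 0")
  check_that(shadow_size > 0, "shadow_size must be positive")
  structure(list(shadow_size = as.integer(shadow_size),
                 shadow_intensity = shadow_intensity,
                 dark_rate = dark_rate),
            class = "shadow_config")
}

#' Apply a random square shadow to an image
#'
#' Draws `p ~ U(0, 1)`; if `p >= dark_rate` the image is returned unchanged.
#' Otherwise a random `shadow_size`-sided square fully inside the image is
#' darkened: every channel value inside it is decreased by
#' `shadow_intensity` and clamped below at 0. Pixels outside the square are
#' untouched. All arithmetic is done in doubles, so the subtraction cannot
#' underflow.
#'
#' @param image `H x W x 3` numeric array, values in `[0, 255]`.
#' @param cfg a [shadow_config()].
#' @return array of the same shape.
#' @export
apply_random_shadow <- function(image, cfg) {
  check_that(is_rgb_array(image), "image must be H x W x 3")
  h <- dim(image)[1]; w <- dim(image)[2]
  check_that(cfg$shadow_size <= min(h, w),
             "shadow_size exceeds image side (", min(h, w), ")")
  p <- stats::runif(1)
  if (p >= cfg$dark_rate) return(image)
  s <- cfg$shadow_size
  top <- sample.int(h - s + 1L, 1L)
  left <- sample.int(w - s + 1L, 1L)
  rows <- top:(top + s - 1L)
  cols <- left:(left + s - 1L)
  image[rows, cols, ] <- pmax(0, image[rows, cols, ] - cfg$shadow_intensity)
  image
}

#' Random crop configuration
#'
#' @param crop_size maximum side of the cropped region in pixels.
#' @param class_proportion_A proportion of the image's class in the training
#'   set, in `[0, 1]`; smaller (minority) proportions modulate the crop
#'   window more strongly.
#' @param d_max normalization scale for the anchor's distance from the image
#'   center, in pixels.
#' @param mode `"plus"` or `"minus"`: which branch of the threshold is used
#'   (plus enlarges the window, minus shrinks it). The training pipeline uses
#'   plus for classes at or below the median proportion and minus above.
#' @param out_size side of the resized output (model resolution).
#' @return a `crop_config` list.
#' @export
crop_config <- function(crop_size = 128L, class_proportion_A = 1,
                        d_max = 112, mode = c("plus", "minus"),
                        out_size = 224L) {
  mode <- match.arg(mode)
  check_that(crop_size > 0, "crop_size must be positive")
  check_that(class_proportion_A >= 0 && class_proportion_A <= 1,
             "class_proportion_A must be in [0,1]")
  check_that(d_max > 0, "d_max must be positive")
  structure(list(crop_size = as.integer(crop_size),
                 class_proportion_A = class_proportion_A,
                 d_max = d_max, mode = mode,
                 out_size = as.integer(out_size)),
            class = "crop_config")
}

#' Imbalance-aware crop threshold
#'
#' `gamma = 1 +/- (1 - A) * d / d_max`: the modulation factor applied to the
#' drawn crop side length. `A` is the class proportion, `d` the Euclidean
#' distance of the crop anchor from the image center. The distance enters in
#' normalized form `d / d_max` so gamma stays within
#' `[1 - (1 - A), 1 + (1 - A)]`; for `A = 1` both branches return exactly 1,
#' and minority classes (small `A`) deviate more from 1.
#'
#' @param A class proportion in `[0, 1]`.
#' @param d distance from the image center, in pixels, in `[0, d_max]`.
#' @param d_max normalization scale in pixels.
#' @param mode `"plus"` or `"minus"`.
#' @return scalar gamma.
#' @export
crop_threshold <- function(A, d, d_max = 112, mode = c("plus", "minus")) {
  mode <- match.arg(mode)
  check_that(A >= 0 && A <= 1, "A must be in [0,1]")
  check_that(d >= 0 && d <= d_max, "d must be in [0, d_max]")
  if (mode == "plus") 1 + (1 - A) * (d / d_max) else 1 - (1 - A) * (d / d_max)
}

#' Random local crop, resized to model resolution
#'
#' Draws a random anchor point and a random nominal side length
#' `L <= crop_size`, modulates the side by [crop_threshold()] evaluated at
#' the anchor's distance from the image center (so minority classes receive
#' larger effective windows under the plus branch), clips the window to the
#' image bounds, and resizes the crop bilinearly to `out_size`.
#'
#' @param image `H x W x 3` numeric array in `[0, 255]`.
#' @param cfg a [crop_config()].
#' @return `out_size x out_size x 3` array.
#' @export
apply_random_crop <- function(image, cfg) {
  check_that(is_rgb_array(image), "image must be H x W x 3")
  h <- dim(image)[1]; w <- dim(image)[2]
  check_that(cfg$crop_size <= min(h, w),
             "crop_size exceeds image side (", min(h, w), ")")
  anchor_r <- sample.int(h, 1L)
  anchor_c <- sample.int(w, 1L)
  L <- sample.int(cfg$crop_size, 1L)
  d <- sqrt((anchor_r - (h + 1) / 2)^2 + (anchor_c - (w + 1) / 2)^2)
  d <- min(d, cfg$d_max)
  gamma <- crop_threshold(cfg$class_proportion_A, d, cfg$d_max, cfg$mode)
  side <- max(8L, min(min(h, w), as.integer(round(L * gamma))))
  top <- min(anchor_r, h - side + 1L)
  left <- min(anchor_c, w - side + 1L)
  crop <- image[top:(top + side - 1L), left:(left + side - 1L), , drop = FALSE]
  resize_image(crop, cfg$out_size)
}

#' Random rotation and flip
#'
#' Applies a uniformly chosen element of the dihedral subgroup
#' \{0, 90, 180, 270 degrees\} x \{identity, horizontal flip\}. Square
#' inputs keep their shape; the pixel multiset is always preserved.
#'
#' @param image `H x W x 3` numeric array.
#' @param rot optional fixed rotation (0, 90, 180, 270); drawn randomly if `NULL`.
#' @param flip optional fixed flip flag; drawn randomly if `NULL`.
#' @return transformed array.
#' @export
apply_flip_rotate <- function(image, rot = NULL, flip = NULL) {
  check_that(is_rgb_array(image), "image must be H x W x 3")
  if (is.null(rot)) rot <- sample(c(0L, 90L, 180L, 270L), 1L)
  if (is.null(flip)) flip <- sample(c(FALSE, TRUE), 1L)
  out <- image
  if (flip) out <- out[, rev(seq_len(dim(out)[2])), , drop = FALSE]
  k <- (rot %/% 90L) %% 4L
  for (i in seq_len(k)) {
    # 90 degrees counter-clockwise: transpose then reverse rows
    out <- aperm(out, c(2, 1, 3))
    out <- out[rev(seq_len(dim(out)[1])), , , drop = FALSE]
  }
  out
}

#' Plan a per-class augmentation budget
#'
#' Emits, for each class, exactly the requested number of augmentation jobs,
#' sampling source images uniformly with replacement. The job list is fully
#' determined by `seed`.
#'
#' @param manifest a `dataset_manifest` or [generate_dataset()] manifest.
#' @param per_class_targets named integer vector: class name -> number of
#'   augmented images to produce (0 allowed).
#' @param seed integer seed.
#' @return data.frame with columns `class_name`, `source_path`, `job_id`.
#' @export
plan_augmentation <- function(manifest, per_class_targets, seed = 1L) {
  check_that(all(per_class_targets >= 0), "targets must be >= 0")
  paths_by_class <- manifest_paths(manifest)
  missing <- setdiff(names(per_class_targets), names(paths_by_class))
  check_that(length(missing) == 0,
             "classes absent from manifest: ", paste(missing, collapse = ", "))
  with_seed(seed, {
    jobs <- lapply(names(per_class_targets), function(cls) {
      n <- per_class_targets[[cls]]
      if (n == 0) return(NULL)
      data.frame(class_name = cls,
                 source_path = sample(paths_by_class[[cls]], n, replace = TRUE),
                 job_id = seq_len(n),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, jobs)
  })
}

manifest_paths <- function(manifest) {
  if (inherits(manifest, "dataset_manifest")) {
    split(manifest$items$path,
          manifest$class_names[manifest$items$class_index + 1L])
  } else {
    manifest
  }
}

#' Augment a dataset on disk
#'
#' Executes a [plan_augmentation()] job list: each job reads its source
#' image and applies crop, then shadow, then flip/rotate (in that fixed,
#' documented order), writing the result as PNG under
#' `out_dir/<class>/aug_<id>.png`. Class-proportion crop thresholds are
#' computed from the manifest; classes at or below the median proportion use
#' the plus branch (larger windows), the rest the minus branch.
#'
#' @param manifest source `dataset_manifest`.
#' @param out_dir output directory.
#' @param per_class_targets named vector of per-class augmentation counts.
#' @param shadow a [shadow_config()].
#' @param crop_size,out_size crop parameters (see [crop_config()]).
#' @param seed integer seed.
#' @return invisibly, vector of written paths.
#' @export
augment_dataset <- function(manifest, out_dir, per_class_targets,
                            shadow = shadow_config(),
                            crop_size = 128L, out_size = 224L, seed = 1L) {
  jobs <- plan_augmentation(manifest, per_class_targets, seed)
  props <- class_proportions(manifest)
  med <- stats::median(props)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  with_seed(seed + 1L, {
    for (cls in unique(jobs$class_name)) {
      dir.create(file.path(out_dir, cls), showWarnings = FALSE)
      sub <- jobs[jobs$class_name == cls, ]
      mode <- if (props[[cls]] <= med) "plus" else "minus"
      for (i in seq_len(nrow(sub))) {
        img <- load_image(sub$source_path[i], target_size = NA_integer_)
        ccfg <- crop_config(crop_size = min(crop_size, min(dim(img)[1:2])),
                            class_proportion_A = props[[cls]],
                            mode = mode, out_size = out_size)
        img <- apply_random_crop(img, ccfg)
        img <- apply_random_shadow(img, shadow)
        img <- apply_flip_rotate(img)
        path <- file.path(out_dir, cls, sprintf("aug_%05d.png", sub$job_id[i]))
        png::writePNG(pmin(pmax(img / 255, 0), 1), path)
        written <- c(written, path)
      }
    }
  })
  invisible(written)
}
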