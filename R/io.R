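#' Scan a one-folder-per-class image directory into a manifest
#'
#' Classes are the immediate subdirectories of `root`, sorted
#' lexicographically (C locale) so the class-to-index mapping is stable
#' across operating systems. Non-image files are skipped and counted.
#'
#' @param root dataset root directory.
#' @return a `dataset_manifest`: list with `class_names` (ordered character
#'   vector), `items` (data.frame with `path`, `class_index` 0-based),
#'   `root`, and `n_skipped`.
#' @export
scan_dataset <- function(root) {
  check_that(dir.exists(root), "dataset root does not exist: ", root)
  dirs <- list.dirs(root, recursive = FALSE, full.names = FALSE)
  dirs <- sort(dirs, method = "radix")
  check_that(length(dirs) > 0, "no class subdirectories under ", root)
  items <- list()
  n_skipped <- 0L
  for (i in seq_along(dirs)) {
    files <- sort(list.files(file.path(root, dirs[i]), full.names = TRUE),
                  method = "radix")
    is_img <- grepl("\\.(png|jpg|jpeg)$", files, ignore.case = TRUE)
    n_skipped <- n_skipped + sum(!is_img)
    if (any(is_img)) {
      items[[i]] <- data.frame(path = files[is_img],
                               class_index = i - 1L,
                               stringsAsFactors = FALSE)
    }
  }
  items <- do.call(rbind, items)
  check_that(!is.null(items) && nrow(items) > 0, "no images found under ", root)
  if (n_skipped > 0) {
    message(sprintf("scan_dataset: skipped %d non-image file(s)", n_skipped))
  }
  structure(list(class_names = dirs, items = items, root = root,
                 n_skipped = n_skipped),
            class = "dataset_manifest")
}

#' Load an image as an RGB array at a target resolution
#'
#' Decodes a PNG (or JPEG via EBImage) to an `H x W x 3` numeric array with
#' values in `[0, 255]`, resized to `target_size` x `target_size` with
#' bilinear resampling. Grayscale inputs are replicated across the three
#' channels; an already-target-size image passes through pixel-identically.
#'
#' @param path image file path.
#' @param target_size side of the square output in pixels; `NA` keeps the
#'   native resolution.
#' @return numeric array `target_size x target_size x 3`, values in `[0, 255]`.
#' @export
load_image <- function(path, target_size = 224L) {
  check_that(file.exists(path), "no such image file: ", path)
  img <- tryCatch({
    if (grepl("\\.png$", path, ignore.case = TRUE)) {
      png::readPNG(path)
    } else {
      EBImage::imageData(EBImage::readImage(path))
    }
  }, error = function(e) {
    stop(errorCondition(paste0("cannot decode image ", path, ": ",
                               conditionMessage(e)),
                        class = c("hybridmae_io_error", "error")))
  })
  if (length(dim(img)) == 2L) {
    img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  } else if (dim(img)[3] == 4L) {
    img <- img[, , 1:3, drop = FALSE]  # drop alpha
  } else if (dim(img)[3] > 3L) {
    img <- img[, , 1:3, drop = FALSE]
  }
  img <- img * 255
  if (!is.na(target_size)) img <- resize_image(img, target_size)
  img
}

#' Bilinear resize of an RGB array
#'
#' Thin wrapper over `EBImage::resize` (bilinear filter); pass-through when
#' the image already has the target size.
#'
#' @param img `H x W x 3` numeric array, any value scale.
#' @param target_size output side in pixels.
#' @return `target_size x target_size x 3` numeric array on the input scale.
#' @export
resize_image <- function(img, target_size) {
  check_that(is_rgb_array(img), "expected an H x W x 3 array")
  if (dim(img)[1] == target_size && dim(img)[2] == target_size) return(img)
  out <- EBImage::resize(EBImage::Image(img / 255, colormode = "Color"),
                         w = target_size, h = target_size, filter = "bilinear")
  EBImage::imageData(out) * 255
}

#' Read a run configuration file
#'
#' YAML mapping covering model, training, loss and augmentation settings.
#' Unknown keys are rejected so typos fail loudly instead of silently using
#' defaults.
#'
#' @param path YAML file.
#' @return named list of settings.
#' @export
read_run_config <- function(path) {
  check_that(file.exists(path), "no such config file: ", path)
  cfg <- yaml::read_yaml(path)
  allowed <- c("model", "train", "loss", "augment", "data", "seed")
  unknown <- setdiff(names(cfg), allowed)
  check_that(length(unknown) == 0,
             "unknown config keys: ", paste(unknown, collapse = ", "),
             " (allowed: ", paste(allowed, collapse = ", "), ")")
  model_keys <- c("image_size", "patch_size", "embed_dim", "encoder_depth",
                  "n_heads", "decoder_dim", "decoder_depth", "n_classes",
                  "mask_ratio", "use_depthwise_conv", "use_conv_stem",
                  "use_cls_branch", "dw_kernel", "pool")
  if (!is.null(cfg$model)) {
    unknown <- setdiff(names(cfg$model), model_keys)
    check_that(length(unknown) == 0,
               "unknown model config keys: ", paste(unknown, collapse = ", "))
  }
  cfg
}

#' Serialize a manifest to JSON and back
#'
#' @param manifest a `dataset_manifest`.
#' @param path output JSON file.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(list(class_names = manifest$class_names,
                            items = manifest$items,
                            root = manifest$root,
                            n_skipped = manifest$n_skipped),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(class_names = x$class_names,
                 items = as.data.frame(x$items),
                 root = x$root,
                 n_skipped = as.integer(x$n_skipped)),
            class = "dataset_manifest")
}
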