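#' Training configuration
#'
#' Defaults follow the published training recipe: AdamW at learning rate
#' 1e-3, batch size 32, StepLR decay (gamma 0.1) for pre-training over 400
#' epochs, cosine annealing for fine-tuning over 200 epochs, 70/15/15
#' train/test/validation split. Tests and examples override the epoch counts
#' with tiny values.
#'
#' @param phase `"pretrain"` or `"finetune"`.
#' @param lr initial learning rate.
#' @param optimizer currently `"adamw"`.
#' @param schedule `"steplr"` or `"cosine"`.
#' @param batch_size images per optimizer step.
#' @param epochs run length (defaults 400 pretrain / 200 finetune).
#' @param seed integer seed; fixes every random draw in the loop.
#' @param grad_clip global-norm clipping threshold (`Inf` disables).
#' @param weight_decay AdamW decoupled weight decay.
#' @param augment apply random crop/shadow/flip-rotate to training images.
#' @param freeze_encoder fine-tuning only: update just the head parameters.
#' @return a `train_config` list.
#' @export
train_config <- function(phase = c("pretrain", "finetune"), lr = 1e-3,
                         optimizer = "adamw",
                         schedule = NULL, batch_size = 32L, epochs = NULL,
                         seed = 1L, grad_clip = 1.0, weight_decay = 0.05,
                         augment = TRUE, freeze_encoder = FALSE) {
  phase <- match.arg(phase)
  if (is.null(schedule)) schedule <- if (phase == "pretrain") "steplr" else "cosine"
  check_that(schedule %in% c("steplr", "cosine"), "unknown schedule: ", schedule)
  check_that(optimizer == "adamw", "unknown optimizer: ", optimizer)
  if (is.null(epochs)) epochs <- if (phase == "pretrain") 400L else 200L
  structure(list(phase = phase, lr = lr, optimizer = optimizer,
                 schedule = schedule, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 grad_clip = grad_clip, weight_decay = weight_decay,
                 augment = isTRUE(augment),
                 freeze_encoder = isTRUE(freeze_encoder)),
            class = "train_config")
}

#' Stratified train/test/validation split
#'
#' Splits a manifest class by class so every class is represented in every
#' nonempty split whenever it has at least as many images as nonzero
#' fractions. Deterministic for a fixed seed; the three parts are disjoint
#' and jointly exhaustive.
#'
#' @param manifest a `dataset_manifest`.
#' @param fractions length-3 numeric `(train, test, val)` summing to 1.
#' @param seed integer seed.
#' @return named list of three `dataset_manifest`s: `train`, `test`, `val`.
#' @export
split_dataset <- function(manifest, fractions = c(0.70, 0.15, 0.15), seed = 1L) {
  check_that(abs(sum(fractions) - 1) < 1e-9, "fractions must sum to 1")
  items <- manifest$items
  assign_split <- function(n) {
    base <- floor(fractions * n)
    rem <- n - sum(base)
    if (rem > 0) {
      extra <- order(fractions * n - base, decreasing = TRUE)[seq_len(rem)]
      base[extra] <- base[extra] + 1L
    }
    # guarantee representation: move from the largest part into empty ones
    if (n >= sum(fractions > 0)) {
      for (k in which(fractions > 0 & base == 0)) {
        donor <- which.max(base)
        base[donor] <- base[donor] - 1L
        base[k] <- base[k] + 1L
      }
    } else {
      warning("class with only ", n, " image(s): best-effort split assignment")
    }
    base
  }
  out <- list(train = NULL, test = NULL, val = NULL)
  with_seed(seed, {
    for (ci in sort(unique(items$class_index))) {
      sub <- items[items$class_index == ci, , drop = FALSE]
      sub <- sub[sample.int(nrow(sub)), , drop = FALSE]
      n3 <- assign_split(nrow(sub))
      cuts <- cumsum(c(0, n3))
      for (k in 1:3) {
        if (n3[k] > 0) {
          part <- sub[(cuts[k] + 1L):cuts[k + 1L], , drop = FALSE]
          out[[k]] <- rbind(out[[k]], part)
        }
      }
    }
  })
  lapply(out, function(it) {
    structure(list(class_names = manifest$class_names,
                   items = if (is.null(it)) items[0, ] else it,
                   root = manifest$root, n_skipped = 0L),
              class = "dataset_manifest")
  })
}

# Load every image of a manifest at model resolution; returns list with
# `images` (arrays in [0,255]) and `labels` (0-based integer vector).
load_split <- function(manifest, image_size) {
  n <- nrow(manifest$items)
  images <- vector("list", n)
  for (i in seq_len(n)) {
    images[[i]] <- load_image(manifest$items$path[i], image_size)
  }
  list(images = images, labels = as.integer(manifest$items$class_index),
       class_names = manifest$class_names)
}

# Per-sample training augmentation: crop -> shadow -> flip/rotate, on the
# [0,255] scale, returning an image at model resolution.
augment_one <- function(img, A, mode, image_size, shadow_cfg, crop_size) {
  side <- min(dim(img)[1:2])
  ccfg <- crop_config(crop_size = min(crop_size, side), class_proportion_A = A,
                      mode = mode, out_size = image_size)
  img <- apply_random_crop(img, ccfg)
  scfg <- shadow_config(shadow_size = min(shadow_cfg$shadow_size, image_size),
                        shadow_intensity = shadow_cfg$shadow_intensity,
                        dark_rate = shadow_cfg$dark_rate)
  img <- apply_random_shadow(img, scfg)
  apply_flip_rotate(img)
}

epoch_log_record <- function(epoch, mse, cls, total, lr, val_acc = NA_real_) {
  list(epoch = epoch, loss_mse = mse, loss_cls = cls, loss_total = total,
       lr = lr, val_acc = val_acc)
}

append_jsonl <- function(record, path) {
  if (is.null(path)) return(invisible(NULL))
  cat(jsonlite::toJSON(record, auto_unbox = TRUE, digits = NA, na = "null"),
      "\n", sep = "", file = path, append = TRUE)
}

#' Masked pre-training loop
#'
#' Optimizes the combined reconstruction + classification objective with
#' random masking active. Every epoch logs the mean loss terms and the
#' learning rate; a checkpoint is written at the end (and every
#' `checkpoint_every` epochs when `out_dir` is given). Fully deterministic
#' on CPU for a fixed `train_cfg$seed`.
#'
#' @param model a `hybridmae_model` (from [init_model()] or a checkpoint).
#' @param train_manifest training-split `dataset_manifest`.
#' @param train_cfg a [train_config()] with phase `"pretrain"`.
#' @param loss_cfg a [loss_config()].
#' @param out_dir optional checkpoint/log directory.
#' @param checkpoint_every write an intermediate checkpoint every so many
#'   epochs.
#' @param resume_from path to an intermediate checkpoint; training continues
#'   from its epoch with its optimizer moments and random stream restored,
#'   reproducing the uninterrupted run exactly.
#' @return list with `model`, `log` (data.frame, one row per epoch), and
#'   `checkpoint` (path or NULL).
#' @export
pretrain <- function(model, train_manifest, train_cfg, loss_cfg,
                     out_dir = NULL, checkpoint_every = Inf,
                     resume_from = NULL) {
  stopifnot(train_cfg$phase == "pretrain")
  run_training(model, train_manifest, train_cfg, loss_cfg,
               val_manifest = NULL, out_dir = out_dir,
               checkpoint_every = checkpoint_every, masked = TRUE,
               resume_from = resume_from)
}

#' Supervised fine-tuning loop
#'
#' Masking is forced off (every patch visible), the decoder is dropped, and
#' only the classification loss is optimized under a cosine schedule.
#' Validation accuracy is computed each epoch; the returned model carries
#' the best-validation parameters.
#'
#' @param model a `hybridmae_model`, typically from a pre-training
#'   checkpoint.
#' @param train_manifest,val_manifest manifests for the train and validation
#'   splits.
#' @param train_cfg a [train_config()] with phase `"finetune"`.
#' @param loss_cfg a [loss_config()]; `w_mse` is ignored (no decoder).
#' @param out_dir optional checkpoint/log directory.
#' @return list with `model` (best validation), `log`, `checkpoint`.
#' @export
finetune <- function(model, train_manifest, val_manifest, train_cfg,
                     loss_cfg = NULL, out_dir = NULL) {
  stopifnot(train_cfg$phase == "finetune")
  check_that(model$cfg$use_cls_branch,
             "fine-tuning requires the classification branch")
  if (is.null(loss_cfg)) {
    loss_cfg <- loss_config(n_classes = model$cfg$n_classes)
  }
  loss_cfg$w_mse <- 0
  run_training(model, train_manifest, train_cfg, loss_cfg,
               val_manifest = val_manifest, out_dir = out_dir,
               checkpoint_every = Inf, masked = FALSE)
}

run_training <- function(model, train_manifest, train_cfg, loss_cfg,
                         val_manifest, out_dir, checkpoint_every, masked,
                         resume_from = NULL) {
  cfg <- model$cfg
  check_that(loss_cfg$n_classes == cfg$n_classes,
             "loss_config n_classes != model n_classes")
  data <- load_split(train_manifest, cfg$image_size)
  n <- length(data$images)
  check_that(n > 0, "empty training manifest")
  val_data <- if (!is.null(val_manifest)) load_split(val_manifest, cfg$image_size)
  props <- class_proportions(train_manifest)
  med <- stats::median(props)
  shadow_cfg <- shadow_config()
  log_path <- if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    file.path(out_dir, paste0(train_cfg$phase, "_log.jsonl"))
  }
  if (!is.null(log_path) && file.exists(log_path)) file.remove(log_path)

  trainable <- trainable_predicate(train_cfg, masked)
  opt <- adamw_init(model$params, lr = train_cfg$lr,
                    weight_decay = train_cfg$weight_decay)
  params <- model$params
  first_epoch <- 1L
  resume_rng <- NULL
  if (!is.null(resume_from)) {
    ck <- readRDS(resume_from)
    check_that(!is.null(ck$state), "checkpoint has no resume state: ", resume_from)
    params <- ck$params
    opt <- ck$state$opt
    resume_rng <- ck$state$rng
    first_epoch <- ck$header$epoch + 1L
    check_that(first_epoch <= train_cfg$epochs,
               "checkpoint already covers all ", train_cfg$epochs, " epochs")
  }
  log <- vector("list", train_cfg$epochs)
  best_val <- -Inf
  best_params <- params

  with_seed(train_cfg$seed, {
    if (!is.null(resume_rng)) {
      assign(".Random.seed", resume_rng, envir = globalenv())
    }
    for (epoch in first_epoch:train_cfg$epochs) {
      lr_e <- if (train_cfg$schedule == "steplr") {
        schedule_steplr(train_cfg$lr, epoch, train_cfg$epochs)
      } else {
        schedule_cosine(train_cfg$lr, epoch, train_cfg$epochs)
      }
      ord <- sample.int(n)
      sum_mse <- 0; sum_cls <- 0; n_seen <- 0
      for (start in seq(1L, n, by = train_cfg$batch_size)) {
        idx <- ord[start:min(n, start + train_cfg$batch_size - 1L)]
        acc <- tree_zero_like(params)
        b_mse <- 0; b_cls <- 0
        for (i in idx) {
          img <- data$images[[i]]
          lab <- data$labels[i]
          if (train_cfg$augment) {
            cls_name <- data$class_names[lab + 1L]
            A <- props[[cls_name]]
            mode <- if (A <= med) "plus" else "minus"
            img <- augment_one(img, A, mode, cfg$image_size, shadow_cfg,
                               crop_size = cfg$image_size)
          }
          part <- if (masked && cfg$mask_ratio > 0) {
            random_mask(cfg$N, cfg$mask_ratio)
          }
          m <- list(cfg = cfg, params = params)
          fw <- model_forward(m, img / 255, partition = part,
                              with_decoder = masked, keep_cache = TRUE)
          bw <- model_backward(m, fw, label = lab, loss_cfg = loss_cfg)
          if (!is.finite(bw$loss_total)) {
            stop("non-finite loss at epoch ", epoch, " (image ", i,
                 "); last terms: mse=", bw$loss_mse, " cls=", bw$loss_cls)
          }
          acc <- tree_add_partial(acc, bw$grads)
          b_mse <- b_mse + bw$loss_mse
          b_cls <- b_cls + bw$loss_cls
        }
        acc <- tree_scale(acc, 1 / length(idx))
        if (is.finite(train_cfg$grad_clip)) {
          acc <- clip_global_norm(acc, train_cfg$grad_clip)$grads
        }
        st <- adamw_step(params, acc, opt, lr = lr_e, trainable = trainable)
        params <- st$params
        opt <- st$state
        sum_mse <- sum_mse + b_mse; sum_cls <- sum_cls + b_cls
        n_seen <- n_seen + length(idx)
      }
      mean_mse <- sum_mse / n_seen
      mean_cls <- sum_cls / n_seen
      total <- loss_cfg$w_mse * mean_mse + loss_cfg$w_cls * mean_cls
      val_acc <- NA_real_
      if (!is.null(val_data)) {
        m <- list(cfg = cfg, params = params)
        preds <- max.col(model_predict(m, lapply(val_data$images, function(x) x / 255))) - 1L
        val_acc <- mean(preds == val_data$labels)
        if (val_acc >= best_val) {
          best_val <- val_acc
          best_params <- params
        }
      }
      rec <- epoch_log_record(epoch, mean_mse, mean_cls, total, lr_e, val_acc)
      append_jsonl(rec, log_path)
      log[[epoch]] <- rec
      if (!is.null(out_dir) && is.finite(checkpoint_every) &&
          epoch %% checkpoint_every == 0) {
        save_checkpoint(list(cfg = cfg, params = params),
                        file.path(out_dir, sprintf("ckpt_epoch%04d.rds", epoch)),
                        extra = list(phase = train_cfg$phase, epoch = epoch),
                        state = list(opt = opt,
                                     rng = get(".Random.seed",
                                               envir = globalenv())))
      }
    }
  })

  final_params <- if (!is.null(val_data)) best_params else params
  model$params <- final_params
  ckpt <- NULL
  if (!is.null(out_dir)) {
    ckpt <- file.path(out_dir, paste0(train_cfg$phase, "_final.rds"))
    save_checkpoint(model, ckpt,
                    extra = list(phase = train_cfg$phase,
                                 epoch = train_cfg$epochs,
                                 class_names = train_manifest$class_names))
  }
  log_df <- do.call(rbind, lapply(log, function(r) as.data.frame(r)))
  list(model = model, log = log_df, checkpoint = ckpt)
}

trainable_predicate <- function(train_cfg, masked) {
  if (train_cfg$phase == "finetune" && train_cfg$freeze_encoder) {
    function(path) grepl("^(head_ln_|W_head|b_head)", path)
  } else if (!masked) {
    # fine-tuning drops the decoder entirely
    function(path) !grepl("^(dec|W_dec_|b_dec_|mask_token)", path)
  } else {
    function(path) TRUE
  }
}

#' Save / load a model checkpoint
#'
#' The checkpoint is an RDS file holding the named parameter map, plus a
#' JSON sidecar (`<path>.json`) with the model configuration and any extra
#' metadata (phase, epoch, class names). [load_checkpoint()] validates that
#' the stored configuration is structurally complete.
#'
#' @param model a `hybridmae_model`.
#' @param path output `.rds` path.
#' @param extra named list of metadata for the JSON header.
#' @param state optional resume state (optimizer moments, RNG); stored in
#'   the RDS only, never in the JSON header.
#' @export
save_checkpoint <- function(model, path, extra = list(), state = NULL) {
  header <- c(list(config = unclass(model$cfg)), extra)
  saveRDS(list(header = header, params = model$params, state = state), path)
  jsonlite::write_json(header, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param path checkpoint `.rds` path.
#' @return a `hybridmae_model` with attribute `header`.
#' @export
load_checkpoint <- function(path) {
  check_that(file.exists(path), "no such checkpoint: ", path)
  x <- readRDS(path)
  need <- c("image_size", "patch_size", "embed_dim", "n_classes")
  check_that(all(need %in% names(x$header$config)),
             "checkpoint header is missing config fields")
  cfg <- do.call(model_config, x$header$config[setdiff(names(x$header$config),
                                                       c("grid_h", "grid_w", "N"))])
  model <- structure(list(cfg = cfg, params = x$params),
                     class = "hybridmae_model")
  attr(model, "header") <- x$header
  model
}
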