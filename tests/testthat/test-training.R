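tiny_pretrain_cfg <- function(epochs = 2L, seed = 1L, augment = FALSE) {
  train_config("pretrain", epochs = epochs, seed = seed, augment = augment,
               batch_size = 16L)
}

test_that("stratified split is a disjoint, exhaustive, seeded partition", {
  man <- scan_dataset(fixture_dir_small())
  splits <- split_dataset(man, c(0.7, 0.15, 0.15), seed = 3)
  all_paths <- sort(man$items$path)
  got <- sort(c(splits$train$items$path, splits$test$items$path,
                splits$val$items$path))
  expect_identical(got, all_paths)
  expect_length(intersect(splits$train$items$path, splits$test$items$path), 0)
  expect_length(intersect(splits$train$items$path, splits$val$items$path), 0)
  expect_length(intersect(splits$test$items$path, splits$val$items$path), 0)
  # per-class stratification: every class appears in every split
  for (s in splits) {
    expect_setequal(unique(s$items$class_index), 0:5)
  }
  # 70/15/15 on a round count
  man100 <- man
  man100$items <- man$items[man$items$class_index == 0, ][1:40, ]
  s100 <- split_dataset(man100, c(0.7, 0.15, 0.15), seed = 1)
  expect_equal(nrow(s100$train$items), 28)
  expect_equal(nrow(s100$test$items), 6)
  expect_equal(nrow(s100$val$items), 6)
  # determinism
  splits2 <- split_dataset(man, c(0.7, 0.15, 0.15), seed = 3)
  expect_identical(splits$train$items, splits2$train$items)
  expect_error(split_dataset(man, c(0.5, 0.3, 0.1)),
               class = "hybridmae_validation_error")
})

test_that("pre-training decreases the combined loss and logs both terms", {
  man <- scan_dataset(fixture_dir_small())
  splits <- split_dataset(man, seed = 1)
  small_train <- splits$train
  small_train$items <- small_train$items[
    unlist(lapply(split(seq_len(nrow(small_train$items)),
                        small_train$items$class_index), head, 8)), ]
  model <- init_model(tiny_model_config(n_classes = 6), seed = 1)
  lc <- loss_config(n_classes = 6)
  out <- pretrain(model, small_train, tiny_pretrain_cfg(epochs = 2L), lc)
  expect_equal(nrow(out$log), 2)
  expect_lt(out$log$loss_total[2], out$log$loss_total[1])
  expect_true(all(out$log$loss_mse > 0))
  expect_true(all(out$log$loss_cls > 0))
  # classification weight 0: log contains only reconstruction loss
  lc0 <- loss_config(n_classes = 6, w_cls = 0)
  out0 <- pretrain(model, small_train, tiny_pretrain_cfg(epochs = 1L), lc0)
  expect_equal(out0$log$loss_cls, 0)
  expect_gt(out0$log$loss_mse, 0)
})

test_that("training is bitwise deterministic for a fixed seed", {
  man <- scan_dataset(fixture_dir_small())
  splits <- split_dataset(man, seed = 1)
  small_train <- splits$train
  small_train$items <- small_train$items[
    unlist(lapply(split(seq_len(nrow(small_train$items)),
                        small_train$items$class_index), head, 5)), ]
  model <- init_model(tiny_model_config(n_classes = 6), seed = 4)
  lc <- loss_config(n_classes = 6)
  a <- pretrain(model, small_train, tiny_pretrain_cfg(epochs = 1L, seed = 9,
                                                      augment = TRUE), lc)
  b <- pretrain(model, small_train, tiny_pretrain_cfg(epochs = 1L, seed = 9,
                                                      augment = TRUE), lc)
  expect_identical(a$log, b$log)
  expect_identical(a$model$params, b$model$params)
})

test_that("resuming from a checkpoint reproduces the uninterrupted run", {
  man <- scan_dataset(fixture_dir_small())
  splits <- split_dataset(man, seed = 1)
  small_train <- splits$train
  small_train$items <- small_train$items[
    unlist(lapply(split(seq_len(nrow(small_train$items)),
                        small_train$items$class_index), head, 4)), ]
  model <- init_model(tiny_model_config(n_classes = 6), seed = 2)
  lc <- loss_config(n_classes = 6)
  dir_a <- file.path(tempdir(), "resume_a")
  unlink(dir_a, recursive = TRUE)
  full <- pretrain(model, small_train, tiny_pretrain_cfg(epochs = 2L, seed = 5),
                   lc)
  part1 <- pretrain(model, small_train,
                    tiny_pretrain_cfg(epochs = 2L, seed = 5), lc,
                    out_dir = dir_a, checkpoint_every = 1L)
  ck <- file.path(dir_a, "ckpt_epoch0001.rds")
  expect_true(file.exists(ck))
  resumed <- pretrain(model, small_train,
                      tiny_pretrain_cfg(epochs = 2L, seed = 5), lc,
                      resume_from = ck)
  expect_equal(resumed$model$params, full$model$params)
  expect_equal(resumed$log$loss_total, full$log$loss_total[2])
})

test_that("learning-rate schedules decay as configured", {
  expect_equal(schedule_steplr(1e-3, 1, 100), 1e-3)
  expect_equal(schedule_steplr(1e-3, 51, 100), 1e-4)  # gamma 0.1 at 50%
  expect_equal(schedule_steplr(1e-3, 80, 100), 1e-5)  # again at 75%
  expect_lt(schedule_cosine(1e-3, 200, 200), 1e-3)
  expect_equal(schedule_cosine(1e-3, 1, 200), 1e-3)
  expect_gt(schedule_cosine(1e-3, 100, 200), schedule_cosine(1e-3, 199, 200))
})

test_that("every ablation switch combination trains without error", {
  man <- scan_dataset(fixture_dir_small())
  splits <- split_dataset(man, seed = 1)
  tr <- splits$train
  tr$items <- tr$items[unlist(lapply(split(seq_len(nrow(tr$items)),
                                           tr$items$class_index), head, 2)), ]
  lc <- loss_config(n_classes = 6)
  for (dw in c(FALSE, TRUE)) {
    for (stem in c(FALSE, TRUE)) {
      for (cls in c(FALSE, TRUE)) {
        model <- init_model(tiny_model_config(n_classes = 6,
                                              use_depthwise_conv = dw,
                                              use_conv_stem = stem,
                                              use_cls_branch = cls), seed = 1)
        lcc <- lc
        if (!cls) lcc$w_cls <- 0
        out <- pretrain(model, tr, tiny_pretrain_cfg(epochs = 1L), lcc)
        expect_true(is.finite(out$log$loss_total),
                    label = sprintf("dw=%d stem=%d cls=%d", dw, stem, cls))
      }
    }
  }
})

test_that("frozen-encoder fine-tuning changes only head parameters", {
  man <- scan_dataset(fixture_dir_small())
  splits <- split_dataset(man, seed = 1)
  tr <- splits$train
  tr$items <- tr$items[unlist(lapply(split(seq_len(nrow(tr$items)),
                                           tr$items$class_index), head, 3)), ]
  model <- init_model(tiny_model_config(n_classes = 6), seed = 3)
  ft <- finetune(model, tr, splits$val,
                 train_config("finetune", epochs = 1L, seed = 1,
                              augment = FALSE, batch_size = 16L,
                              freeze_encoder = TRUE))
  p0 <- model$params; p1 <- ft$model$params
  expect_identical(p0$W_embed, p1$W_embed)
  expect_identical(p0$enc, p1$enc)
  expect_identical(p0$E_pos, p1$E_pos)
  expect_false(identical(p0$W_head, p1$W_head))
  expect_false(identical(p0$head_ln_g, p1$head_ln_g))
})

test_that("non-finite loss aborts with a diagnostic", {
  man <- scan_dataset(fixture_dir_small())
  splits <- split_dataset(man, seed = 1)
  tr <- splits$train
  tr$items <- tr$items[1:4, ]
  model <- init_model(tiny_model_config(n_classes = 6), seed = 1)
  model$params$W_head <- model$params$W_head * Inf
  lc <- loss_config(n_classes = 6)
  expect_error(pretrain(model, tr, tiny_pretrain_cfg(epochs = 1L), lc),
               "non-finite")
})
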