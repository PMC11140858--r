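#' Confusion matrix
#'
#' Rows are true labels, columns predicted labels (0-based class indices);
#' entry `[t, p]` counts samples with true class `t` predicted as `p`. The
#' total equals the number of evaluated samples.
#'
#' @param true_labels,predicted_labels equal-length integer vectors with
#'   values in `[0, n_classes)`.
#' @param n_classes number of classes.
#' @return `n_classes x n_classes` integer matrix.
#' @export
confusion <- function(true_labels, predicted_labels, n_classes) {
  check_that(length(true_labels) == length(predicted_labels),
             "label vectors differ in length")
  check_that(all(true_labels >= 0 & true_labels < n_classes) &&
             all(predicted_labels >= 0 & predicted_labels < n_classes),
             "labels out of range [0, ", n_classes, ")")
  lv <- seq_len(n_classes) - 1L
  cm <- table(factor(true_labels, levels = lv),
              factor(predicted_labels, levels = lv))
  m <- matrix(as.integer(cm), n_classes, n_classes,
              dimnames = list(true = lv, predicted = lv))
  m
}

#' Harmonic-mean F1 score
#'
#' `2 * precision * recall / (precision + recall)`; 0 when both inputs are 0.
#'
#' @param precision,recall values in `[0, 1]` (vectorized).
#' @return F1 in `[0, 1]`.
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Per-class classification metrics from a confusion matrix
#'
#' For each class, one-vs-rest counts are derived (TP on the diagonal, FP
#' the rest of the column, FN the rest of the row, TN everything else) and
#' turned into precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, specificity
#' `TN/(FP+TN)` and the harmonic-mean F1
#' `2 * precision * recall / (precision + recall)`. When a denominator is
#' zero the metric is reported as 0 with a warning (documented convention
#' for degenerate classes).
#'
#' @param cm confusion matrix from [confusion()].
#' @return a `metrics_report`: list with `per_class` (data.frame:
#'   `class_index`, `precision`, `recall`, `specificity`, `f1`, `support`),
#'   `macro` (named vector), `accuracy`, `confusion`.
#' @export
per_class_metrics <- function(cm) {
  n <- nrow(cm)
  total <- sum(cm)
  check_that(total > 0, "empty confusion matrix")
  safe_div <- function(num, den, what, k) {
    if (den == 0) {
      warning(sprintf("class %d: %s undefined (zero denominator); reported as 0",
                      k - 1L, what))
      0
    } else num / den
  }
  rows <- lapply(seq_len(n), function(k) {
    tp <- cm[k, k]
    fp <- sum(cm[, k]) - tp
    fn <- sum(cm[k, ]) - tp
    tn <- total - tp - fp - fn
    prec <- safe_div(tp, tp + fp, "precision", k)
    rec <- safe_div(tp, tp + fn, "recall", k)
    spec <- safe_div(tn, fp + tn, "specificity", k)
    f1 <- f1_score(prec, rec)
    data.frame(class_index = k - 1L, precision = prec, recall = rec,
               specificity = spec, f1 = f1, support = tp + fn)
  })
  per_class <- do.call(rbind, rows)
  structure(list(
    per_class = per_class,
    macro = c(precision = mean(per_class$precision),
              recall = mean(per_class$recall),
              specificity = mean(per_class$specificity),
              f1 = mean(per_class$f1)),
    accuracy = sum(diag(cm)) / total,
    confusion = cm), class = "metrics_report")
}

#' One-vs-rest ROC AUC per class
#'
#' For each class the AUC is the normalized Mann-Whitney U statistic of the
#' class score (midranks handle ties), which equals the area under the
#' trapezoidal ROC curve. Classes absent from the truth get `NA` and are
#' excluded from the macro average.
#'
#' @param true_labels 0-based integer labels.
#' @param class_scores matrix, one row per sample, one column per class
#'   (probabilities or logits — AUC is rank-invariant).
#' @return list with `per_class` (numeric vector, NA where undefined) and
#'   `macro` (unweighted mean over defined classes).
#' @export
roc_auc <- function(true_labels, class_scores) {
  n_classes <- ncol(class_scores)
  check_that(length(true_labels) == nrow(class_scores),
             "labels/scores length mismatch")
  aucs <- vapply(seq_len(n_classes), function(k) {
    pos <- true_labels == (k - 1L)
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0 || n0 == 0) return(NA_real_)
    r <- rank(class_scores[, k])  # midranks for ties
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, numeric(1))
  list(per_class = aucs, macro = mean(aucs, na.rm = TRUE))
}

#' Evaluate a model on a manifest split
#'
#' Runs full-visibility prediction, then computes the confusion matrix, the
#' per-class metric suite and one-vs-rest AUCs.
#'
#' @param model a `hybridmae_model` with the classification branch enabled.
#' @param manifest a `dataset_manifest` (typically the test split).
#' @return a `metrics_report` with additional elements `auc` (from
#'   [roc_auc()]), `class_names`, `n`.
#' @export
evaluate_model <- function(model, manifest) {
  data <- load_split(manifest, model$cfg$image_size)
  logits <- model_predict(model, lapply(data$images, function(x) x / 255))
  preds <- max.col(logits) - 1L
  probs <- t(apply(logits, 1, softmax_vec))
  rep_ <- per_class_metrics(confusion(data$labels, preds, model$cfg$n_classes))
  rep_$auc <- roc_auc(data$labels, probs)
  rep_$class_names <- manifest$class_names
  rep_$n <- length(data$labels)
  rep_
}

#' Write a metrics report to disk
#'
#' Emits `metrics.json` (machine-readable, 3-decimal rounding to match the
#' reporting precision used throughout), `confusion.csv` (rows true,
#' columns predicted, class-index order) and `metrics.txt` (human-readable
#' table).
#'
#' @param report a `metrics_report`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  check_that(dir.exists(out_dir), "cannot create ", out_dir)
  json_path <- file.path(out_dir, "metrics.json")
  csv_path <- file.path(out_dir, "confusion.csv")
  txt_path <- file.path(out_dir, "metrics.txt")
  payload <- list(
    accuracy = report$accuracy,
    macro = as.list(report$macro),
    per_class = report$per_class,
    auc_per_class = report$auc$per_class,
    auc_macro = report$auc$macro,
    class_names = report$class_names)
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  utils::write.csv(as.data.frame(report$confusion[, , drop = FALSE]),
                   csv_path, row.names = TRUE)
  tbl <- report$per_class
  tbl[, c("precision", "recall", "specificity", "f1")] <-
    round(tbl[, c("precision", "recall", "specificity", "f1")], 3)
  lines <- c(sprintf("accuracy: %.3f", report$accuracy),
             sprintf("macro F1: %.3f  macro AUC: %.3f",
                     report$macro[["f1"]],
                     if (is.null(report$auc)) NA else report$auc$macro),
             utils::capture.output(print(tbl, row.names = FALSE)))
  writeLines(lines, txt_path)
  invisible(c(json_path, csv_path, txt_path))
}

#' Read back a metrics JSON file
#'
#' @param path `metrics.json` written by [write_report()].
#' @return list mirroring the written payload.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
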