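# Confusion matrices and one-vs-rest accuracy / recall / precision /
# F-measure, reported as macro means with across-class standard deviations.

#' Confusion matrix
#'
#' Entry (i, j) counts windows of true class i predicted as class j.
#'
#' @param truth,pred Equal-length vectors/factors over the class set.
#' @param levels Class levels (default [ACTIVITIES]).
#' @return Integer matrix with classes as dimnames.
#' @export
confusion_matrix <- function(truth, pred, levels = ACTIVITIES) {
  truth <- as.character(truth); pred <- as.character(pred)
  if (length(truth) != length(pred))
    abort_("locomode_bad_argument", "label vectors differ in length")
  bad <- setdiff(unique(c(truth, pred)), levels)
  if (length(bad))
    abort_("locomode_bad_label", "labels outside the class set: %s",
           paste(bad, collapse = ", "))
  tab <- table(factor(truth, levels), factor(pred, levels))
  matrix(as.integer(tab), nrow(tab), dimnames = list(levels, levels))
}

#' Row-normalised confusion matrix (percent)
#' @param confusion Integer confusion matrix.
#' @return Matrix of row percentages (rows with zero support stay zero).
#' @export
confusion_percent <- function(confusion) {
  rs <- rowSums(confusion)
  out <- 100 * sweep(confusion, 1L, pmax(rs, 1L), "/")
  out[rs == 0L, ] <- 0
  out
}

#' Classification metrics from a confusion matrix
#'
#' Derives per-class one-vs-rest counts (TP on the diagonal, FP the rest of
#' the column, FN the rest of the row, TN the remainder) and computes
#' recall `TP/(TP+FN)`, precision `TP/(TP+FP)` and their harmonic mean, the
#' F-measure, per class. Accuracy is the trace over the grand total; the
#' mean of per-class one-vs-rest accuracies is reported alongside. Macro
#' means and across-class standard deviations are reported for
#' recall/precision/F. A class with no true (predicted) instances gets
#' recall (precision) 0, with a message.
#'
#' @param confusion Non-negative integer matrix, rows true, columns
#'   predicted.
#' @return An object of class `"eval_report"`: `confusion`, `accuracy`,
#'   `mean_class_accuracy`, `per_class` data.frame (counts and metrics) and
#'   `macro` (mean and sd per metric).
#' @export
metrics_from_confusion <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (any(confusion < 0) || sum(confusion) == 0)
    abort_("locomode_bad_argument",
           "confusion matrix must be non-negative with positive total")
  n <- sum(confusion)
  k <- nrow(confusion)
  tp <- diag(confusion)
  fp <- colSums(confusion) - tp
  fn <- rowSums(confusion) - tp
  tn <- n - tp - fp - fn
  div0 <- function(num, den, what) {
    out <- ifelse(den > 0, num / den, 0)
    if (any(den == 0))
      message(sprintf("%s undefined for %d class(es); reported as 0",
                      what, sum(den == 0)))
    out
  }
  recall <- div0(tp, tp + fn, "recall")
  precision <- div0(tp, tp + fp, "precision")
  f <- ifelse(precision + recall > 0,
              2 * precision * recall / (precision + recall), 0)
  per_class <- data.frame(
    class = rownames(confusion) %||% as.character(seq_len(k)),
    TP = tp, FP = fp, FN = fn, TN = tn,
    recall = recall, precision = precision, f_measure = f,
    row.names = NULL)
  macro <- list(
    recall = mean(recall), recall_sd = sd(recall),
    precision = mean(precision), precision_sd = sd(precision),
    f_measure = mean(f), f_measure_sd = sd(f))
  structure(list(confusion = confusion,
                 accuracy = sum(tp) / n,
                 mean_class_accuracy = mean((tp + tn) / n),
                 per_class = per_class, macro = macro, n = n),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, digits = 4, ...) {
  cat(sprintf("<eval_report> %d windows, accuracy %.*f\n", x$n, digits,
              x$accuracy))
  cat(sprintf("  macro recall    %.*f (%.*f)\n", digits, x$macro$recall,
              digits, x$macro$recall_sd))
  cat(sprintf("  macro precision %.*f (%.*f)\n", digits, x$macro$precision,
              digits, x$macro$precision_sd))
  cat(sprintf("  macro F-measure %.*f (%.*f)\n", digits, x$macro$f_measure,
              digits, x$macro$f_measure_sd))
  print(x$confusion)
  invisible(x)
}

#' Evaluate a model on labelled windows
#'
#' Runs the forward pass and summarises predictions against the true labels.
#'
#' @param model A `"locomode_net"` or `"locomode_fit"`.
#' @param data A `"window_set"` or named list of window sets (multi-head).
#' @param labels True labels; defaults to the labels carried by the first
#'   window set.
#' @return An `"eval_report"`.
#' @export
evaluate_model <- function(model, data, labels = NULL) {
  if (inherits(model, "locomode_fit")) model <- model$model
  if (is.null(labels)) {
    labels <- if (inherits(data, "window_set")) data$labels
              else data[[1]]$labels
  }
  pred <- predict(model, data, type = "class")
  metrics_from_confusion(confusion_matrix(labels, pred))
}

#' Write an evaluation report
#'
#' Serialises the metrics as JSON and the confusion matrix as CSV next to
#' it.
#'
#' @param report An `"eval_report"`.
#' @param path Output JSON path (`<path>.csv` gets the confusion matrix
#'   with `.json` replaced).
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  cm <- report$confusion
  write_json_(list(accuracy = report$accuracy,
                   mean_class_accuracy = report$mean_class_accuracy,
                   macro = report$macro, per_class = report$per_class,
                   confusion = matrix(as.integer(cm), nrow(cm),
                                      dimnames = dimnames(cm)),
                   n = report$n), path)
  csv <- sub("\\.json$", ".csv", path)
  utils::write.csv(as.data.frame(report$confusion), csv, row.names = TRUE)
  invisible(path)
}
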