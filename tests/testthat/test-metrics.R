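# Independent oracle: per-class one-vs-rest counts by explicit enumeration
# over the label vectors, then the metric definitions applied directly.
brute_metrics <- function(truth, pred, levels = ACTIVITIES) {
  per <- lapply(levels, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    tn <- sum(truth != cl & pred != cl)
    recall <- if (tp + fn > 0) tp / (tp + fn) else 0
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    f <- if (precision + recall > 0)
      2 * precision * recall / (precision + recall) else 0
    c(tp = tp, fp = fp, fn = fn, tn = tn,
      recall = recall, precision = precision, f = f)
  })
  m <- do.call(rbind, per)
  list(accuracy = sum(truth == pred) / length(truth),
       recall = mean(m[, "recall"]), precision = mean(m[, "precision"]),
       f = mean(m[, "f"]), per = m)
}

test_that("confusion matrix counts true/predicted pairs", {
  truth <- c("LW", "LW", "SA", "RD")
  pred <- c("LW", "SA", "SA", "RD")
  cm <- confusion_matrix(truth, pred)
  expect_equal(sum(cm), 4)
  expect_equal(cm["LW", "LW"], 1)
  expect_equal(cm["LW", "SA"], 1)
  expect_equal(cm["RD", "RD"], 1)
  # permutation invariance
  o <- sample(4)
  expect_identical(confusion_matrix(truth[o], pred[o]), cm)
  # degenerate: single predicted class fills one column
  cm2 <- confusion_matrix(truth, rep("LW", 4))
  expect_true(all(cm2[, setdiff(ACTIVITIES, "LW")] == 0))
  expect_error(confusion_matrix(c("LW", "??"), c("LW", "LW")),
               class = "locomode_bad_label")
  expect_error(confusion_matrix("LW", c("LW", "SA")),
               class = "locomode_bad_argument")
})

test_that("metrics match hand-evaluated binary example", {
  cm <- matrix(c(8, 2, 1, 9), 2, 2, byrow = TRUE,
               dimnames = list(c("a", "b"), c("a", "b")))
  rep <- metrics_from_confusion(cm)
  expect_equal(rep$per_class$recall[1], 0.8)
  expect_equal(rep$per_class$precision[1], 8 / 9)
  expect_equal(rep$per_class$f_measure[1],
               2 * 0.8 * (8 / 9) / (0.8 + 8 / 9), tolerance = 1e-12)
  expect_equal(rep$accuracy, 17 / 20)
})

test_that("metrics agree with the brute-force enumerator on random matrices", {
  set.seed(123)
  for (i in 1:200) {
    n <- sample(20:200, 1)
    lab <- random_labels(n)
    cm <- confusion_matrix(lab$truth, lab$pred)
    rep <- suppressMessages(metrics_from_confusion(cm))
    oracle <- brute_metrics(lab$truth, lab$pred)
    expect_equal(rep$accuracy, oracle$accuracy)
    expect_equal(rep$macro$recall, oracle$recall)
    expect_equal(rep$macro$precision, oracle$precision)
    expect_equal(rep$macro$f_measure, oracle$f)
    expect_equal(unname(rep$per_class$TP), unname(oracle$per[, "tp"]))
    expect_equal(unname(rep$per_class$TN), unname(oracle$per[, "tn"]))
    # one-vs-rest counts always partition the total
    expect_true(all(rep$per_class$TP + rep$per_class$FP +
                      rep$per_class$FN + rep$per_class$TN == n))
  }
})

test_that("identity and degenerate confusion matrices behave", {
  ident <- diag(c(10, 20, 30, 40, 50))
  dimnames(ident) <- list(ACTIVITIES, ACTIVITIES)
  rep <- metrics_from_confusion(ident)
  expect_equal(rep$accuracy, 1)
  expect_equal(rep$macro$recall, 1)
  expect_equal(rep$macro$precision, 1)
  expect_equal(rep$macro$f_measure, 1)
  expect_equal(rep$macro$f_measure_sd, 0)
  # a never-predicted class gets precision 0 (with a note), not NaN
  cm <- diag(c(5, 5, 5, 5, 0))
  cm[5, 1] <- 5
  dimnames(cm) <- list(ACTIVITIES, ACTIVITIES)
  expect_message(rep2 <- metrics_from_confusion(cm), "undefined")
  expect_equal(rep2$per_class$precision[5], 0)
  expect_true(all(rep2$per_class$f_measure >= 0 &
                    rep2$per_class$f_measure <= 1))
  expect_error(metrics_from_confusion(matrix(0, 5, 5)),
               class = "locomode_bad_argument")
})

test_that("macro aggregates respect their structural identities", {
  set.seed(77)
  for (i in 1:20) {
    lab <- random_labels(150)
    rep <- metrics_from_confusion(confusion_matrix(lab$truth, lab$pred))
    # macro F bounded by per-class extremes
    expect_gte(rep$macro$f_measure, min(rep$per_class$f_measure))
    expect_lte(rep$macro$f_measure, max(rep$per_class$f_measure))
    # accuracy = support-weighted mean recall
    support <- rowSums(rep$confusion)
    expect_equal(rep$accuracy,
                 sum(rep$per_class$recall * support) / sum(support))
  }
})

test_that("row-normalised percentages sum to 100 per supported row", {
  lab <- random_labels(200)
  cm <- confusion_matrix(lab$truth, lab$pred)
  pc <- confusion_percent(cm)
  expect_equal(unname(rowSums(pc)[rowSums(cm) > 0]),
               rep(100, sum(rowSums(cm) > 0)))
})

test_that("evaluation reports serialise", {
  lab <- random_labels(100)
  rep <- metrics_from_confusion(confusion_matrix(lab$truth, lab$pred))
  path <- withr::local_tempfile(fileext = ".json")
  write_eval_report(rep, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$accuracy, rep$accuracy)
  expect_true(file.exists(sub("\\.json$", ".csv", path)))
})
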