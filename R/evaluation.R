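#' Stratified hold-out split for a binary experiment
#'
#' For each of the two classes, `round(train_fraction * n)` images are drawn
#' at random (seeded) into the training set; the remainder form the test set.
#' The default 30% training fraction leaves 70% of each class untouched for
#' generalization testing.
#'
#' @param manifest an `amypet_manifest` (or any data.frame with `source_id`
#'   and `label` columns).
#' @param classes character pair, e.g. `c("NC", "AD")`.
#' @param train_fraction fraction of each class used for training.
#' @param seed integer split seed.
#' @return A list of class `split_plan` with `train_ids`, `test_ids`,
#'   `train_fraction`, `seed`.
#' @export
make_split <- function(manifest, classes, train_fraction = 0.30, seed = 1L) {
  stopifnot(length(classes) == 2L)
  if (train_fraction <= 0 || train_fraction >= 1)
    stop_amypet("train_fraction must be in (0, 1)",
                class = "amypet_validation_error")
  train_ids <- character(0)
  test_ids <- character(0)
  with_seed(seed, {
    for (cl in classes) {
      ids <- manifest$source_id[manifest$label == cl]
      if (length(ids) < 2L)
        stop_amypet("class %s has %d image(s); need at least 2", cl,
                    length(ids), class = "amypet_validation_error")
      n_train <- floor(train_fraction * length(ids) + 0.5)
      n_train <- max(1L, min(n_train, length(ids) - 1L))
      picked <- sample(ids, n_train)
      train_ids <- c(train_ids, picked)
      test_ids <- c(test_ids, setdiff(ids, picked))
    }
  })
  structure(list(train_ids = train_ids, test_ids = test_ids,
                 train_fraction = train_fraction, seed = as.integer(seed)),
            class = "split_plan")
}

#' Confusion counts for a binary experiment
#'
#' The disease group is the positive class and NC (or more generally the
#' first class of the pair) the negative class.
#'
#' @param tp,tn,fp,fn non-negative integer counts.
#' @return A list of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || any(counts != floor(counts)))
    stop_amypet("counts must be non-negative integers",
                class = "amypet_validation_error")
  structure(as.list(counts), class = "confusion_counts")
}

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' `sensitivity = 100 tp/(tp+fn)`, `specificity = 100 tn/(tn+fp)`,
#' `accuracy = 100 (tp+tn)/(tp+tn+fp+fn)`, each rounded half away from zero
#' to one decimal place.
#'
#' @param counts a [confusion_counts()].
#' @param experiment experiment name carried into the report (e.g. `"NC/AD"`).
#' @return A list of class `evaluation_report` with the counts and the three
#'   metrics (percentages).
#' @export
compute_metrics <- function(counts, experiment = "") {
  stopifnot(inherits(counts, "confusion_counts"))
  with(counts, {
    if (tp + fn == 0 || tn + fp == 0)
      stop_amypet("metrics undefined: need at least one positive and one negative test case",
                  class = "amypet_undefined_metric_error")
    structure(list(
      experiment = experiment,
      counts = counts,
      sensitivity = round_half_up(100 * tp / (tp + fn), 1),
      specificity = round_half_up(100 * tn / (tn + fp), 1),
      accuracy = round_half_up(100 * (tp + tn) / (tp + tn + fp + fn), 1)
    ), class = "evaluation_report")
  })
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s (positive = disease group)\n",
              x$experiment))
  cat(sprintf("  tp=%d tn=%d fp=%d fn=%d\n", x$counts$tp, x$counts$tn,
              x$counts$fp, x$counts$fn))
  cat(sprintf("  sensitivity %.1f%%  specificity %.1f%%  accuracy %.1f%%\n",
              x$sensitivity, x$specificity, x$accuracy))
  invisible(x)
}

#' Run one binary hold-out experiment end to end
#'
#' Splits the feature table (stratified, seeded), trains a fresh network on
#' the training patterns, predicts the held-out patterns, and computes the
#' confusion matrix and metrics. The first class of `classes` is the
#' negative/control group, the second the positive/disease group.
#'
#' @param features feature `data.frame` from [prepare_manifest()] (columns
#'   `source_id`, `label`, `f...`).
#' @param classes character pair `c(negative, positive)`, e.g.
#'   `c("NC", "AD")`.
#' @param cfg a [network_config()]; a fresh network is initialized from
#'   `cfg$seed` for this experiment.
#' @param split_seed seed for the hold-out split.
#' @param train_fraction per-class training fraction (default 0.30).
#' @return A list of class `experiment_result`: the `evaluation_report`
#'   (`report`), the `train_result` (`train`), `train_accuracy` (%), and the
#'   `split_plan` (`split`).
#' @export
run_experiment <- function(features, classes, cfg = network_config(),
                           split_seed = 1L, train_fraction = 0.30) {
  stopifnot(length(classes) == 2L)
  sub <- features[features$label %in% classes, , drop = FALSE]
  if (!all(classes %in% sub$label))
    stop_amypet("both classes must be present in the dataset",
                class = "amypet_validation_error")
  split <- make_split(sub, classes, train_fraction, split_seed)
  tr <- sub[sub$source_id %in% split$train_ids, , drop = FALSE]
  te <- sub[sub$source_id %in% split$test_ids, , drop = FALSE]

  fit <- nn_train(feature_matrix(tr), tr$label, cfg, classes = classes)

  pred_tr <- nn_predict(fit, feature_matrix(tr))
  train_accuracy <- round_half_up(
    100 * mean(classes[pred_tr + 1L] == tr$label), 1)

  pred_te <- classes[nn_predict(fit, feature_matrix(te)) + 1L]
  pos <- classes[2]; neg <- classes[1]
  counts <- confusion_counts(
    tp = sum(pred_te == pos & te$label == pos),
    tn = sum(pred_te == neg & te$label == neg),
    fp = sum(pred_te == pos & te$label == neg),
    fn = sum(pred_te == neg & te$label == pos)
  )
  report <- compute_metrics(counts, paste(classes, collapse = "/"))
  structure(list(report = report, train = fit,
                 train_accuracy = train_accuracy, split = split),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  print(x$report)
  cat(sprintf("  training accuracy %.1f%%  (%s after %d epochs, RMS %.5f)\n",
              x$train_accuracy,
              if (x$train$converged) "converged" else "stopped",
              x$train$epochs_run, x$train$final_rms))
  invisible(x)
}
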