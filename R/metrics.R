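#' Confusion counts for cardiac classification
#'
#' Disease is the positive class. Ternary labels are collapsed to
#' normal-vs-any-disease when `collapse = TRUE` (the default), so
#' `disease1`/`disease2` both count as positive.
#'
#' @param labels true labels.
#' @param predictions predicted labels.
#' @param collapse collapse multi-class disease labels to `"disease"`.
#' @return object of class `confusion_counts` with fields tp, fp, tn, fn.
#' @export
confusion <- function(labels, predictions, collapse = TRUE) {
  if (length(labels) != length(predictions))
    stop_numeric("confusion: length mismatch")
  to_bin <- function(x) {
    x <- as.character(x)
    if (collapse) ifelse(x == "normal", "normal", "disease") else x
  }
  l <- to_bin(labels); p <- to_bin(predictions)
  structure(list(tp = sum(l == "disease" & p == "disease"),
                 fp = sum(l == "normal" & p == "disease"),
                 tn = sum(l == "normal" & p == "normal"),
                 fn = sum(l == "disease" & p == "normal")),
            class = "confusion_counts")
}

#' Performance measures from confusion counts
#'
#' Accuracy `(TP+TN)/total`, recall (sensitivity) `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, precision `TP/(TP+FP)`, and F1 as the harmonic mean of
#' precision and recall. A ratio with zero denominator is returned as 0 and
#' recorded in the `"flagged"` attribute rather than propagating NaN, so
#' downstream fitness values stay bounded.
#'
#' @param counts a [confusion()] result (or a list with tp/fp/tn/fn).
#' @return named list of the five measures, class `metric_set`.
#' @export
classification_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  total <- tp + fp + tn + fn
  if (total == 0) stop_numeric("classification_metrics: no scored records")
  flagged <- character(0)
  ratio <- function(num, den, what) {
    if (den == 0) { flagged <<- c(flagged, what); 0 } else num / den
  }
  precision <- ratio(tp, tp + fp, "precision")
  recall <- ratio(tp, tp + fn, "recall")
  f1 <- if (precision + recall == 0) { flagged <- c(flagged, "f1"); 0 }
        else 2 * precision * recall / (precision + recall)
  out <- list(accuracy = (tp + tn) / total,
              recall = recall,
              specificity = ratio(tn, tn + fp, "specificity"),
              precision = precision,
              f1 = f1)
  attr(out, "flagged") <- unique(flagged)
  class(out) <- "metric_set"
  out
}

#' @export
print.metric_set <- function(x, ...) {
  v <- unlist(x[c("accuracy", "precision", "recall", "specificity", "f1")])
  print(round(v, 4))
  if (length(attr(x, "flagged")))
    cat("flagged zero-denominator:", paste(attr(x, "flagged"), collapse = ", "), "\n")
  invisible(x)
}

# Validation fitness: mean of accuracy, precision, recall and F1. The
# optimizer maximizes it by minimizing its negation.
fitness_from_metrics <- function(m) {
  mean(c(m$accuracy, m$precision, m$recall, m$f1))
}

# Stratified fold assignment: within each class, shuffle and deal round-robin
# so fold class ratios match the cohort within one record.
stratified_folds <- function(labels, k, seed) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < k)
        stop_config("class '", cl, "' has fewer than k members")
      fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

#' Stratified k-fold cross-validation
#'
#' Splits the cohort into `k` label-stratified folds; each fold serves once
#' as the validation set for a model trained on the remainder.
#'
#' @param records labeled cohort data.frame.
#' @param k number of folds (>= 2).
#' @param train_fn `function(train_records, train_streams)` returning a
#'   fitted model.
#' @param predict_fn `function(model, records, streams)` returning labels.
#' @param seed integer seed for the fold assignment.
#' @param streams optional stream matrix passed through by patient id.
#' @return list with `folds` (per-fold `metric_set`), `assignments`, and
#'   `summary` (mean and sd of each measure across folds).
#' @export
kfold <- function(records, k = 5L, train_fn, predict_fn, seed = 1L,
                  streams = NULL) {
  if (k < 2) stop_config("k must be at least 2")
  if (any(is.na(records$label))) stop_config("kfold requires labeled records")
  fold <- stratified_folds(records$label, k, seed)
  sub_streams <- function(rec) {
    if (is.null(streams)) NULL
    else streams[rec$patient_id, , drop = FALSE]
  }
  folds <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- records[fold != f, ]
    te <- records[fold == f, ]
    model <- train_fn(tr, sub_streams(tr))
    pred <- predict_fn(model, te, sub_streams(te))
    folds[[f]] <- classification_metrics(confusion(te$label, pred))
  }
  nm <- c("accuracy", "precision", "recall", "specificity", "f1")
  tab <- sapply(folds, function(m) unlist(m[nm]))
  list(folds = folds, assignments = fold,
       summary = list(mean = rowMeans(tab),
                      sd = apply(tab, 1, stats::sd)))
}

#' Train:test ratio sweep with model-building time
#'
#' For each requested training fraction, draws one stratified split, trains
#' once, and records held-out metrics together with the wall-clock model
#' building time (MBT). Build times are hardware-dependent and are reported,
#' never asserted.
#'
#' @param records labeled cohort data.frame.
#' @param ratios training fractions, e.g. `c(0.5, 0.6, 0.7, 0.8)`.
#' @param train_fn,predict_fn as in [kfold()].
#' @param seed integer seed.
#' @param streams optional stream matrix.
#' @return data.frame with one row per ratio: the five measures plus
#'   `build_seconds`.
#' @export
split_sweep <- function(records, ratios = c(0.5, 0.6, 0.7, 0.8),
                        train_fn, predict_fn, seed = 1L, streams = NULL) {
  if (any(ratios <= 0 | ratios >= 1)) stop_config("ratios must be in (0, 1)")
  rows <- lapply(seq_along(ratios), function(j) {
    sp <- stratified_split(records, ratios[j], derive_seed(seed, paste0("sweep", j)))
    if (nrow(sp$train) == 0 || nrow(sp$test) == 0)
      stop_config("degenerate split at ratio ", ratios[j])
    str_tr <- if (is.null(streams)) NULL else streams[sp$train$patient_id, , drop = FALSE]
    str_te <- if (is.null(streams)) NULL else streams[sp$test$patient_id, , drop = FALSE]
    t0 <- proc.time()[["elapsed"]]
    model <- train_fn(sp$train, str_tr)
    mbt <- proc.time()[["elapsed"]] - t0
    pred <- predict_fn(model, sp$test, str_te)
    m <- classification_metrics(confusion(sp$test$label, pred))
    data.frame(ratio = ratios[j], accuracy = m$accuracy,
               precision = m$precision, recall = m$recall,
               specificity = m$specificity, f1 = m$f1,
               build_seconds = mbt)
  })
  do.call(rbind, rows)
}

# One stratified train/test split at the given training fraction.
stratified_split <- function(records, train_fraction, seed) {
  with_seed(seed, {
    take <- logical(nrow(records))
    for (cl in unique(records$label)) {
      idx <- which(records$label == cl)
      n_tr <- round(length(idx) * train_fraction)
      take[sample(idx, n_tr)] <- TRUE
    }
    list(train = records[take, ], test = records[!take, ])
  })
}

#' Multi-run outcome summary
#'
#' Order statistics and moments of a per-run scalar metric over repeated
#' independent runs: best, worst, mean, median, sd (n-1 denominator) and
#' variance.
#'
#' @param metric_samples numeric vector, one value per run (length >= 2).
#' @param maximize whether larger values are better (controls best/worst).
#' @export
multirun_outcomes <- function(metric_samples, maximize = TRUE) {
  x <- as.numeric(metric_samples)
  if (length(x) < 2) stop_numeric("multirun_outcomes: need at least 2 runs")
  s <- stats::sd(x)
  list(best = if (maximize) max(x) else min(x),
       worst = if (maximize) min(x) else max(x),
       mean = mean(x), median = stats::median(x),
       sd = s, variance = s^2, n_runs = length(x))
}
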