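# Resampling protocols and the metric suite: balanced sample sets, k-fold
# CV, LOOCV, Sn/Sp/Ac/Pre/MCC and trapezoidal AUC-ROC, aggregated as
# mean +/- sd over folds and sample sets.

METRIC_NAMES <- c("Sn", "Sp", "Ac", "Pre", "MCC", "AUC")

#' Confusion counts
#'
#' @param tp,tn,fp,fn non-negative integer counts (tp/fn refer to the
#'   positive, +1, class).
#' @return A `confusion_counts` object.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  structure(as.list(counts), class = "confusion_counts")
}

tally_confusion <- function(truth, predicted) {
  confusion_counts(tp = sum(truth == 1 & predicted == 1),
                   tn = sum(truth == -1 & predicted == -1),
                   fp = sum(truth == -1 & predicted == 1),
                   fn = sum(truth == 1 & predicted == -1))
}

#' Classification metrics from confusion counts
#'
#' Sn = tp/(tp+fn), Sp = tn/(tn+fp), Ac = (tp+tn)/(tp+fn+tn+fp),
#' Pre = tp/(tp+fp),
#' MCC = (tp*tn - fp*fn) / sqrt((tp+fn)(tp+fp)(tn+fn)(tn+fp)).
#' A metric whose denominator is zero is reported as `NA` (undefined,
#' distinct from 0) and later excluded-and-counted by [aggregate_report()].
#'
#' @param counts a [confusion_counts()] object.
#' @return Named numeric vector `Sn, Sp, Ac, Pre, MCC`.
#' @export
compute_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  rat <- function(num, den) if (den > 0) num / den else NA_real_
  mcc_den <- sqrt((tp + fn) * (tp + fp) * (tn + fn) * (tn + fp))
  c(Sn = rat(tp, tp + fn),
    Sp = rat(tn, tn + fp),
    Ac = rat(tp + tn, tp + fn + tn + fp),
    Pre = rat(tp, tp + fp),
    MCC = if (mcc_den > 0) (tp * tn - fp * fn) / mcc_den else NA_real_)
}

#' ROC curve over all distinct score thresholds
#'
#' Scores are swept from high to low; tied scores collapse onto a single
#' threshold. The curve starts at (0, 0) and ends at (1, 1); false and true
#' positive rates are non-decreasing along the sweep.
#'
#' @param scores numeric score per instance (higher = more positive).
#' @param labels +1 / -1 per instance; both classes required.
#' @return Data frame with columns `threshold`, `fpr` (alpha), `tpr`
#'   (1 - beta).
#' @export
roc_curve <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(is.finite(scores)),
            all(labels %in% c(-1, 1)))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == -1)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- labels[o]
  keep <- which(!duplicated(s, fromLast = TRUE))  # last index of each tie run
  tpr <- cumsum(y == 1)[keep] / n_pos
  fpr <- cumsum(y == -1)[keep] / n_neg
  data.frame(threshold = c(Inf, s[keep]), fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Area under the ROC curve (trapezoidal)
#'
#' Accumulates `sum_i [ (1-beta_(i-1)) * d(alpha) + 1/2 d(1-beta) * d(alpha) ]`
#' over the threshold sweep of [roc_curve()] — the trapezoidal rule, which
#' equals the Mann-Whitney estimate of P(score+ > score-) with ties counted
#' one half.
#'
#' @inheritParams roc_curve
#' @return AUC in \[0, 1\].
#' @export
auc_roc <- function(scores, labels) {
  rc <- roc_curve(scores, labels)
  da <- diff(rc$fpr)
  db <- diff(rc$tpr)
  sum(head(rc$tpr, -1L) * da + 0.5 * db * da)
}

#' Partition indices into k folds
#'
#' @param n number of instances.
#' @param k number of folds (2 <= k <= n).
#' @param seed integer seed for the shuffle.
#' @param stratified preserve the class ratio per fold (within one
#'   instance); requires `labels`.
#' @param labels class labels, needed when `stratified`.
#' @return List of `k` disjoint index vectors covering `1..n`, sizes
#'   differing by at most 1.
#' @export
kfold_split <- function(n, k, seed = 1L, stratified = FALSE, labels = NULL) {
  k <- as.integer(k)
  stopifnot(k >= 2L)
  if (k > n) stop("more folds than instances")
  assign_fold <- withr::with_seed(as.integer(seed), {
    if (!stratified) {
      f <- integer(n)
      f[sample.int(n)] <- rep(seq_len(k), length.out = n)
      f
    } else {
      stopifnot(!is.null(labels), length(labels) == n)
      f <- integer(n)
      direction <- 1L
      for (cls in sort(unique(labels))) {
        idx <- sample(which(labels == cls))
        folds <- rep(seq_len(k), length.out = length(idx))
        if (direction < 0) folds <- (k + 1L) - folds  # balance totals
        f[idx] <- folds
        direction <- -direction
      }
      f
    }
  })
  unname(split(seq_len(n), assign_fold))
}

#' Balanced sample sets from an imbalanced pair of classes
#'
#' Each set contains all positives plus an equal-size uniform draw from the
#' negatives (without replacement within a set, independent across sets).
#'
#' @param positives,negatives `protein_set`s (or data frames with `id`,
#'   `sequence`); negatives must be at least as numerous as positives.
#' @param n_sets number of sample sets.
#' @param seed integer seed.
#' @return List of `n_sets` [labeled_dataset()]s, each with a 50/50 class
#'   split.
#' @export
balanced_sample_sets <- function(positives, negatives, n_sets, seed = 1L) {
  n_pos <- nrow(positives)
  n_neg <- nrow(negatives)
  if (n_neg < n_pos) stop("fewer negatives than positives")
  stopifnot(n_sets >= 1L)
  draws <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_sets), function(s) sample.int(n_neg, n_pos))
  })
  lapply(draws, function(idx) {
    both <- rbind(data.frame(id = positives$id, sequence = positives$sequence,
                             label = 1L, stringsAsFactors = FALSE),
                  data.frame(id = negatives$id[idx],
                             sequence = negatives$sequence[idx],
                             label = -1L, stringsAsFactors = FALSE))
    structure(both, class = c("labeled_dataset", "protein_set", "data.frame"))
  })
}

fold_eval_row <- function(truth, pred) {
  counts <- tally_confusion(truth, pred$label)
  score <- if (all(is.na(pred$probability))) pred$decision_value else
    pred$probability
  auc <- if (length(unique(truth)) == 2L) auc_roc(score, truth) else NA_real_
  c(tp = counts$tp, tn = counts$tn, fp = counts$fp, fn = counts$fn,
    compute_metrics(counts), AUC = auc)
}

#' k-fold cross-validation of one dataset
#'
#' Sequences are encoded once (every descriptor is a per-sequence map, so
#' encoding cannot leak fold information); each fold is scored by a model
#' trained on the remaining k-1 folds.
#'
#' @param dataset a [labeled_dataset()].
#' @param scheme descriptor scheme name (see [encode_features()]).
#' @param k number of folds.
#' @param kernel a [kernel_spec()].
#' @param cost SVM regularization parameter.
#' @param seed integer seed (fold assignment).
#' @param stratified stratify folds by class (default TRUE).
#' @param features optional pre-encoded [feature_matrix()] for `dataset`
#'   (rows in dataset order); when supplied, `scheme` encoding is skipped.
#' @param ... passed to [encode_features()].
#' @return List with `folds` (data frame: fold, tp/tn/fp/fn, Sn, Sp, Ac,
#'   Pre, MCC, AUC) and `predictions` (per-instance: id, fold, truth, label,
#'   probability, decision_value).
#' @export
run_cv <- function(dataset, scheme = "DPC", k = 10L,
                   kernel = kernel_spec("rbf"), cost = 1, seed = 1L,
                   stratified = TRUE, features = NULL, ...) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  fm <- features %||% encode_features(dataset, scheme, ...)
  stopifnot(nrow(fm) == nrow(dataset))
  y <- dataset$label
  folds <- kfold_split(nrow(dataset), k, seed = seed,
                       stratified = stratified, labels = y)
  rows <- list()
  preds <- list()
  for (f in seq_along(folds)) {
    test <- folds[[f]]
    train <- setdiff(seq_len(nrow(dataset)), test)
    model <- train_svm(fm_rows(fm, train), y[train], kernel = kernel,
                       cost = cost, probability = TRUE, seed = seed)
    p <- predict(model, fm_rows(fm, test))
    rows[[f]] <- c(fold = f, fold_eval_row(y[test], p))
    preds[[f]] <- data.frame(id = dataset$id[test], fold = f,
                             truth = y[test], label = p$label,
                             probability = p$probability,
                             decision_value = p$decision_value,
                             stringsAsFactors = FALSE)
  }
  list(folds = as.data.frame(do.call(rbind, rows)),
       predictions = do.call(rbind, preds))
}

#' Leave-one-out cross-validation of one dataset
#'
#' Each instance is predicted by a model trained on all the others; metrics
#' are computed on the pooled confusion counts, AUC on the pooled scores.
#'
#' @inheritParams run_cv
#' @return List with `counts` (pooled [confusion_counts()]), `metrics`
#'   (pooled Sn..MCC plus AUC) and `predictions` (one row per instance).
#' @export
run_loocv <- function(dataset, scheme = "DPC", kernel = kernel_spec("rbf"),
                      cost = 1, seed = 1L, features = NULL, ...) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  n <- nrow(dataset)
  y <- dataset$label
  if (n < 3L || length(unique(y)) < 2L) {
    stop("LOOCV needs at least 3 instances and both classes")
  }
  if (min(table(y)) < 2L) {
    stop("a class with a single member would leave degenerate training sets")
  }
  fm <- features %||% encode_features(dataset, scheme, ...)
  preds <- vector("list", n)
  for (i in seq_len(n)) {
    train <- setdiff(seq_len(n), i)
    model <- train_svm(fm_rows(fm, train), y[train], kernel = kernel,
                       cost = cost, probability = TRUE, seed = seed)
    p <- predict(model, fm_rows(fm, i))
    preds[[i]] <- data.frame(id = dataset$id[i], truth = y[i],
                             label = p$label, probability = p$probability,
                             decision_value = p$decision_value,
                             stringsAsFactors = FALSE)
  }
  preds <- do.call(rbind, preds)
  counts <- tally_confusion(preds$truth, preds$label)
  score <- if (all(is.na(preds$probability))) preds$decision_value else
    preds$probability
  metrics <- c(compute_metrics(counts), AUC = auc_roc(score, preds$truth))
  list(counts = counts, metrics = metrics, predictions = preds)
}

#' Aggregate fold x sample-set metrics into a report
#'
#' Headline mean and (sample) standard deviation are taken over all defined
#' fold-level values; per-set means are also aggregated separately, since
#' published +/- figures are sometimes sd over set means. Undefined (NA)
#' metric values are excluded and counted, never coerced to 0.
#'
#' @param fold_tables list (one element per sample set) of fold-level metric
#'   data frames as produced by [run_cv()] (`$folds`), or single-row data
#'   frames for LOOCV pooled metrics.
#' @param protocol list describing the protocol (k, n_sets, seeds, ...).
#' @return An `evaluation_report` with `cells` (set, fold, counts, metrics),
#'   `summary` (metric, mean, sd, n, n_undefined, set_mean, set_sd) and
#'   `protocol`.
#' @export
aggregate_report <- function(fold_tables, protocol = list()) {
  stopifnot(length(fold_tables) >= 1L)
  cells <- do.call(rbind, lapply(seq_along(fold_tables), function(s) {
    cbind(set = s, fold_tables[[s]])
  }))
  summary <- do.call(rbind, lapply(METRIC_NAMES, function(m) {
    v <- cells[[m]]
    if (all(is.na(v))) stop("metric ", m, " undefined in every cell")
    set_means <- tapply(v, cells$set, mean, na.rm = TRUE)
    data.frame(metric = m, mean = mean(v, na.rm = TRUE),
               sd = if (sum(!is.na(v)) > 1L) sd(v, na.rm = TRUE) else NA_real_,
               n = sum(!is.na(v)), n_undefined = sum(is.na(v)),
               set_mean = mean(set_means),
               set_sd = if (length(set_means) > 1L) sd(set_means) else
                 NA_real_,
               stringsAsFactors = FALSE)
  }))
  structure(list(cells = cells, summary = summary, protocol = protocol),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  p <- x$protocol
  cat(sprintf("evaluation_report: %s sample set(s), %s\n",
              length(unique(x$cells$set)),
              if (!is.null(p$k)) sprintf("%d-fold CV", p$k) else "LOOCV"))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-4s %.3f +/- %.3f  (n = %d, undefined = %d)\n",
                s$metric[i], s$mean[i], s$sd[i], s$n[i], s$n_undefined[i]))
  }
  invisible(x)
}

#' Balanced-resampling cross-validation experiment
#'
#' The full protocol: draw `n_sets` balanced sample sets, run k-fold CV (or
#' LOOCV) on each, aggregate over folds and sets.
#'
#' @param positives,negatives `protein_set`s of the two classes.
#' @param n_sets number of balanced sample sets.
#' @param scheme descriptor scheme.
#' @param k folds (ignored when `loocv = TRUE`).
#' @param kernel a [kernel_spec()].
#' @param cost SVM regularization parameter.
#' @param seed master seed; per-set seeds are derived as `seed + set`.
#' @param loocv use leave-one-out instead of k-fold.
#' @param stratified stratified folds (k-fold only).
#' @param ... passed to [encode_features()].
#' @return An [aggregate_report()] `evaluation_report`.
#' @export
evaluate_balanced <- function(positives, negatives, n_sets = 100L,
                              scheme = "DPC", k = 10L,
                              kernel = kernel_spec("rbf"), cost = 1,
                              seed = 1L, loocv = FALSE, stratified = TRUE,
                              ...) {
  sets <- balanced_sample_sets(positives, negatives, n_sets, seed = seed)
  tables <- lapply(seq_along(sets), function(s) {
    if (loocv) {
      res <- run_loocv(sets[[s]], scheme, kernel = kernel, cost = cost,
                       seed = seed + s, ...)
      cbind(data.frame(fold = 1L, tp = res$counts$tp, tn = res$counts$tn,
                       fp = res$counts$fp, fn = res$counts$fn),
            as.data.frame(as.list(res$metrics)))
    } else {
      run_cv(sets[[s]], scheme, k = k, kernel = kernel, cost = cost,
             seed = seed + s, stratified = stratified, ...)$folds
    }
  })
  aggregate_report(tables, protocol = list(
    k = if (!loocv) as.integer(k), n_sets = as.integer(n_sets),
    loocv = loocv, scheme = scheme, kernel = kernel$kind, cost = cost,
    seed = as.integer(seed)))
}

#' Write an evaluation report as CSV files
#'
#' @param report an `evaluation_report`.
#' @param prefix output path prefix; writes `<prefix>_cells.csv` and
#'   `<prefix>_summary.csv`.
#' @return The two paths, invisibly.
#' @export
write_report <- function(report, prefix) {
  cells <- paste0(prefix, "_cells.csv")
  summ <- paste0(prefix, "_summary.csv")
  write.csv(report$cells, cells, row.names = FALSE)
  write.csv(report$summary, summ, row.names = FALSE)
  invisible(c(cells, summ))
}
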