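# Evaluation against reference operon-pair labels: recall/specificity,
# ROC/AUC, bootstrap confidence intervals, the repeated 75/25 split
# validation protocol, and feature-label Spearman diagnostics.

# join calls to labels by pair identity; tries both gene orientations
.join_calls_labels <- function(calls, labels) {
  lab_key <- if ("pair_id" %in% names(labels)) labels$pair_id else
    paste(labels$geneA_id, labels$geneB_id, sep = "|")
  lab <- stats::setNames(labels$label, lab_key)
  rev_key <- if ("pair_id" %in% names(labels))
    vapply(strsplit(lab_key, "|", fixed = TRUE),
           function(p) paste(rev(p), collapse = "|"), character(1))
  else paste(labels$geneB_id, labels$geneA_id, sep = "|")
  lab_rev <- stats::setNames(labels$label, rev_key)
  y <- lab[calls$pair_id]
  y[is.na(y)] <- lab_rev[calls$pair_id[is.na(y)]]
  keep <- !is.na(y)
  if (!any(keep))
    stop("no overlap between prediction pairs and label pairs")
  cbind(calls[keep, , drop = FALSE], label = as.integer(y[keep]))
}

#' Recall and specificity against reference labels
#'
#' Scores binary calls against the reference pair labels. Only pairs
#' present in both tables are scored. Recall = TP/(TP+FN), specificity =
#' TN/(TN+FP); a ratio with zero denominator is reported as `NA`
#' (missing), never as 0.
#'
#' @param calls data.frame with `pair_id` and a binary `call` column (use
#'   `call = votes >= k` upstream for a thresholded ensemble).
#' @param labels Label data.frame ([read_pair_labels()]).
#' @return Object of class `operon_eval`: list with `recall`,
#'   `specificity`, `n_pairs`, and the confusion counts `tp`, `fp`, `tn`,
#'   `fn`.
#' @export
confusion_metrics <- function(calls, labels) {
  if (!"call" %in% names(calls))
    stop("`calls` must have a binary `call` column")
  df <- .join_calls_labels(calls, labels)
  tp <- sum(df$call == 1L & df$label == 1L)
  fp <- sum(df$call == 1L & df$label == 0L)
  tn <- sum(df$call == 0L & df$label == 0L)
  fn <- sum(df$call == 0L & df$label == 1L)
  structure(list(
    recall = if (tp + fn > 0L) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0L) tn / (tn + fp) else NA_real_,
    n_pairs = nrow(df), tp = tp, fp = fp, tn = tn, fn = fn
  ), class = "operon_eval")
}

#' @export
print.operon_eval <- function(x, ...) {
  cat(sprintf("operon_eval: n = %d, recall = %s, specificity = %s\n",
              x$n_pairs, format(x$recall, digits = 4),
              format(x$specificity, digits = 4)))
  invisible(x)
}

#' ROC curve and AUC
#'
#' Sweeps thresholds over the score (a probability or a vote count) to
#' produce (FPR, TPR) points and computes the area under the curve by the
#' trapezoid rule. For a single binary call the curve is the polyline
#' (0,0) -> (1-specificity, sensitivity) -> (1,1), whose area equals
#' (sensitivity + specificity) / 2.
#'
#' @param scores Numeric score vector (higher = more operon-like).
#' @param labels 0/1 labels, same length.
#' @return List: `points` (data.frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_auc <- function(scores, labels) {
  y <- as.integer(labels)
  stopifnot(length(scores) == length(y))
  if (length(unique(y)) < 2L)
    stop("roc_auc(): labels contain a single class")
  np <- sum(y == 1L); nn <- sum(y == 0L)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- t(vapply(thr, function(t) {
    call <- scores >= t
    c(fpr = sum(call & y == 0L) / nn, tpr = sum(call & y == 1L) / np)
  }, numeric(2)))
  points <- data.frame(threshold = thr, fpr = pts[, "fpr"],
                       tpr = pts[, "tpr"])
  o <- order(points$fpr, points$tpr)
  fpr <- points$fpr[o]; tpr <- points$tpr[o]
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(points = points, auc = auc)
}

#' Bootstrap mean and 95% confidence interval of a metric
#'
#' Each iteration draws `fraction * n` scored pairs with replacement and
#' recomputes the metric; reported are the mean and the 2.5/97.5
#' percentile bounds across iterations. Iterations where the metric is
#' undefined (zero denominator) are dropped; more than 50% undefined is an
#' error.
#'
#' @param metric `"recall"`, `"specificity"` or `"accuracy"`, or a
#'   function(call, label) -> number.
#' @param calls data.frame with `pair_id` and `call`.
#' @param labels Label data.frame.
#' @param n_boot Number of bootstrap iterations (default 100).
#' @param fraction Fraction of scored pairs drawn per iteration (default
#'   0.10).
#' @param seed RNG seed.
#' @return List: `mean`, `lower`, `upper` (95% CI), `values` (per
#'   iteration).
#' @export
bootstrap_ci <- function(metric, calls, labels, n_boot = 100L,
                         fraction = 0.10, seed = 1L) {
  df <- .join_calls_labels(calls, labels)
  if (nrow(df) < 10L) stop("bootstrap_ci(): fewer than 10 scored pairs")
  f <- if (is.function(metric)) metric else switch(metric,
    recall = function(call, label) {
      if (!any(label == 1L)) NA_real_ else
        sum(call == 1L & label == 1L) / sum(label == 1L)
    },
    specificity = function(call, label) {
      if (!any(label == 0L)) NA_real_ else
        sum(call == 0L & label == 0L) / sum(label == 0L)
    },
    accuracy = function(call, label) mean(call == label),
    stop("unknown metric: ", metric))
  m <- max(1L, round(fraction * nrow(df)))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  vals <- vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(nrow(df), m, replace = TRUE)
    f(df$call[idx], df$label[idx])
  }, numeric(1))
  if (mean(is.na(vals)) > 0.5)
    stop("bootstrap_ci(): metric undefined in more than half the iterations")
  ok <- vals[!is.na(vals)]
  list(mean = mean(ok),
       lower = unname(quantile(ok, 0.025, type = 7)),
       upper = unname(quantile(ok, 0.975, type = 7)),
       values = vals)
}

#' Repeated random split validation of the suite
#'
#' Repeats the train/predict/score cycle on random splits of the labelled
#' feature table: `train_fraction` of the *pairs* (stratified by label;
#' all replicate rows of a pair stay on one side) train the suite, the
#' rest are scored. Reports mean recall and specificity per algorithm
#' across splits.
#'
#' @param features Labelled feature data.frame (with `label`).
#' @param n_splits Number of random splits (default 50; reduce for
#'   desk-scale runs).
#' @param train_fraction Fraction of pairs used for training (default
#'   0.75).
#' @param seed Master seed.
#' @param optimize Passed to [train_suite()].
#' @param hyperparameters Passed to [train_suite()].
#' @return List: `per_algorithm` (data.frame `algorithm`, `recall`,
#'   `specificity` -- means across splits), `splits` (per-split
#'   data.frames).
#' @export
split_validate <- function(features, n_splits = 50L, train_fraction = 0.75,
                           seed = 1L, optimize = FALSE,
                           hyperparameters = NULL) {
  if (!"label" %in% names(features)) stop("features must carry a `label` column")
  if (length(unique(features$label)) < 2L)
    stop("split_validate(): both classes must be present")
  pair_lab <- tapply(features$label, features$pair_id, function(v) v[1])
  pairs <- names(pair_lab)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  splits <- vector("list", n_splits)
  for (s in seq_len(n_splits)) {
    set.seed((seed + 977L * s) %% .Machine$integer.max)
    train_pairs <- unlist(lapply(split(pairs, pair_lab), function(p)
      sample(p, round(train_fraction * length(p)))))
    tr <- features$pair_id %in% train_pairs
    suite <- train_suite(features[tr, , drop = FALSE], optimize = optimize,
                         hyperparameters = hyperparameters,
                         seed = (seed + 977L * s) %% .Machine$integer.max)
    preds <- predict_suite(suite, features[!tr, , drop = FALSE])
    y <- features$label[!tr]
    splits[[s]] <- do.call(rbind, lapply(.alg_keys, function(alg) {
      call <- preds[[paste0(alg, "_call")]]
      data.frame(algorithm = alg,
                 recall = if (any(y == 1L))
                   sum(call == 1L & y == 1L) / sum(y == 1L) else NA_real_,
                 specificity = if (any(y == 0L))
                   sum(call == 0L & y == 0L) / sum(y == 0L) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }
  all <- do.call(rbind, splits)
  per_alg <- do.call(rbind, lapply(.alg_keys, function(alg) {
    a <- all[all$algorithm == alg, ]
    data.frame(algorithm = alg, recall = mean(a$recall, na.rm = TRUE),
               specificity = mean(a$specificity, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  list(per_algorithm = per_alg, splits = splits)
}

#' Spearman correlation of each feature with the pair label
#'
#' Diagnostic mirroring the feature-label correlation analysis: midrank
#' Spearman coefficient of each of the 12 features against the binary
#' label. Constant features yield `NA`.
#'
#' @param features Labelled feature data.frame.
#' @param labels Optional label vector overriding `features$label`.
#' @return Named numeric vector, one coefficient per feature.
#' @export
feature_label_spearman <- function(features, labels = NULL) {
  if (is.null(labels)) labels <- features$label
  y <- as.numeric(labels)
  if (length(y) < 3L) stop("need at least 3 rows")
  vapply(operon_feature_names(), function(col) {
    v <- features[[col]]
    if (length(unique(v)) < 2L || length(unique(y)) < 2L) return(NA_real_)
    cor(v, y, method = "spearman")
  }, numeric(1))
}
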