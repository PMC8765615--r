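# The six-classifier suite: min-max scaler, per-algorithm fit/predict
# backends, suite training, prediction and directory persistence.
# Features are scaled for LR, SVM, MLP and GNB; the tree ensembles (RF,
# XGB) see raw features, as rank-based splits are scale-invariant.

#' Min-max feature scaler
#'
#' Learns per-feature minimum and maximum from training data; `apply_scaler`
#' maps the training minimum to 0 and maximum to 1 linearly. Constant
#' features map to 0. Prediction-time values outside the training range are
#' *not* clipped and may fall outside \[0, 1\].
#'
#' @param features Feature data.frame or numeric matrix with the columns of
#'   [operon_feature_names()] (extra columns ignored).
#' @return Object of class `operon_scaler`.
#' @export
fit_scaler <- function(features) {
  X <- .feature_matrix(features)
  structure(list(min = apply(X, 2L, min), max = apply(X, 2L, max),
                 cols = colnames(X)),
            class = "operon_scaler")
}

#' @rdname fit_scaler
#' @param scaler A fitted `operon_scaler`.
#' @export
apply_scaler <- function(scaler, features) {
  X <- .feature_matrix(features, cols = scaler$cols)
  missing <- setdiff(scaler$cols, colnames(X))
  if (length(missing))
    stop("feature table missing column(s): ", paste(missing, collapse = ", "))
  X <- X[, scaler$cols, drop = FALSE]
  rng <- scaler$max - scaler$min
  rng[rng == 0] <- Inf  # constant feature -> 0
  sweep(sweep(X, 2L, scaler$min), 2L, rng, "/")
}

.feature_matrix <- function(features, cols = operon_feature_names()) {
  if (is.matrix(features)) {
    # plain matrices are taken as-is (the scaler is generic); named
    # selection applies only when the requested columns are present
    if (is.null(colnames(features)))
      colnames(features) <- paste0("V", seq_len(ncol(features)))
    if (all(cols %in% colnames(features)))
      return(features[, cols, drop = FALSE])
    return(features)
  }
  missing <- setdiff(cols, names(features))
  if (length(missing))
    stop("feature table missing column(s): ", paste(missing, collapse = ", "))
  as.matrix(features[cols])
}

#' Documented default hyperparameters for each algorithm
#'
#' Used when [train_suite()] is run with `optimize = FALSE`.
#'
#' @return Named list keyed by [algorithm_keys()].
#' @export
default_hyperparameters <- function() {
  list(
    LR = list(penalty = "L2", C = 1),
    SVM = list(kernel = "radial", C = 1, gamma = NA),  # NA: 1/n_features
    RF = list(min_split = 2L, max_depth = 0L, n_estimators = 200L),
    XGB = list(gamma = 0, learning_rate = 0.3, n_estimators = 100L),
    MLP = list(alpha = 1e-4, max_iter = 300L, n_layers = 1L, neurons = 32L),
    GNB = list(var_smoothing = 1e-9)
  )
}

# fit one algorithm; X must already be scaled/raw as appropriate
.fit_algorithm <- function(alg, X, y, hp, seed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- nrow(X)
  switch(alg,
    LR = {
      alpha <- if (identical(hp$penalty, "L1")) 1 else 0
      lambda <- 1 / (n * hp$C)
      m <- tryCatch(
        glmnet::glmnet(X, factor(y, levels = 0:1), family = "binomial",
                       alpha = alpha, lambda = lambda),
        error = function(e) NULL)
      if (is.null(m)) {
        # glmnet refuses near-degenerate class counts; plain IRLS memorizes
        df <- data.frame(y = y, X)
        m <- suppressWarnings(glm(y ~ ., data = df, family = binomial()))
        class(m) <- c("operon_glm_fallback", class(m))
      }
      list(model = m, lambda = lambda)
    },
    SVM = {
      gamma <- if (is.null(hp$gamma) || is.na(hp$gamma)) 1 / ncol(X) else hp$gamma
      counts <- table(factor(y, levels = 0:1))
      use_prob <- all(counts >= 5L)
      m <- e1071::svm(x = X, y = factor(y, levels = 0:1),
                      kernel = hp$kernel, cost = hp$C, gamma = gamma,
                      probability = use_prob, scale = FALSE)
      list(model = m, prob = use_prob && isTRUE(m$compprob))
    },
    RF = {
      # min_split counts samples needed to split a node; ranger's
      # min.node.size is the smallest node that may still be split minus one
      ranger::ranger(
        x = as.data.frame(X), y = factor(y, levels = 0:1),
        num.trees = hp$n_estimators,
        min.node.size = max(1L, hp$min_split - 1L),
        max.depth = hp$max_depth, probability = TRUE,
        seed = seed, num.threads = 1L)
    },
    XGB = {
      dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1L)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", eta = hp$learning_rate,
                      gamma = hp$gamma, max_depth = 6L,
                      min_child_weight = 0, nthread = 1L, seed = seed),
        data = dtrain, nrounds = hp$n_estimators, verbose = 0L)
    },
    MLP = mlp_fit(X, y, hidden = rep(hp$neurons, hp$n_layers),
                  alpha = hp$alpha, max_iter = hp$max_iter, seed = seed),
    GNB = gnb_fit(X, y, var_smoothing = hp$var_smoothing),
    stop("unknown algorithm key: ", alg)
  )
}

# positive-class probability from one fitted algorithm
.predict_algorithm <- function(alg, fit, X) {
  p <- switch(alg,
    LR = {
      if (inherits(fit$model, "operon_glm_fallback")) {
        suppressWarnings(as.numeric(
          predict(fit$model, newdata = as.data.frame(X), type = "response")))
      } else {
        as.numeric(predict(fit$model, X, type = "response", s = fit$lambda))
      }
    },
    SVM = {
      if (fit$prob) {
        pr <- attr(predict(fit$model, X, probability = TRUE), "probabilities")
        as.numeric(pr[, "1"])
      } else {
        dv <- attr(predict(fit$model, X, decision.values = TRUE),
                   "decision.values")
        # positive decision values favor the first level ("0")
        sgn <- if (colnames(dv)[1] == "0/1") -1 else 1
        plogis(sgn * as.numeric(dv))
      }
    },
    RF = as.numeric(predict(fit, data = as.data.frame(X),
                            num.threads = 1L)$predictions[, "1"]),
    XGB = as.numeric(predict(fit, xgboost::xgb.DMatrix(X, nthread = 1L))),
    MLP = mlp_predict(fit, X),
    GNB = gnb_predict(fit, X),
    stop("unknown algorithm key: ", alg)
  )
  pmin(pmax(p, 0), 1)
}

#' Train the six-classifier suite
#'
#' Fits LR, SVM, RF, XGB, MLP and GNB on the labelled feature table. The
#' min-max scaler is learned on the training features and applied to all
#' algorithms except RF and XGB, at training and at prediction time. With
#' `optimize = TRUE`, each algorithm's hyperparameters are first tuned with
#' [optimize_hyperparameters()]; otherwise [default_hyperparameters()] (or
#' the `hyperparameters` argument) are used.
#'
#' @param features Feature data.frame containing [operon_feature_names()]
#'   columns and, unless `labels` is given, a 0/1 `label` column.
#' @param labels Optional 0/1 vector overriding `features$label`.
#' @param optimize Run Bayesian hyperparameter optimization per algorithm.
#' @param hyperparameters Optional named list (per algorithm key) of
#'   hyperparameters overriding the defaults.
#' @param seed Master seed; each algorithm is fitted under a sub-seed
#'   derived from it.
#' @param opt_control List of optimization settings: `iterations`, `folds`,
#'   `method` ("gp" or "random"); see [optimize_hyperparameters()].
#' @return Object of class `operon_suite`.
#' @export
train_suite <- function(features, labels = NULL, optimize = FALSE,
                        hyperparameters = NULL, seed = 1009731L,
                        opt_control = list()) {
  if (is.null(labels)) {
    if (!"label" %in% names(features))
      stop("no `labels` argument and no `label` column in features")
    labels <- features$label
  }
  y <- as.integer(labels)
  if (!all(y %in% 0:1)) stop("labels must be binary 0/1")
  X <- .feature_matrix(features)
  bad <- which(!stats::complete.cases(X) | apply(X, 1L, function(r) any(!is.finite(r))))
  if (length(bad))
    stop("non-finite feature values in row(s): ",
         paste(head(bad, 10L), collapse = ", "))
  scaler <- fit_scaler(X)
  Xs <- apply_scaler(scaler, X)
  hp <- default_hyperparameters()
  if (!is.null(hyperparameters))
    for (k in names(hyperparameters)) hp[[k]][names(hyperparameters[[k]])] <-
      hyperparameters[[k]]
  oc <- utils::modifyList(list(iterations = 10L, folds = 10L, method = "gp"),
                          opt_control)
  models <- list()
  for (i in seq_along(.alg_keys)) {
    alg <- .alg_keys[i]
    Xa <- if (alg %in% .scaled_algs) Xs else X
    sub_seed <- (seed + 101L * i) %% .Machine$integer.max
    if (optimize) {
      opt <- optimize_hyperparameters(alg, X, y,
                                      iterations = oc$iterations,
                                      folds = oc$folds, seed = sub_seed,
                                      method = oc$method, scaler = scaler)
      hp[[alg]][names(opt$best_config)] <- opt$best_config
    }
    models[[alg]] <- .fit_algorithm(alg, Xa, y, hp[[alg]], sub_seed)
  }
  structure(list(models = models, scaler = scaler, hyperparameters = hp,
                 seed = seed, n = nrow(X),
                 feature_names = colnames(X),
                 version = as.character(utils::packageVersion("operonvoter"))),
            class = "operon_suite")
}

#' @export
print.operon_suite <- function(x, ...) {
  cat("operon_suite: 6 classifiers (", paste(names(x$models), collapse = ", "),
      ") trained on ", x$n, " rows, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Predict with a trained suite
#'
#' Emits, per (pair, sample) row, each algorithm's positive-class
#' probability and binary call. A call is positive iff the probability is
#' at least 0.5 (ties go to the positive class, favoring recall).
#'
#' @param suite An `operon_suite` from [train_suite()].
#' @param features Feature data.frame with the training feature columns
#'   (order is re-validated on every call).
#' @return data.frame: `pair_id`, `sample_id`, then `<ALG>_prob` and
#'   `<ALG>_call` per algorithm.
#' @export
predict_suite <- function(suite, features) {
  if (nrow(features) == 0L) {
    out <- stats::setNames(data.frame(matrix(nrow = 0, ncol = length(.pred_cols()))),
                           .pred_cols())
    return(out)
  }
  X <- .feature_matrix(features, cols = suite$feature_names)
  Xs <- apply_scaler(suite$scaler, X)
  out <- data.frame(
    pair_id = if ("pair_id" %in% names(features)) features$pair_id
              else as.character(seq_len(nrow(X))),
    sample_id = if ("sample_id" %in% names(features)) features$sample_id
                else "sample",
    stringsAsFactors = FALSE
  )
  for (alg in .alg_keys) {
    Xa <- if (alg %in% .scaled_algs) Xs else X
    p <- .predict_algorithm(alg, suite$models[[alg]], Xa)
    out[[paste0(alg, "_prob")]] <- p
    out[[paste0(alg, "_call")]] <- as.integer(p >= 0.5)
  }
  out[.pred_cols()]
}

#' Persist / restore a trained suite
#'
#' The suite is stored as a directory: `metadata.json` (feature order,
#' hyperparameters, seed, version, training size) plus one binary blob per
#' algorithm and one for the scaler. `load_suite(save_suite(s, d))` yields
#' identical predictions.
#'
#' @param suite An `operon_suite`.
#' @param dir Directory path (created if needed).
#' @return `save_suite()` returns `dir` invisibly; `load_suite()` the
#'   restored `operon_suite`.
#' @export
save_suite <- function(suite, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(feature_names = suite$feature_names,
               hyperparameters = suite$hyperparameters,
               seed = suite$seed, n = suite$n, version = suite$version,
               algorithms = names(suite$models))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  saveRDS(suite$scaler, file.path(dir, "scaler.rds"))
  for (alg in names(suite$models)) {
    obj <- suite$models[[alg]]
    if (alg == "XGB") obj <- xgboost::xgb.save.raw(obj)
    saveRDS(obj, file.path(dir, paste0(alg, ".rds")))
  }
  invisible(dir)
}

#' @rdname save_suite
#' @export
load_suite <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  models <- list()
  for (alg in meta$algorithms) {
    obj <- readRDS(file.path(dir, paste0(alg, ".rds")))
    if (alg == "XGB") obj <- xgboost::xgb.load.raw(obj)
    models[[alg]] <- obj
  }
  hp <- lapply(meta$hyperparameters, as.list)
  structure(list(models = models,
                 scaler = readRDS(file.path(dir, "scaler.rds")),
                 hyperparameters = hp, seed = meta$seed, n = meta$n,
                 feature_names = meta$feature_names,
                 version = meta$version),
            class = "operon_suite")
}
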