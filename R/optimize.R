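# Hyperparameter search spaces (bounded versions of the published
# dimensions) and sequential model-based optimization: a Gaussian-process
# surrogate with expected improvement over the unit hypercube, or plain
# random search over the same space and budget.

#' Hyperparameter search space for one algorithm
#'
#' Dimensions per algorithm: LR penalty (L1/L2) and C; RF minimum node
#' size to split, maximum depth and number of trees (integers); SVM kernel
#' (RBF by default; the full categorical search is available via
#' `svm_kernel_search`), C and gamma; XGB gamma, learning rate and number
#' of estimators (integer); GNB variance smoothing; MLP alpha, maximum
#' iterations, hidden-layer count and neurons per layer (integers).
#' Continuous scale-type dimensions (C, gamma, learning rate, smoothing,
#' alpha) are searched on a log scale.
#'
#' @param algorithm One of [algorithm_keys()].
#' @param svm_kernel_search Search linear/radial/sigmoid/polynomial kernels
#'   instead of fixing RBF.
#' @return List of dimension descriptors (`name`, `type`, bounds or
#'   `values`, `log`).
#' @export
hyperparameter_space <- function(algorithm, svm_kernel_search = FALSE) {
  num <- function(name, lower, upper, log = FALSE)
    list(name = name, type = "num", lower = lower, upper = upper, log = log)
  int <- function(name, lower, upper)
    list(name = name, type = "int", lower = lower, upper = upper, log = FALSE)
  cat_ <- function(name, values) list(name = name, type = "cat", values = values)
  switch(algorithm,
    LR = list(cat_("penalty", c("L1", "L2")), num("C", 1e-3, 1e3, log = TRUE)),
    RF = list(int("min_split", 2L, 20L), int("max_depth", 2L, 20L),
              int("n_estimators", 50L, 500L)),
    SVM = list(
      cat_("kernel", if (svm_kernel_search)
        c("linear", "radial", "sigmoid", "polynomial") else "radial"),
      num("C", 1e-3, 1e3, log = TRUE), num("gamma", 1e-4, 10, log = TRUE)),
    XGB = list(num("gamma", 0, 5), num("learning_rate", 1e-3, 0.5, log = TRUE),
               int("n_estimators", 50L, 500L)),
    GNB = list(num("var_smoothing", 1e-12, 1e-6, log = TRUE)),
    MLP = list(num("alpha", 1e-5, 1e-1, log = TRUE),
               int("max_iter", 100L, 500L), int("n_layers", 1L, 3L),
               int("neurons", 4L, 128L)),
    stop("unknown algorithm key: ", algorithm)
  )
}

# draw one random configuration from a space (uses the current RNG stream)
.sample_config <- function(space) {
  cfg <- list()
  for (d in space) {
    cfg[[d$name]] <- switch(d$type,
      cat = sample(d$values, 1L),
      int = sample(seq.int(d$lower, d$upper), 1L),
      num = if (d$log) exp(runif(1, log(d$lower), log(d$upper)))
            else runif(1, d$lower, d$upper))
  }
  cfg
}

# encode a configuration into [0,1]^d for the GP
.config_to_unit <- function(space, cfg) {
  vapply(space, function(d) {
    v <- cfg[[d$name]]
    switch(d$type,
      cat = if (length(d$values) == 1L) 0 else
        (match(v, d$values) - 1) / (length(d$values) - 1),
      int = if (d$upper == d$lower) 0 else (v - d$lower) / (d$upper - d$lower),
      num = if (d$log) (log(v) - log(d$lower)) / (log(d$upper) - log(d$lower))
            else (v - d$lower) / (d$upper - d$lower))
  }, numeric(1))
}

.space_is_singleton <- function(space) {
  all(vapply(space, function(d) switch(d$type,
    cat = length(d$values) == 1L,
    int = d$lower == d$upper,
    num = d$lower == d$upper), logical(1)))
}

.singleton_config <- function(space) {
  cfg <- list()
  for (d in space) cfg[[d$name]] <- switch(d$type, cat = d$values[1],
                                           int = d$lower, num = d$lower)
  cfg
}

# round-robin stratified fold assignment
.stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Mean stratified k-fold cross-validated accuracy of one algorithm
#'
#' The optimization objective: fits the algorithm with the given
#' hyperparameters on k-1 folds and scores accuracy on the held-out fold,
#' averaged over folds. Folds are stratified by class.
#'
#' @param algorithm Algorithm key.
#' @param features Feature data.frame or matrix.
#' @param labels 0/1 labels.
#' @param hp Hyperparameter list (missing entries filled from defaults).
#' @param folds Number of folds.
#' @param seed Seed for fold assignment and fits.
#' @param scaler Optional pre-fitted scaler; fitted on `features` if NULL.
#' @return Mean accuracy across folds.
#' @export
cv_accuracy <- function(algorithm, features, labels, hp = list(),
                        folds = 10L, seed = 1L, scaler = NULL) {
  X <- .feature_matrix(features)
  y <- as.integer(labels)
  hp_full <- default_hyperparameters()[[algorithm]]
  hp_full[names(hp)] <- hp
  if (algorithm %in% .scaled_algs) {
    if (is.null(scaler)) scaler <- fit_scaler(X)
    X <- apply_scaler(scaler, X)
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fold <- .stratified_folds(y, folds)
  accs <- vapply(seq_len(folds), function(f) {
    tr <- fold != f; te <- fold == f
    if (!any(te) || length(unique(y[tr])) < 2L) return(NA_real_)
    fit <- .fit_algorithm(algorithm, X[tr, , drop = FALSE], y[tr], hp_full,
                          seed + f)
    p <- .predict_algorithm(algorithm, fit, X[te, , drop = FALSE])
    mean(as.integer(p >= 0.5) == y[te])
  }, numeric(1))
  mean(accs, na.rm = TRUE)
}

# --- minimal Gaussian-process surrogate (RBF kernel, fixed lengthscale) ---

.gp_kernel <- function(A, B, lengthscale) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  exp(-0.5 * pmax(d2, 0) / lengthscale^2)
}

.gp_fit <- function(X, y, lengthscale = 0.3, noise = 1e-6) {
  mu <- mean(y); sdv <- sd(y); if (!is.finite(sdv) || sdv == 0) sdv <- 1
  ys <- (y - mu) / sdv
  K <- .gp_kernel(X, X, lengthscale) + diag(noise + 1e-8, nrow(X))
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), ys))
  list(X = X, L = L, alpha = alpha, mu = mu, sd = sdv,
       lengthscale = lengthscale)
}

.gp_predict <- function(gp, Xnew) {
  Ks <- .gp_kernel(Xnew, gp$X, gp$lengthscale)
  mean_s <- drop(Ks %*% gp$alpha)
  v <- forwardsolve(t(gp$L), t(Ks))
  var_s <- pmax(1 - colSums(v^2), 1e-12)
  list(mean = gp$mu + gp$sd * mean_s, sd = gp$sd * sqrt(var_s))
}

.expected_improvement <- function(mean_s, sd_s, best) {
  z <- (mean_s - best) / sd_s
  (mean_s - best) * stats::pnorm(z) + sd_s * stats::dnorm(z)
}

#' Optimize hyperparameters for one algorithm
#'
#' Sequential model-based optimization with a Gaussian-process surrogate:
#' an initial random design is evaluated, then each further evaluation
#' maximizes expected improvement of the surrogate over random candidate
#' configurations, for `iterations` objective evaluations in total. The
#' objective is mean stratified k-fold CV accuracy ([cv_accuracy()]). A
#' random-search fallback over the same space and budget is selected with
#' `method = "random"`.
#'
#' @inheritParams cv_accuracy
#' @param space Search space from [hyperparameter_space()] (default for
#'   the algorithm if NULL).
#' @param iterations Total number of objective evaluations (default 10).
#' @param method `"gp"` (Gaussian-process surrogate) or `"random"`.
#' @return List: `best_config` (named hyperparameter list), `best_score`
#'   (CV accuracy), `history` (data.frame of evaluated configurations and
#'   scores).
#' @export
optimize_hyperparameters <- function(algorithm, features, labels,
                                     space = NULL, iterations = 10L,
                                     folds = 10L, seed = 1L,
                                     method = c("gp", "random"),
                                     scaler = NULL) {
  method <- match.arg(method)
  y <- as.integer(labels)
  if (length(unique(y)) < 2L)
    stop("optimize_hyperparameters(): labels contain a single class")
  if (is.null(space)) space <- hyperparameter_space(algorithm)
  if (.space_is_singleton(space)) {
    cfg <- .singleton_config(space)
    score <- cv_accuracy(algorithm, features, y, cfg, folds, seed, scaler)
    return(list(best_config = cfg, best_score = score,
                history = data.frame(eval = 1L, score = score)))
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  configs <- list(); scores <- numeric(0)
  n_init <- if (method == "random") iterations else
    min(max(3L, ceiling(iterations / 3)), iterations)
  evaluate <- function(cfg, i) {
    cv_accuracy(algorithm, features, y, cfg, folds,
                seed = (seed + 31L * i) %% .Machine$integer.max,
                scaler = scaler)
  }
  for (i in seq_len(n_init)) {
    configs[[i]] <- .sample_config(space)
    scores[i] <- evaluate(configs[[i]], i)
  }
  unit_matrix <- function(cfgs) {
    m <- vapply(cfgs, function(cfg) .config_to_unit(space, cfg),
                numeric(length(space)))
    if (is.null(dim(m))) matrix(m, ncol = 1L) else t(m)
  }
  i <- n_init
  while (i < iterations) {
    i <- i + 1L
    gp <- .gp_fit(unit_matrix(configs), scores)
    cands <- replicate(200L, .sample_config(space), simplify = FALSE)
    Uc <- unit_matrix(cands)
    pr <- .gp_predict(gp, Uc)
    ei <- .expected_improvement(pr$mean, pr$sd, max(scores))
    configs[[i]] <- cands[[which.max(ei)]]
    scores[i] <- evaluate(configs[[i]], i)
  }
  best <- which.max(scores)
  list(best_config = configs[[best]], best_score = scores[best],
       history = data.frame(eval = seq_along(scores), score = scores))
}
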