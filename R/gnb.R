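# Gaussian naive Bayes with variance smoothing: per-class feature means
# and variances, each variance floored by var_smoothing times the largest
# overall feature variance (keeps degenerate/constant features usable).

#' Fit a Gaussian naive Bayes classifier
#'
#' @param X Numeric matrix (n x d).
#' @param y 0/1 labels.
#' @param var_smoothing Fraction of the largest per-feature variance added
#'   to every class variance for numerical stability.
#' @return Object of class `operon_gnb`.
#' @keywords internal
gnb_fit <- function(X, y, var_smoothing = 1e-9) {
  X <- as.matrix(X); y <- as.integer(y)
  stopifnot(all(y %in% 0:1), length(unique(y)) >= 1L)
  vars <- apply(X, 2L, function(v) mean((v - mean(v))^2))
  eps <- var_smoothing * max(vars, 1e-12)
  cls <- sort(unique(y))
  mu <- sig <- matrix(0, length(cls), ncol(X),
                      dimnames = list(as.character(cls), colnames(X)))
  prior <- numeric(length(cls)); names(prior) <- as.character(cls)
  for (i in seq_along(cls)) {
    Xi <- X[y == cls[i], , drop = FALSE]
    mu[i, ] <- colMeans(Xi)
    sig[i, ] <- apply(Xi, 2L, function(v) mean((v - mean(v))^2)) + eps
    prior[i] <- nrow(Xi) / nrow(X)
  }
  structure(list(classes = cls, mu = mu, sigma = sig, prior = prior),
            class = "operon_gnb")
}

#' @rdname gnb_fit
#' @param model A fitted `operon_gnb`.
#' @keywords internal
gnb_predict <- function(model, X) {
  X <- as.matrix(X)
  loglik <- sapply(seq_along(model$classes), function(i) {
    mu <- model$mu[i, ]; s2 <- model$sigma[i, ]
    rowSums(sweep(-0.5 * sweep(X, 2L, mu)^2, 2L, s2, "/") -
              matrix(0.5 * log(2 * pi * s2), nrow(X), ncol(X), byrow = TRUE)) +
      log(model$prior[i])
  })
  loglik <- matrix(loglik, nrow = nrow(X))
  if (length(model$classes) == 1L)
    return(rep(as.numeric(model$classes == 1L), nrow(X)))
  # normalized posterior of class "1"
  m <- apply(loglik, 1L, max)
  post <- exp(loglik - m)
  post[, which(model$classes == 1L)] / rowSums(post)
}
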