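# Small multilayer perceptron for binary classification: rectified-linear
# hidden layers (1-3), sigmoid output, cross-entropy loss with L2 weight
# penalty, trained full-batch with the adam optimizer. Deterministic given
# the seed.

.relu <- function(z) pmax(z, 0)

#' Fit a multilayer perceptron classifier
#'
#' @param X Numeric matrix (n x d) of (scaled) features.
#' @param y 0/1 numeric labels of length n.
#' @param hidden Integer vector of hidden-layer sizes (length 1-3).
#' @param alpha L2 penalty on the weights (as a rate per sample).
#' @param max_iter Number of full-batch adam epochs.
#' @param learning_rate Adam step size.
#' @param seed Seed for the weight initialization.
#' @return Object of class `operon_mlp`.
#' @keywords internal
mlp_fit <- function(X, y, hidden = 32L, alpha = 1e-4, max_iter = 300L,
                    learning_rate = 1e-3, seed = 1L) {
  X <- as.matrix(X); y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)))
  n <- nrow(X)
  sizes <- c(ncol(X), as.integer(hidden), 1L)
  nl <- length(sizes) - 1L
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  W <- vector("list", nl); b <- vector("list", nl)
  for (l in seq_len(nl)) {
    # He-style initialization for relu layers
    W[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1L],
                           sd = sqrt(2 / sizes[l])),
                     sizes[l], sizes[l + 1L])
    b[[l]] <- numeric(sizes[l + 1L])
  }
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(x) x * 0); vb <- mb
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (t in seq_len(max_iter)) {
    # forward
    A <- vector("list", nl + 1L)
    A[[1L]] <- X
    for (l in seq_len(nl - 1L))
      A[[l + 1L]] <- .relu(sweep(A[[l]] %*% W[[l]], 2L, b[[l]], "+"))
    logits <- drop(A[[nl]] %*% W[[nl]]) + b[[nl]]
    p <- plogis(logits)
    # backward (cross-entropy + L2)
    delta <- matrix((p - y) / n, ncol = 1L)
    for (l in rev(seq_len(nl))) {
      gW <- crossprod(A[[l]], delta) + (alpha / n) * W[[l]]
      gb <- colSums(delta)
      if (l > 1L)
        delta <- (delta %*% t(W[[l]])) * (A[[l]] > 0)
      mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gW
      vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gW^2
      mb[[l]] <- b1 * mb[[l]] + (1 - b1) * gb
      vb[[l]] <- b2 * vb[[l]] + (1 - b2) * gb^2
      corr1 <- 1 - b1^t; corr2 <- 1 - b2^t
      W[[l]] <- W[[l]] - learning_rate * (mW[[l]] / corr1) /
        (sqrt(vW[[l]] / corr2) + eps)
      b[[l]] <- b[[l]] - learning_rate * (mb[[l]] / corr1) /
        (sqrt(vb[[l]] / corr2) + eps)
    }
  }
  structure(list(W = W, b = b, sizes = sizes), class = "operon_mlp")
}

#' @rdname mlp_fit
#' @param model A fitted `operon_mlp`.
#' @keywords internal
mlp_predict <- function(model, X) {
  X <- as.matrix(X)
  nl <- length(model$W)
  A <- X
  for (l in seq_len(nl - 1L))
    A <- .relu(sweep(A %*% model$W[[l]], 2L, model$b[[l]], "+"))
  plogis(drop(A %*% model$W[[nl]]) + model$b[[nl]])
}

# save/restore global RNG state so seeded fits don't perturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv())
}
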