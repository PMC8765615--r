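#' Kruskal-Wallis rank test on coverage windows
#'
#' Computes the Kruskal-Wallis H statistic with midranks for ties and the
#' standard tie-correction divisor, and a p-value from the chi-square upper
#' tail with `k - 1` degrees of freedom. This is the featurization primitive
#' of the method: coverage vectors from the two gene windows and the
#' intergenic window are compared pairwise and three-way, and the statistic
#' and p-value of each comparison become model features.
#'
#' When every observation across all groups is identical the rank variance
#' (and the tie-correction divisor) is zero; that degenerate case is defined
#' as H = 0, p = 1, i.e. "no evidence the windows differ".
#'
#' @param groups List of two or more non-empty numeric vectors.
#' @return An object of class `kw_result`: list with `H` (statistic, >= 0),
#'   `p` (p-value in (0, 1]), `k` (number of groups), `n` (total
#'   observations).
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
#' kruskal_wallis(list(c(5, 5, 5), c(5, 5, 5)))  # degenerate: H = 0, p = 1
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("kruskal_wallis() needs a list of at least 2 groups")
  sizes <- lengths(groups)
  if (any(sizes == 0L))
    stop("kruskal_wallis(): empty group (group ",
         paste(which(sizes == 0L), collapse = ", "), ")")
  x <- as.numeric(unlist(groups, use.names = FALSE))
  if (anyNA(x)) stop("kruskal_wallis(): NA observations")
  n <- length(x)
  k <- length(groups)
  if (n < 3L) stop("kruskal_wallis(): fewer than 3 total observations")

  if (all(x == x[1L]))
    return(structure(list(H = 0, p = 1, k = k, n = n), class = "kw_result"))

  g <- rep.int(seq_len(k), sizes)
  r <- rank(x)  # midranks
  rank_sums <- vapply(split(r, g), sum, numeric(1))
  H <- 12 / (n * (n + 1)) * sum(rank_sums^2 / sizes) - 3 * (n + 1)
  tie_counts <- table(x)
  tie_div <- 1 - sum(tie_counts^3 - tie_counts) / (n^3 - n)
  H <- H / tie_div
  H <- max(H, 0)  # guard tiny negative rounding
  p <- pchisq(H, df = k - 1, lower.tail = FALSE)
  p <- min(max(p, 1e-320), 1)
  structure(list(H = H, p = p, k = k, n = n), class = "kw_result")
}

#' @export
print.kw_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.6g, df = %d, p = %.4g (n = %d)\n",
              x$H, x$k - 1L, x$p, x$n))
  invisible(x)
}
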