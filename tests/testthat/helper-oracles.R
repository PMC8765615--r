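# Independent brute-force oracles, deliberately implemented by a different
# route than the package code (counting-based midranks, group-mean form of
# the rank statistic, explicit permutation).

# midrank of each value by counting: (# smaller) + (# equal + 1) / 2
oracle_midranks <- function(x) {
  vapply(seq_along(x),
         function(i) sum(x < x[i]) + (sum(x == x[i]) + 1) / 2,
         numeric(1))
}

# H = 12/(N(N+1)) * sum n_i (Rbar_i - (N+1)/2)^2, tie-corrected
oracle_kw <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  N <- length(x)
  ni <- lengths(groups)
  g <- rep(seq_along(groups), ni)
  r <- oracle_midranks(x)
  rbar <- tapply(r, g, mean)
  H0 <- 12 / (N * (N + 1)) * sum(ni * (rbar - (N + 1) / 2)^2)
  tt <- table(x)
  D <- 1 - sum(tt^3 - tt) / (N^3 - N)
  if (D <= 0) return(list(H = 0, p = 1))
  H <- H0 / D
  list(H = H, p = stats::pchisq(H, length(groups) - 1, lower.tail = FALSE))
}

# Monte-Carlo permutation p-value of the observed H
oracle_perm_p <- function(groups, B = 10000) {
  obs <- oracle_kw(groups)$H
  x <- unlist(groups, use.names = FALSE)
  ni <- lengths(groups)
  g <- rep(seq_along(ni), ni)
  hits <- 0L
  for (b in seq_len(B)) {
    xs <- sample(x)
    hits <- hits + (oracle_kw(split(xs, g))$H >= obs - 1e-12)
  }
  hits / B
}

# exact permutation p for two groups: enumerate all assignments
oracle_exact_perm_p_2groups <- function(g1, g2) {
  x <- c(g1, g2)
  obs <- oracle_kw(list(g1, g2))$H
  combs <- utils::combn(length(x), length(g1))
  hits <- apply(combs, 2, function(idx)
    oracle_kw(list(x[idx], x[-idx]))$H >= obs - 1e-12)
  mean(hits)
}

# random group sets with ties for the equivalence sweep
random_group_set <- function() {
  k <- sample(2:4, 1)
  groups <- lapply(seq_len(k), function(i)
    sample(0:100, sample(1:60, 1), replace = TRUE))
  while (sum(lengths(groups)) < 3 ||
           length(unique(unlist(groups))) < 2) {
    groups <- lapply(seq_len(k), function(i)
      sample(0:100, sample(1:60, 1), replace = TRUE))
  }
  groups
}
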