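# Recall/specificity, ROC/AUC, bootstrap CIs, split validation, Spearman
# diagnostics.

toy_scored <- function(call, label, prefix = "p") {
  list(calls = data.frame(pair_id = paste0(prefix, seq_along(call)),
                          call = call),
       labels = data.frame(geneA_id = paste0(prefix, seq_along(label)),
                           geneB_id = "x", label = label))
}
# labels keyed by pair_id directly
toy_scored_pid <- function(call, label) {
  list(calls = data.frame(pair_id = paste0("p", seq_along(call)), call = call),
       labels = data.frame(pair_id = paste0("p", seq_along(label)),
                           label = label))
}

test_that("confusion metrics follow the recall/specificity formulas", {
  s <- toy_scored_pid(rep(c(1, 0, 1, 0), c(8, 2, 3, 7)),
                      rep(c(1, 1, 0, 0), c(8, 2, 3, 7)))
  m <- confusion_metrics(s$calls, s$labels)
  expect_equal(m$recall, 0.8)
  expect_equal(m$specificity, 0.7)
  expect_equal(m$n_pairs, 20L)

  perfect <- toy_scored_pid(c(1, 1, 0, 0), c(1, 1, 0, 0))
  mp <- confusion_metrics(perfect$calls, perfect$labels)
  expect_equal(mp$recall, 1)
  expect_equal(mp$specificity, 1)

  allpos <- toy_scored_pid(c(1, 0, 1), c(1, 1, 1))
  expect_true(is.na(confusion_metrics(allpos$calls, allpos$labels)$specificity))

  disjoint <- list(calls = data.frame(pair_id = "a|b", call = 1),
                   labels = data.frame(geneA_id = "c", geneB_id = "d",
                                       label = 1))
  expect_error(confusion_metrics(disjoint$calls, disjoint$labels),
               "no overlap")
})

test_that("labels join in either gene orientation", {
  calls <- data.frame(pair_id = c("g2|g1", "g3|g4"), call = c(1, 0))
  labels <- data.frame(geneA_id = c("g1", "g3"), geneB_id = c("g2", "g4"),
                       label = c(1L, 0L))
  m <- confusion_metrics(calls, labels)
  expect_equal(m$n_pairs, 2L)
  expect_equal(m$recall, 1)
  expect_equal(m$specificity, 1)
})

test_that("ROC/AUC: perfect ranking, binary-call polyline, random baseline", {
  y <- rep(c(1, 0), each = 50)
  perfect <- roc_auc(c(runif(50, 0.6, 1), runif(50, 0, 0.4)), y)
  expect_equal(perfect$auc, 1)

  # binary call with sens 0.9, spec 0.8 -> (sens + spec)/2
  call <- c(rep(1, 45), rep(0, 5), rep(1, 10), rep(0, 40))
  bin <- roc_auc(call, y)
  expect_equal(bin$auc, 0.85)

  set.seed(10)
  n <- 10000
  yr <- rep(c(0, 1), n / 2)
  r <- roc_auc(runif(n), yr)
  sigma <- sqrt((n / 2 + n / 2 + 1) / (12 * (n / 2)^2))
  expect_lt(abs(r$auc - 0.5), 3 * sigma)

  expect_error(roc_auc(runif(5), rep(1, 5)), "single class")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(3)
  y <- rbinom(300, 1, 0.45)
  sc <- runif(300) + 0.4 * y
  ours <- roc_auc(sc, y)$auc
  ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(y, sc,
                                                         direction = "<"))))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("bootstrap CIs are seeded, degenerate on constant metrics, and tighten with fraction", {
  s <- toy_scored_pid(rep(1, 40), rep(1, 40))  # recall always 1
  b <- bootstrap_ci("recall", s$calls, s$labels, n_boot = 50, seed = 4)
  expect_equal(b$mean, 1)
  expect_equal(b$upper - b$lower, 0)

  set.seed(77)
  s2 <- toy_scored_pid(rbinom(200, 1, 0.6), rbinom(200, 1, 0.5))
  b1 <- bootstrap_ci("recall", s2$calls, s2$labels, n_boot = 100, seed = 9)
  b2 <- bootstrap_ci("recall", s2$calls, s2$labels, n_boot = 100, seed = 9)
  expect_identical(b1, b2)

  widths <- vapply(1:5, function(sd) {
    w01 <- with(bootstrap_ci("recall", s2$calls, s2$labels, 100, 0.1, sd),
                upper - lower)
    w10 <- with(bootstrap_ci("recall", s2$calls, s2$labels, 100, 1.0, sd),
                upper - lower)
    w01 - w10
  }, numeric(1))
  expect_gt(mean(widths), 0)  # larger subsamples -> tighter CIs on average

  allpos <- toy_scored_pid(rep(1, 12), rep(1, 12))
  expect_error(bootstrap_ci("specificity", allpos$calls, allpos$labels,
                            n_boot = 20, seed = 1),
               "undefined")
})

test_that("one split equals a single train/test evaluation", {
  bm <- small_benchmark(seed = 41, n_genes = 250)
  sv <- split_validate(bm$features, n_splits = 1, seed = 5)
  expect_equal(nrow(sv$per_algorithm), 6L)
  expect_identical(sv$per_algorithm[c("recall", "specificity")],
                   sv$splits[[1]][c("recall", "specificity")])
  expect_true(all(sv$per_algorithm$recall >= 0 &
                    sv$per_algorithm$recall <= 1))
})

test_that("shuffled labels push recall to the positive-call rate", {
  bm <- small_benchmark(seed = 43, n_genes = 250)
  ft <- bm$features
  set.seed(1)
  ft$label <- sample(ft$label)
  # keep pair-level consistency of labels within replicates
  lab <- tapply(ft$label, ft$pair_id, function(v) v[1])
  ft$label <- as.integer(lab[ft$pair_id])
  sv <- split_validate(ft, n_splits = 2, seed = 31)
  # with no true signal, recall ~ positive-call rate; check loosely per alg
  for (i in seq_len(nrow(sv$per_algorithm))) {
    expect_lt(abs(sv$per_algorithm$recall[i] -
                    (1 - sv$per_algorithm$specificity[i])), 0.25)
  }
})

test_that("Spearman diagnostics recover signs and handle degenerate features", {
  set.seed(2)
  ft <- random_feature_table(100)
  ft$lenA <- ft$label          # rho = 1
  ft$lenB <- -ft$label         # rho = -1
  ft$strand_match <- 1L        # constant -> NA
  rho <- feature_label_spearman(ft)
  expect_equal(unname(rho["lenA"]), 1)
  expect_equal(unname(rho["lenB"]), -1)
  expect_true(is.na(rho["strand_match"]))

  set.seed(3)
  big <- random_feature_table(10000)
  rho_null <- feature_label_spearman(big)["kw_AB_H"]
  expect_lt(abs(rho_null), 3 / sqrt(10000))
})
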