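# Vote tallying, replicate consensus and operon chaining.

make_calls <- function(calls, pair_id = "p1", sample_id = "s1") {
  df <- data.frame(pair_id = pair_id, sample_id = sample_id,
                   stringsAsFactors = FALSE)
  for (i in seq_along(algorithm_keys())) {
    df[[paste0(algorithm_keys()[i], "_prob")]] <-
      ifelse(is.na(calls[i]), 0.5, as.numeric(calls[i]))
    df[[paste0(algorithm_keys()[i], "_call")]] <- calls[i]
  }
  df
}

test_that("vote tallies and thresholded calls follow the k-of-6 rule", {
  tv <- tally_votes(make_calls(c(1L, 1L, 1L, 0L, 0L, 0L)))
  expect_equal(tv$votes, 3L)
  expect_equal(tv$call_3, 1L)
  expect_equal(tv$call_4, 0L)

  expect_equal(tally_votes(make_calls(rep(0L, 6)))$votes, 0L)
  tv6 <- tally_votes(make_calls(rep(1L, 6)))
  expect_equal(tv6$votes, 6L)
  expect_true(all(unlist(tv6[paste0("call_", 1:6)]) == 1L))

  # call(k) non-increasing in k, always
  set.seed(61)
  preds <- random_predictions(50)
  tv <- tally_votes(preds)
  calls <- as.matrix(tv[paste0("call_", 1:6)])
  expect_true(all(calls[, -1] <= calls[, -6]))

  expect_error(tally_votes(preds[, setdiff(names(preds), "LR_call")]),
               "call column")
})

test_that("replicate consensus keeps agreement, abstains on conflict, drops singletons", {
  p <- rbind(make_calls(c(1L, 1L, 0L, 0L, 1L, 0L), "pA", "s1"),
             make_calls(c(1L, 0L, 0L, 1L, 1L, 0L), "pA", "s2"),
             make_calls(rep(1L, 6), "pB", "s1"))
  cons <- replicate_consensus(p, min_replicates = 2)
  expect_equal(cons$pair_id, "pA")  # pB seen once -> dropped
  expect_equal(cons$LR_call, 1L)    # (1,1) agree
  expect_true(is.na(cons$SVM_call)) # (1,0) abstain
  expect_equal(cons$RF_call, 0L)    # (0,0) agree
  tv <- tally_votes(cons)
  expect_equal(tv$votes, 2L)        # LR + MLP

  # consensus never increases the number of voting algorithms
  set.seed(8)
  preds <- rbind(random_predictions(40, "s1"), random_predictions(40, "s2"))
  cons <- replicate_consensus(preds, min_replicates = 2)
  per_sample <- tally_votes(preds)
  for (i in seq_len(nrow(cons))) {
    votes_each <- per_sample$votes[per_sample$pair_id == cons$pair_id[i]]
    voting <- sum(!is.na(cons[i, paste0(algorithm_keys(), "_call")]))
    expect_lte(voting, 6L)
    expect_lte(tally_votes(cons[i, ])$votes, max(votes_each))
  }
})

test_that("majority consensus mode needs a strict majority", {
  p <- rbind(make_calls(c(1L, 1L, 0L, 0L, 1L, 0L), "pA", "s1"),
             make_calls(c(1L, 0L, 0L, 1L, 1L, 0L), "pA", "s2"),
             make_calls(c(1L, 0L, 1L, 1L, 1L, 0L), "pA", "s3"))
  cons <- replicate_consensus(p, min_replicates = 3, mode = "majority")
  expect_equal(cons$LR_call, 1L)   # (1,1,1)
  expect_equal(cons$SVM_call, 0L)  # (1,0,0) -> majority 0
  expect_equal(cons$XGB_call, 1L)  # (0,1,1) -> majority 1
  expect_equal(cons$GNB_call, 0L)  # (0,0,0)
  # an even split is a tie: abstain
  tie <- replicate_consensus(p[1:2, ], min_replicates = 2, mode = "majority")
  expect_true(is.na(tie$SVM_call))
  expect_equal(tie$LR_call, 1L)
})

test_that("operon chaining merges maximal runs and breaks correctly", {
  genes <- toy_genes(list("g1", "chr1", 1, 100, "+"),
                     list("g2", "chr1", 120, 220, "+"),
                     list("g3", "chr1", 240, 340, "+"),
                     list("g4", "chr1", 360, 460, "+"))
  chain_of <- function(pos_pairs) {
    calls <- data.frame(pair_id = c("g1|g2", "g2|g3", "g3|g4"),
                        call = as.integer(c("g1|g2", "g2|g3", "g3|g4") %in%
                                            pos_pairs))
    string_operons(calls, genes)
  }
  ops <- chain_of(c("g1|g2", "g2|g3"))
  expect_equal(nrow(ops), 1L)
  expect_equal(ops$genes, "g1,g2,g3")
  expect_equal(ops$n_genes, 3L)

  expect_equal(nrow(chain_of(character(0))), 0L)

  two <- chain_of(c("g1|g2", "g3|g4"))
  expect_equal(two$genes, c("g1,g2", "g3,g4"))

  all4 <- chain_of(c("g1|g2", "g2|g3", "g3|g4"))
  expect_equal(all4$genes, "g1,g2,g3,g4")
})

test_that("opposite-strand pairs break chains and minus chains list 5'->3'", {
  genes <- toy_genes(list("g1", "chr1", 1, 100, "+"),
                     list("g2", "chr1", 120, 220, "+"),
                     list("g3", "chr1", 240, 340, "-"),
                     list("g4", "chr1", 360, 460, "-"),
                     list("g5", "chr1", 480, 580, "-"))
  # votes interface: threshold 3
  calls <- data.frame(
    pair_id = c("g1|g2", "g3|g2", "g4|g3", "g5|g4"),
    votes = c(6L, 6L, 4L, 3L))
  ops <- string_operons(calls, genes, threshold = 3)
  # g2|g3 is opposite-strand: breaks regardless of votes
  expect_equal(nrow(ops), 2L)
  plus <- ops[ops$strand == "+", ]
  minus <- ops[ops$strand == "-", ]
  expect_equal(plus$genes, "g1,g2")
  expect_equal(minus$genes, "g5,g4,g3")  # transcription order, right to left
  # raising the threshold trims the weaker link of the minus chain
  ops4 <- string_operons(calls, genes, threshold = 4)
  expect_equal(sort(ops4$genes), sort(c("g1,g2", "g4,g3")))
  ops5 <- string_operons(calls, genes, threshold = 5)
  expect_equal(ops5$genes, "g1,g2")
})

test_that("chains partition the positive same-strand pairs", {
  set.seed(19)
  truth <- simulate_genome(simulation_config(n_genes = 120, seed = 5))
  pairs <- enumerate_adjacent_pairs(truth$genes)
  calls <- data.frame(pair_id = pairs$pair_id,
                      call = rbinom(nrow(pairs), 1, 0.5))
  ops <- string_operons(calls, truth$genes)
  chain_genes <- strsplit(ops$genes, ",")
  # every positive same-strand pair appears in exactly one chain
  pos <- pairs[pairs$strand_match == 1 &
                 pairs$pair_id %in% calls$pair_id[calls$call == 1], ]
  hits <- vapply(seq_len(nrow(pos)), function(i) {
    sum(vapply(chain_genes, function(g) {
      ia <- match(pos$geneA_id[i], g); ib <- match(pos$geneB_id[i], g)
      !is.na(ia) && !is.na(ib) && abs(ia - ib) == 1
    }, logical(1)))
  }, numeric(1))
  expect_true(all(hits == 1))
  # chain members are consecutive genes on one strand
  for (g in chain_genes) expect_gte(length(g), 2L)
})
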