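# Pair enumeration, expression filter, window extraction and feature
# assembly. The positional coverage track (depth == genomic position)
# makes extracted windows directly observable.

test_that("plus-strand adjacent pair gets the specified geometry and windows", {
  genes <- toy_genes(list("g1", "chr1", 101, 400, "+"),
                     list("g2", "chr1", 451, 800, "+"))
  pairs <- enumerate_adjacent_pairs(genes)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$geneA_id, "g1")
  expect_equal(pairs$geneB_id, "g2")
  expect_equal(pairs$intergenic_start, 401L)
  expect_equal(pairs$intergenic_end, 450L)
  expect_equal(pairs$intergenic_length, 50L)
  expect_equal(pairs$strand_match, 1L)

  w <- extract_windows(pairs[1, ], positional_track(900))
  expect_equal(w$covA, as.numeric(351:400))
  expect_equal(w$covI, as.numeric(401:450))
  expect_equal(w$covB, as.numeric(451:500))
})

test_that("minus-strand pair is transcription-ordered: A is the right gene", {
  genes <- toy_genes(list("g1", "chr1", 100, 400, "-"),
                     list("g2", "chr1", 451, 800, "-"))
  pairs <- enumerate_adjacent_pairs(genes)
  expect_equal(pairs$geneA_id, "g2")  # 5'-most in transcription
  expect_equal(pairs$geneB_id, "g1")
  expect_equal(pairs$intergenic_length, 50L)

  w <- extract_windows(pairs[1, ], positional_track(900))
  expect_equal(w$covA, as.numeric(451:500))  # 3' end of g2 = genomic left
  expect_equal(w$covB, as.numeric(351:400))  # 5' end of g1 = genomic right
  expect_equal(w$covI, as.numeric(401:450))
})

test_that("window extraction is mirror-symmetric between the strands", {
  # a minus/minus pair must yield the same windows as its reverse-
  # complemented (mirrored) plus/plus layout with reversed coverage
  set.seed(31)
  L <- 2000L
  depth <- as.numeric(sample(0:50, L, replace = TRUE))
  for (i in 1:10) {
    aLen <- sample(1:120, 1); bLen <- sample(1:120, 1)
    gap <- sample(1:120, 1)
    s1 <- sample(1:(L - aLen - bLen - gap - 10), 1)
    g_minus <- toy_genes(list("x", "c", s1, s1 + aLen - 1, "-"),
                         list("y", "c", s1 + aLen + gap,
                              s1 + aLen + gap + bLen - 1, "-"))
    p_minus <- enumerate_adjacent_pairs(g_minus)
    w_minus <- extract_windows(p_minus,
                               coverage_track("s", list(c = depth)))
    mirror <- function(pos) L + 1L - pos
    g_plus <- toy_genes(
      list("y", "c", mirror(g_minus$end[2]), mirror(g_minus$start[2]), "+"),
      list("x", "c", mirror(g_minus$end[1]), mirror(g_minus$start[1]), "+"))
    p_plus <- enumerate_adjacent_pairs(g_plus)
    w_plus <- extract_windows(p_plus,
                              coverage_track("s", list(c = rev(depth))))
    expect_equal(rev(w_plus$covA), w_minus$covA)
    expect_equal(rev(w_plus$covB), w_minus$covB)
    # the central intergenic window is left-biased by construction, so it
    # is mirror-symmetric only when the trimmed length is even
    if (gap <= 50 || (gap - 50) %% 2 == 0)
      expect_equal(rev(w_plus$covI), w_minus$covI)
  }
})

test_that("overlapping and short-intergenic pairs follow the boundary rules", {
  ov <- toy_genes(list("g1", "chr1", 1, 100, "+"),
                  list("g2", "chr1", 95, 200, "+"))
  pairs <- enumerate_adjacent_pairs(ov)
  expect_equal(pairs$intergenic_length, -6L)  # 95 - 100 - 1
  w <- extract_windows(pairs[1, ], positional_track(300))
  expect_equal(w$covI, 100)  # single base at the left gene's genomic end

  short <- toy_genes(list("g1", "chr1", 101, 400, "+"),
                     list("g2", "chr1", 408, 500, "+"))
  pairs <- enumerate_adjacent_pairs(short)
  expect_equal(pairs$intergenic_length, 7L)
  w <- extract_windows(pairs[1, ], positional_track(600))
  expect_equal(w$covI, as.numeric(401:407))  # whole short region
})

test_that("central intergenic window is left-biased for long regions", {
  genes <- toy_genes(list("g1", "chr1", 1, 100, "+"),
                     list("g2", "chr1", 224, 400, "+"))
  pairs <- enumerate_adjacent_pairs(genes)   # intergenic 101..223, L = 123
  w <- extract_windows(pairs[1, ], positional_track(500))
  expect_equal(w$covI, as.numeric((101 + 36):(101 + 36 + 49)))  # floor(73/2)
})

test_that("window lengths satisfy the invariants over random geometries", {
  set.seed(77)
  for (i in 1:60) {
    aLen <- sample(c(1, 2, sample(1:200, 1)), 1)
    bLen <- sample(c(1, sample(1:200, 1)), 1)
    gap <- sample(-10:200, 1)  # negative: overlapping genes
    gap <- max(gap, -min(aLen, bLen) + 1)  # keep both starts ordered
    s1 <- 50
    aEnd <- s1 + aLen - 1
    bStart <- aEnd + gap + 1
    strands <- sample(list(c("+", "+"), c("-", "-"), c("+", "-"), c("-", "+")), 1)[[1]]
    genes <- toy_genes(list("a", "c", s1, aEnd, strands[1]),
                       list("b", "c", bStart, bStart + bLen - 1, strands[2]))
    pairs <- enumerate_adjacent_pairs(genes)
    w <- extract_windows(pairs[1, ], positional_track(1200, seqid = "c"))
    expect_equal(length(w$covA), min(50, pairs$lenA))
    expect_equal(length(w$covB), min(50, pairs$lenB))
    expect_equal(length(w$covI), min(50, max(1, pairs$intergenic_length)))
    expect_true(all(c(w$covA, w$covI, w$covB) >= 0))
  }
})

test_that("expression filter keeps a pair iff one gene mean reaches the cutoff", {
  genes <- toy_genes(list("g1", "chr1", 1, 100, "+"),
                     list("g2", "chr1", 151, 250, "+"))
  pairs <- enumerate_adjacent_pairs(genes)
  mk_track <- function(mA, mB) {
    d <- numeric(300); d[1:100] <- mA; d[151:250] <- mB
    coverage_track("s", list(chr1 = d))
  }
  expect_equal(nrow(filter_expressed(pairs, mk_track(12, 3))), 1L)
  expect_equal(nrow(filter_expressed(pairs, mk_track(3, 12))), 1L)
  expect_equal(nrow(filter_expressed(pairs, mk_track(9.9, 9.9))), 0L)
  expect_equal(nrow(filter_expressed(pairs, mk_track(10, 0))), 1L)  # >= rule
  expect_equal(nrow(filter_expressed(pairs, mk_track(0, 0))), 0L)
})

test_that("same-strand-only flag and out-of-bounds windows behave", {
  genes <- toy_genes(list("g1", "chr1", 1, 100, "+"),
                     list("g2", "chr1", 151, 250, "-"),
                     list("g3", "chr1", 300, 380, "-"))
  all_pairs <- enumerate_adjacent_pairs(genes)
  expect_equal(nrow(all_pairs), 2L)
  ss <- enumerate_adjacent_pairs(genes, same_strand_only = TRUE)
  expect_equal(ss$strand_match, 1L)
  expect_equal(nrow(ss), 1L)
  expect_error(extract_windows(all_pairs[2, ], positional_track(200)),
               "outside coverage bounds")
  expect_error(extract_windows(all_pairs[1, ],
                               positional_track(400, seqid = "other")),
               "absent from coverage")
})

test_that("feature assembly composes the standalone Kruskal-Wallis results", {
  genes <- toy_genes(list("g1", "chr1", 101, 400, "+"),
                     list("g2", "chr1", 451, 800, "+"))
  pair <- enumerate_adjacent_pairs(genes)[1, ]
  set.seed(5)
  depth <- as.numeric(sample(0:40, 900, replace = TRUE))
  track <- coverage_track("s7", list(chr1 = depth))
  w <- extract_windows(pair, track)
  fv <- compute_features(pair, w, "s7", label = 1)
  expect_equal(fv$sample_id, "s7")
  expect_equal(fv$label, 1L)
  expect_equal(fv$lenA, 300L)
  expect_equal(fv$intergenic_length, 50L)
  kw_ai <- kruskal_wallis(list(w$covA, w$covI))
  kw_aib <- kruskal_wallis(list(w$covA, w$covI, w$covB))
  expect_equal(fv$kw_AI_H, kw_ai$H)
  expect_equal(fv$kw_AI_logp, log10(kw_ai$p))
  expect_equal(fv$kw_AIB_H, kw_aib$H)

  # identical constant coverage in all three windows: degenerate features
  fc <- compute_features(pair, extract_windows(pair, constant_track(900, 8)),
                         "s8")
  kw_cols <- grep("^kw_", operon_feature_names(), value = TRUE)
  expect_true(all(unlist(fc[kw_cols]) == 0))

  # constant depth shifts never change the rank features
  w_shift <- lapply(w, function(v) v + 100)
  fv_shift <- compute_features(pair, structure(w_shift, class = "window_sample"),
                               "s7", label = 1)
  expect_equal(fv_shift[kw_cols], fv[kw_cols])
})

test_that("log10 p features are clipped into [-300, 0]", {
  bm <- small_benchmark(seed = 19, n_genes = 120)
  kw_logp <- grep("_logp$", names(bm$features), value = TRUE)
  for (col in kw_logp) {
    expect_true(all(bm$features[[col]] <= 0))
    expect_true(all(bm$features[[col]] >= -300))
  }
})
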