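# Shared fixtures, built in code at test time.

# gene table builder (already sorted by caller or not -- readers sort)
toy_genes <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(gene_id = r[[1]], seqid = r[[2]],
               start = as.integer(r[[3]]), end = as.integer(r[[4]]),
               strand = r[[5]], stringsAsFactors = FALSE)))
  df$length <- df$end - df$start + 1L
  df[order(df$seqid, df$start), ]
}

# coverage track whose depth equals the genomic position (distinct
# everywhere: window extraction becomes directly observable)
positional_track <- function(len, seqid = "chr1", sample_id = "s1") {
  coverage_track(sample_id, stats::setNames(list(as.numeric(seq_len(len))),
                                            seqid))
}

constant_track <- function(len, depth, seqid = "chr1", sample_id = "s1") {
  coverage_track(sample_id, stats::setNames(list(rep(as.numeric(depth), len)),
                                            seqid))
}

# write a small GFF3 file from raw lines
write_gff3_text <- function(lines, path = tempfile(fileext = ".gff3")) {
  writeLines(c("##gff-version 3", lines), path)
  path
}

# random labelled feature table (valid ranges, used for IO round-trips)
random_feature_table <- function(n, with_label = TRUE) {
  df <- data.frame(
    pair_id = sprintf("gA%03d|gB%03d", seq_len(n), seq_len(n)),
    sample_id = sample(c("rep1", "rep2"), n, replace = TRUE),
    lenA = sample(50:2000, n, TRUE), lenB = sample(50:2000, n, TRUE),
    intergenic_length = sample(-20:400, n, TRUE),
    strand_match = sample(0:1, n, TRUE),
    stringsAsFactors = FALSE)
  for (cmp in c("AI", "BI", "AB", "AIB")) {
    df[[paste0("kw_", cmp, "_H")]] <- round(stats::runif(n, 0, 60), 6)
    df[[paste0("kw_", cmp, "_logp")]] <- round(stats::runif(n, -300, 0), 6)
  }
  if (with_label) df$label <- sample(0:1, n, TRUE)
  df
}

# random prediction table for voting property tests
random_predictions <- function(n_pairs, samples = "rep1") {
  grid <- data.frame(
    pair_id = rep(sprintf("p%04d", seq_len(n_pairs)), times = length(samples)),
    sample_id = rep(samples, each = n_pairs), stringsAsFactors = FALSE)
  for (alg in algorithm_keys()) {
    grid[[paste0(alg, "_prob")]] <- stats::runif(nrow(grid))
    grid[[paste0(alg, "_call")]] <-
      as.integer(grid[[paste0(alg, "_prob")]] >= 0.5)
  }
  grid
}

# memoized default benchmarks (simulation + featurization is the slow part)
.benchmark_cache <- new.env(parent = emptyenv())
cached_benchmark <- function(seed = 1) {
  key <- paste0("seed", seed)
  if (is.null(.benchmark_cache[[key]]))
    .benchmark_cache[[key]] <- default_benchmark(seed = seed)
  .benchmark_cache[[key]]
}

# small, fast benchmark for classifier unit tests
small_benchmark <- function(seed = 11, n_genes = 400) {
  cfg <- simulation_config(n_genes = n_genes, seed = seed)
  truth <- simulate_genome(cfg)
  tracks <- simulate_coverage(truth, cfg)
  feats <- do.call(rbind, lapply(tracks, function(tr)
    extract_features(truth$genes, tr, labels = truth$labels)))
  rownames(feats) <- NULL
  list(features = feats, truth = truth, tracks = tracks)
}
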