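# Seeded synthetic genomes, operon structures and per-base coverage
# tracks. The generator encodes the premise the method rests on: genes in
# one transcription unit are covered at similar depth and their intergenic
# gaps carry read-through signal, while gaps between units fall to
# background. Per-base noise is negative binomial (overdispersed, as bulk
# RNA-seq coverage is).

#' Simulation configuration
#'
#' Defaults define the study conditions of the package's benchmark:
#' 4,000 genes grouped into transcription units by a geometric
#' stop process (`p_stop = 0.5`, i.e. mean unit size 2), gene lengths
#' uniform 100-1,000 bp, within-operon intergenic gaps uniform 1-30 bp
#' versus 20-400 bp between units (the distributions overlap, so distance
#' alone is not perfectly separating), 40% minus-strand units, unit mean
#' depths log-normal around 50x (sdlog 0.4), read-through factor
#' `readthrough = 0.9` (within-operon intergenic mean depth as a fraction
#' of the unit depth), background depth 1x, negative-binomial dispersion
#' (size) 5, two replicates.
#'
#' @param n_genes Number of genes.
#' @param p_stop Geometric stop probability per gene; adjacent genes share
#'   a unit with probability `1 - p_stop`.
#' @param gene_length Length-2 vector: uniform gene-length bounds (bp).
#' @param intergenic_within Uniform bounds (bp) for within-operon gaps.
#' @param intergenic_between Uniform bounds (bp) for between-unit gaps.
#' @param minus_fraction Fraction of minus-strand transcription units.
#' @param depth_meanlog,depth_sdlog Log-normal parameters of unit mean
#'   depth.
#' @param readthrough Read-through factor r in \[0, 1\].
#' @param background Mean background depth in inter-unit gaps.
#' @param dispersion Negative-binomial size parameter (larger = closer to
#'   Poisson).
#' @param n_replicates Number of coverage replicates.
#' @param redraw_depths If TRUE each replicate redraws unit depths
#'   (emulating different conditions); if FALSE (default) replicates share
#'   unit depths and differ only in noise (biological replicates).
#' @param seqid Sequence name of the single replicon.
#' @param seed RNG seed.
#' @return List of class `sim_config`.
#' @export
simulation_config <- function(n_genes = 4000L, p_stop = 0.5,
                              gene_length = c(100L, 1000L),
                              intergenic_within = c(1L, 30L),
                              intergenic_between = c(20L, 400L),
                              minus_fraction = 0.4,
                              depth_meanlog = log(50), depth_sdlog = 0.4,
                              readthrough = 0.9, background = 1,
                              dispersion = 5, n_replicates = 2L,
                              redraw_depths = FALSE, seqid = "chr",
                              seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(p_stop > 0, p_stop <= 1, minus_fraction >= 0, minus_fraction <= 1,
            readthrough >= 0, readthrough <= 1, background >= 0,
            dispersion > 0, n_replicates >= 1, n_genes >= 1,
            gene_length[1] >= 1, intergenic_within[1] >= 1,
            intergenic_between[1] >= 1)
  structure(cfg, class = "sim_config")
}

#' Simulate a genome with operon structure
#'
#' Lays `n_genes` genes left to right on one replicon, groups consecutive
#' genes into transcription units with geometric sizes (stop probability
#' `p_stop`), assigns each unit a strand, and draws intergenic gaps from
#' the within-unit or between-unit distribution according to membership.
#' Every adjacent pair is labelled: 1 if both genes share a unit, else 0.
#' Deterministic under a fixed seed.
#'
#' @param config A [simulation_config()].
#' @return List of class `synthetic_truth`: `genes` (gene data.frame),
#'   `labels` (pair label data.frame), `units` (integer unit index per
#'   gene), `config`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  n <- config$n_genes
  # memoryless grouping: gene i+1 continues gene i's unit w.p. 1 - p_stop
  continues <- rbinom(max(n - 1L, 0L), 1L, 1 - config$p_stop) == 1L
  units <- cumsum(c(1L, !continues))
  strand_per_unit <- ifelse(runif(max(units)) < config$minus_fraction, "-", "+")
  lengths <- floor(runif(n, config$gene_length[1], config$gene_length[2] + 1))
  gaps <- ifelse(continues,
    floor(runif(n - 1L, config$intergenic_within[1],
                config$intergenic_within[2] + 1)),
    floor(runif(n - 1L, config$intergenic_between[1],
                config$intergenic_between[2] + 1)))
  start <- cumsum(c(1, lengths[-n] + gaps))
  genes <- data.frame(
    gene_id = sprintf("g%05d", seq_len(n)),
    seqid = config$seqid,
    start = as.integer(start),
    end = as.integer(start + lengths - 1),
    strand = strand_per_unit[units],
    length = as.integer(lengths),
    stringsAsFactors = FALSE
  )
  pairs <- enumerate_adjacent_pairs(genes)
  unit_of <- stats::setNames(units, genes$gene_id)
  labels <- data.frame(
    geneA_id = pairs$geneA_id, geneB_id = pairs$geneB_id,
    label = as.integer(unit_of[pairs$geneA_id] == unit_of[pairs$geneB_id]),
    stringsAsFactors = FALSE
  )
  structure(list(genes = genes, labels = labels, units = units,
                 config = config),
            class = "synthetic_truth")
}

#' Simulate per-base coverage for a synthetic genome
#'
#' Each transcription unit draws a mean depth from the log-normal
#' expression distribution; gene bases get negative-binomial noise around
#' it, within-unit intergenic bases around `readthrough` times the unit
#' depth, and between-unit bases around the background depth. Each
#' replicate redraws the noise (and, with `redraw_depths`, the unit
#' depths) under a distinct sub-seed. The within-unit intergenic mean is
#' `background + readthrough * (unit depth - background)`, i.e. the
#' read-through factor interpolates between pure background (r = 0) and
#' the full unit expression level (r = 1).
#'
#' @param truth A `synthetic_truth` from [simulate_genome()].
#' @param config A [simulation_config()]; defaults to `truth$config`.
#' @return List of [coverage_track()] objects, one per replicate, named
#'   `rep1`, `rep2`, ...
#' @export
simulate_coverage <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "synthetic_truth"))
  genes <- truth$genes
  units <- truth$units
  n_units <- max(units)
  L <- max(genes$end) + 200L
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed((config$seed + 13L) %% .Machine$integer.max)
  base_depths <- rlnorm(n_units, config$depth_meanlog, config$depth_sdlog)
  tracks <- vector("list", config$n_replicates)
  for (r in seq_len(config$n_replicates)) {
    set.seed((config$seed + 7919L * r) %% .Machine$integer.max)
    mu_unit <- if (config$redraw_depths)
      rlnorm(n_units, config$depth_meanlog, config$depth_sdlog) else
      base_depths
    d <- rnbinom(L, mu = config$background, size = config$dispersion)
    n <- nrow(genes)
    for (i in seq_len(n)) {
      span <- genes$start[i]:genes$end[i]
      d[span] <- rnbinom(length(span), mu = mu_unit[units[i]],
                         size = config$dispersion)
      if (i < n && units[i + 1L] == units[i] &&
            genes$start[i + 1L] > genes$end[i] + 1L) {
        gap <- (genes$end[i] + 1L):(genes$start[i + 1L] - 1L)
        # read-through interpolates between background (r = 0) and the
        # full unit depth (r = 1)
        mu_gap <- config$background +
          config$readthrough * (mu_unit[units[i]] - config$background)
        d[gap] <- rnbinom(length(gap), mu = max(mu_gap, 0),
                          size = config$dispersion)
      }
    }
    tracks[[r]] <- coverage_track(paste0("rep", r),
                                  stats::setNames(list(as.numeric(d)),
                                                  config$seqid))
  }
  names(tracks) <- vapply(tracks, `[[`, character(1), "sample_id")
  tracks
}

#' Write a simulation to disk
#'
#' Writes the annotation as GFF3, one per-base coverage file per replicate
#' and the pair-label TSV, all byte-compatible with the package readers.
#'
#' @param truth A `synthetic_truth`.
#' @param tracks Coverage tracks from [simulate_coverage()].
#' @param dir Output directory (created if needed).
#' @return Named list of written paths (`gff`, `labels`, `coverage`).
#' @export
write_simulation <- function(truth, tracks, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gff <- file.path(dir, "genes.gff3")
  write_gff3_genes(truth$genes, gff)
  lab <- file.path(dir, "labels.tsv")
  write_pair_labels(truth$labels, lab)
  cov <- vapply(tracks, function(tr) {
    p <- file.path(dir, paste0("coverage_", tr$sample_id, ".tsv"))
    write_coverage(tr, p)
    p
  }, character(1))
  list(gff = gff, labels = lab, coverage = cov)
}

#' The default synthetic benchmark
#'
#' Runs [simulate_genome()] and [simulate_coverage()] with the default
#' [simulation_config()] under the given seed, featurizes every replicate
#' end-to-end (expression filter at mean depth 10), attaches the true
#' labels, and fixes a stratified 75/25 pair-level train/test split. This
#' is the fixture behind the classifier benchmarks: all replicate rows of
#' a pair fall on the same side of the split.
#'
#' @param seed RNG seed (drives the simulation and the split).
#' @param config Optional [simulation_config()] override (its seed is
#'   replaced by `seed`).
#' @return List: `features` (all labelled rows), `train`, `test` (row
#'   subsets), `train_pairs`, `test_pairs`, `truth`.
#' @export
default_benchmark <- function(seed = 1L, config = NULL) {
  if (is.null(config)) config <- simulation_config(seed = seed)
  else config$seed <- seed
  truth <- simulate_genome(config)
  tracks <- simulate_coverage(truth, config)
  features <- do.call(rbind, lapply(tracks, function(tr)
    extract_features(truth$genes, tr, labels = truth$labels, min_mean = 10)))
  rownames(features) <- NULL
  pair_lab <- tapply(features$label, features$pair_id, function(v) v[1])
  pairs <- names(pair_lab)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed((seed + 999L) %% .Machine$integer.max)
  train_pairs <- unlist(lapply(split(pairs, pair_lab), function(p)
    sample(p, round(0.75 * length(p)))), use.names = FALSE)
  test_pairs <- setdiff(pairs, train_pairs)
  list(features = features,
       train = features[features$pair_id %in% train_pairs, , drop = FALSE],
       test = features[features$pair_id %in% test_pairs, , drop = FALSE],
       train_pairs = train_pairs, test_pairs = test_pairs,
       truth = truth)
}
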