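# Adjacent-pair enumeration, expression filtering, coverage-window
# extraction and assembly of the 12-feature vector per (pair, sample).

#' Enumerate adjacent gene pairs
#'
#' Builds one ordered pair per consecutive gene couple per sequence. Gene A
#' is the 5'-most gene in transcription order: for a pair where both genes
#' are on the minus strand, transcription runs right-to-left, so gene A is
#' the genomically *right* gene; in every other case gene A is the
#' genomically left gene. The intergenic region is the bases strictly
#' between the genes; its signed length
#' `(start of right gene) - (end of left gene) - 1` is negative when the
#' genes overlap and zero when they abut.
#'
#' @param genes Gene data.frame sorted by (seqid, start), as returned by
#'   [read_gff3_genes()].
#' @param same_strand_only If `TRUE`, keep only pairs whose genes share a
#'   strand.
#' @return data.frame with one row per pair: `pair_id`
#'   (`"<geneA>|<geneB>"`), gene A and B ids/coordinates/strands, `seqid`,
#'   `lenA`, `lenB`, `strand_match` (0/1), `intergenic_start`,
#'   `intergenic_end`, `intergenic_length` (signed).
#' @export
enumerate_adjacent_pairs <- function(genes, same_strand_only = FALSE) {
  stopifnot(is.data.frame(genes), nrow(genes) >= 0)
  if (is.unsorted(order(genes$seqid, genes$start)))
    genes <- genes[order(genes$seqid, genes$start), , drop = FALSE]
  out <- lapply(split(genes, genes$seqid), function(g) {
    n <- nrow(g)
    if (n < 2L) return(NULL)
    L <- g[-n, , drop = FALSE]  # genomically left gene of each couple
    R <- g[-1L, , drop = FALSE]
    minus_pair <- L$strand == "-" & R$strand == "-"
    A <- ifelse(minus_pair, R$gene_id, L$gene_id)
    B <- ifelse(minus_pair, L$gene_id, R$gene_id)
    data.frame(
      pair_id = paste(A, B, sep = "|"),
      geneA_id = A, geneB_id = B,
      seqid = L$seqid,
      geneA_start = ifelse(minus_pair, R$start, L$start),
      geneA_end = ifelse(minus_pair, R$end, L$end),
      geneA_strand = ifelse(minus_pair, R$strand, L$strand),
      geneB_start = ifelse(minus_pair, L$start, R$start),
      geneB_end = ifelse(minus_pair, L$end, R$end),
      geneB_strand = ifelse(minus_pair, L$strand, R$strand),
      lenA = ifelse(minus_pair, R$length, L$length),
      lenB = ifelse(minus_pair, L$length, R$length),
      strand_match = as.integer(L$strand == R$strand),
      intergenic_start = L$end + 1L,
      intergenic_end = R$start - 1L,
      intergenic_length = R$start - L$end - 1L,
      stringsAsFactors = FALSE
    )
  })
  pairs <- do.call(rbind, out)
  if (is.null(pairs))
    pairs <- data.frame(pair_id = character(0))
  rownames(pairs) <- NULL
  if (same_strand_only && nrow(pairs))
    pairs <- pairs[pairs$strand_match == 1L, , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

.track_slice <- function(track, seqid, lo, hi, what = "") {
  d <- track$depth[[seqid]]
  if (is.null(d))
    stop("sequence '", seqid, "' absent from coverage track '",
         track$sample_id, "'", if (nzchar(what)) paste0(" (", what, ")"))
  if (lo < 1L || hi > length(d))
    stop("window ", lo, "-", hi, " outside coverage bounds of '", seqid,
         "' (length ", length(d), ")", if (nzchar(what)) paste0(" for ", what))
  d[lo:hi]
}

#' Filter pairs by the gene-expression threshold
#'
#' Keeps a pair iff the mean depth over the *full* span of gene A or of
#' gene B is at least `min_mean` (default 10). Unexpressed pairs carry no
#' usable read-through signal and would only teach the classifiers to call
#' silence.
#'
#' @param pairs Pair data.frame from [enumerate_adjacent_pairs()].
#' @param track A [coverage_track()] covering all gene spans.
#' @param min_mean Minimum mean per-base depth (default 10).
#' @return The kept rows of `pairs`, order preserved.
#' @export
filter_expressed <- function(pairs, track, min_mean = 10) {
  if (nrow(pairs) == 0L) return(pairs)
  keep <- vapply(seq_len(nrow(pairs)), function(i) {
    p <- pairs[i, ]
    mA <- mean(.track_slice(track, p$seqid, p$geneA_start, p$geneA_end,
                            p$pair_id))
    mB <- mean(.track_slice(track, p$seqid, p$geneB_start, p$geneB_end,
                            p$pair_id))
    mA >= min_mean || mB >= min_mean
  }, logical(1))
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Genomic bounds of the terminal window of one gene.
# side "3p"/"5p" is in transcription orientation; offset (>= 0) moves the
# window away from the terminus into the gene body, clamped to the gene.
.gene_window_bounds <- function(start, end, strand, side, window, offset = 0L) {
  at_right <- (strand == "+") == (side == "3p")  # terminus on genomic right?
  if (at_right) {
    hi <- end - offset
    lo <- hi - window + 1L
  } else {
    lo <- start + offset
    hi <- lo + window - 1L
  }
  c(lo = max(lo, start), hi = min(hi, end))
}

#' Extract the three coverage windows of a pair
#'
#' `covA` is the depth over the (up to) `window` bases of gene A nearest
#' its 3' end in transcription orientation, `covB` the same for the 5' end
#' of gene B, and `covI` the central `window` bases of the intergenic
#' region: when the region is longer than `window` the window starts
#' `floor((L - window)/2)` bases from its left bound; when `1 <= L <=
#' window` the whole region is used; when the genes abut or overlap
#' (`intergenic_length <= 0`) the single base at the left gene's genomic
#' end stands in for the boundary signal. Genes shorter than `window`
#' contribute their whole span.
#'
#' @param pair One row of the data.frame from [enumerate_adjacent_pairs()].
#' @param track A [coverage_track()].
#' @param window Window width in bp (default 50).
#' @param offset Distance in bp between each gene window and its terminus
#'   (default 0, i.e. the terminal bases adjacent to the intergenic
#'   region).
#' @return List of class `window_sample` with numeric vectors `covA`,
#'   `covI`, `covB`.
#' @export
extract_windows <- function(pair, track, window = 50L, offset = 0L) {
  stopifnot(nrow(pair) == 1L, window >= 1L, offset >= 0L)
  wA <- .gene_window_bounds(pair$geneA_start, pair$geneA_end,
                            pair$geneA_strand, "3p", window, offset)
  wB <- .gene_window_bounds(pair$geneB_start, pair$geneB_end,
                            pair$geneB_strand, "5p", window, offset)
  L <- pair$intergenic_length
  if (L <= 0L) {
    ilo <- ihi <- pair$intergenic_start - 1L  # left gene's genomic end
  } else if (L <= window) {
    ilo <- pair$intergenic_start
    ihi <- pair$intergenic_end
  } else {
    ilo <- pair$intergenic_start + floor((L - window) / 2)
    ihi <- ilo + window - 1L
  }
  structure(list(
    covA = .track_slice(track, pair$seqid, wA["lo"], wA["hi"], pair$pair_id),
    covI = .track_slice(track, pair$seqid, ilo, ihi, pair$pair_id),
    covB = .track_slice(track, pair$seqid, wB["lo"], wB["hi"], pair$pair_id)
  ), class = "window_sample")
}

#' Assemble the 12-feature vector for one (pair, sample)
#'
#' Runs [kruskal_wallis()] on the window combinations (A,I), (B,I), (A,B)
#' and (A,I,B) and stores each H statistic and log10 p-value (p clipped to
#' >= 1e-300 before the logarithm, so log10 p is in \[-300, 0\]), together
#' with the gene lengths, signed intergenic distance and strand match.
#'
#' @param pair One row of the pair data.frame.
#' @param windows A `window_sample` from [extract_windows()].
#' @param sample_id Sample identifier for the feature row.
#' @param label Optional 0/1 pair label.
#' @return One-row data.frame: `pair_id`, `sample_id`, the 12 features of
#'   [operon_feature_names()], and `label` if given.
#' @export
compute_features <- function(pair, windows, sample_id, label = NULL) {
  kw_feats <- function(groups) {
    r <- kruskal_wallis(groups)
    c(H = r$H, logp = max(log10(max(r$p, 1e-300)), -300))
  }
  ai <- kw_feats(list(windows$covA, windows$covI))
  bi <- kw_feats(list(windows$covB, windows$covI))
  ab <- kw_feats(list(windows$covA, windows$covB))
  aib <- kw_feats(list(windows$covA, windows$covI, windows$covB))
  row <- data.frame(
    pair_id = pair$pair_id, sample_id = sample_id,
    lenA = pair$lenA, lenB = pair$lenB,
    intergenic_length = pair$intergenic_length,
    strand_match = pair$strand_match,
    kw_AI_H = ai[["H"]], kw_AI_logp = ai[["logp"]],
    kw_BI_H = bi[["H"]], kw_BI_logp = bi[["logp"]],
    kw_AB_H = ab[["H"]], kw_AB_logp = ab[["logp"]],
    kw_AIB_H = aib[["H"]], kw_AIB_logp = aib[["logp"]],
    stringsAsFactors = FALSE
  )
  if (!is.null(label)) row$label <- as.integer(label)
  row
}

#' Featurize a whole annotation against one coverage track
#'
#' End-to-end featurization: enumerate adjacent pairs, apply the
#' expression filter, extract windows and compute the feature vector for
#' every kept pair. Labels, when provided, are joined by (geneA_id,
#' geneB_id).
#'
#' @param genes Gene data.frame.
#' @param track A [coverage_track()].
#' @param labels Optional label data.frame from [read_pair_labels()].
#' @param min_mean Expression filter threshold (default 10); `0` disables.
#' @param window,offset Window geometry, see [extract_windows()].
#' @param same_strand_only Restrict to same-strand pairs.
#' @return Feature data.frame, one row per kept pair.
#' @export
extract_features <- function(genes, track, labels = NULL, min_mean = 10,
                             window = 50L, offset = 0L,
                             same_strand_only = FALSE) {
  pairs <- enumerate_adjacent_pairs(genes, same_strand_only = same_strand_only)
  if (min_mean > 0) pairs <- filter_expressed(pairs, track, min_mean)
  lab_lookup <- NULL
  if (!is.null(labels))
    lab_lookup <- stats::setNames(labels$label,
                                  paste(labels$geneA_id, labels$geneB_id,
                                        sep = "|"))
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    p <- pairs[i, ]
    w <- extract_windows(p, track, window = window, offset = offset)
    lab <- if (!is.null(lab_lookup)) {
      v <- lab_lookup[p$pair_id]
      # labels may be keyed in genomic order rather than transcription order
      if (is.na(v)) v <- lab_lookup[paste(p$geneB_id, p$geneA_id, sep = "|")]
      if (is.na(v)) NA_integer_ else as.integer(v)
    } else NULL
    compute_features(p, w, track$sample_id, label = lab)
  })
  if (!length(rows)) {
    out <- stats::setNames(
      data.frame(matrix(nrow = 0, ncol = length(.feature_table_cols(!is.null(labels))))),
      .feature_table_cols(!is.null(labels)))
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
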