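# Ensemble voting: tally per-pair positive calls across the six
# algorithms, apply vote thresholds 1-6, enforce replicate consensus, and
# string consecutive positive pairs into multi-gene operons.

.call_cols <- function() paste0(.alg_keys, "_call")

#' Tally algorithm votes per prediction row
#'
#' Counts, for each (pair, sample) row, how many of the six algorithms
#' called the pair positive, and derives the thresholded ensemble call
#' `call_k = 1` iff `votes >= k` for k = 1..6. `NA` calls (abstaining
#' algorithms after replicate consensus) contribute no vote.
#'
#' @param predictions Prediction data.frame with the six `<ALG>_call`
#'   columns (e.g. from [predict_suite()] or [replicate_consensus()]).
#' @return data.frame: `pair_id` (and `sample_id` if present), `votes`
#'   (0-6), `call_1` .. `call_6`.
#' @export
tally_votes <- function(predictions) {
  missing <- setdiff(.call_cols(), names(predictions))
  if (length(missing))
    stop("predictions are missing algorithm call column(s): ",
         paste(missing, collapse = ", "))
  calls <- as.matrix(predictions[.call_cols()])
  out <- predictions[intersect(c("pair_id", "sample_id", "n_replicates"),
                               names(predictions))]
  out$votes <- as.integer(rowSums(calls == 1L, na.rm = TRUE))
  for (k in 1:6) out[[paste0("call_", k)]] <- as.integer(out$votes >= k)
  out
}

#' Replicate-consensus calls
#'
#' Groups prediction rows by pair across samples (replicates). Pairs
#' observed in fewer than `min_replicates` samples are dropped. Within each
#' algorithm, a consensus call exists only if the replicate calls agree
#' (`mode = "unanimous"`, the default) or a strict majority agrees
#' (`mode = "majority"`); otherwise the algorithm abstains for that pair
#' (call `NA`, contributing no vote).
#'
#' @param predictions Prediction data.frame from [predict_suite()], rows
#'   spanning >= 1 sample per pair.
#' @param min_replicates Minimum number of samples a pair must appear in.
#' @param mode `"unanimous"` or `"majority"`.
#' @return data.frame with one row per retained pair: `pair_id`,
#'   `sample_id = "consensus"`, `n_replicates`, and per-algorithm `_call`
#'   (0/1/NA) and `_prob` (mean probability across replicates) columns.
#' @export
replicate_consensus <- function(predictions, min_replicates = 2L,
                                mode = c("unanimous", "majority")) {
  mode <- match.arg(mode)
  missing <- setdiff(.call_cols(), names(predictions))
  if (length(missing))
    stop("predictions are missing algorithm call column(s): ",
         paste(missing, collapse = ", "))
  grp <- split(seq_len(nrow(predictions)), predictions$pair_id)
  grp <- grp[vapply(grp, length, integer(1)) >= min_replicates]
  rows <- lapply(names(grp), function(pid) {
    idx <- grp[[pid]]
    row <- data.frame(pair_id = pid, sample_id = "consensus",
                      n_replicates = length(idx), stringsAsFactors = FALSE)
    for (alg in .alg_keys) {
      cc <- predictions[[paste0(alg, "_call")]][idx]
      row[[paste0(alg, "_prob")]] <-
        mean(predictions[[paste0(alg, "_prob")]][idx])
      row[[paste0(alg, "_call")]] <- switch(mode,
        unanimous = if (length(unique(cc)) == 1L) cc[1] else NA_integer_,
        majority = {
          pos <- sum(cc == 1L)
          if (pos * 2L > length(cc)) 1L
          else if ((length(cc) - pos) * 2L > length(cc)) 0L
          else NA_integer_
        })
    }
    row
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pair_id = character(0), sample_id = character(0),
               n_replicates = integer(0))
  rownames(out) <- NULL
  out
}

#' String consecutive positive pairs into multi-gene operons
#'
#' Walks each sequence in genomic order and merges maximal runs of
#' consecutive same-strand pairs called positive at the chosen vote
#' threshold into operon chains. A negative pair, an opposite-strand pair,
#' or a pair absent from `calls` breaks the chain; an isolated positive
#' pair yields a 2-gene chain. Genes within a chain are listed in
#' transcription (5' to 3') order.
#'
#' @param calls data.frame keyed by `pair_id` carrying either a `votes`
#'   column (thresholded at `threshold`) or a binary `call` column.
#' @param genes Gene data.frame ([read_gff3_genes()]).
#' @param threshold Vote threshold k (default 3) applied when `calls` has
#'   a `votes` column.
#' @return data.frame: `chain_id`, `seqid`, `strand`, `genes`
#'   (comma-separated gene ids), `n_genes`.
#' @export
string_operons <- function(calls, genes, threshold = 3L) {
  if ("votes" %in% names(calls)) {
    positive <- calls$pair_id[calls$votes >= threshold]
  } else if ("call" %in% names(calls)) {
    positive <- calls$pair_id[calls$call == 1L]
  } else stop("`calls` must have a `votes` or `call` column")
  pairs <- enumerate_adjacent_pairs(genes)
  if (nrow(pairs) == 0L)
    return(data.frame(chain_id = character(0), seqid = character(0),
                      strand = character(0), genes = character(0),
                      n_genes = integer(0)))
  chains <- list()
  for (sq in unique(pairs$seqid)) {
    ps <- pairs[pairs$seqid == sq, , drop = FALSE]  # genomic order
    link <- ps$strand_match == 1L & ps$pair_id %in% positive
    r <- rle(link)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in seq_along(r$values)) {
      if (!r$values[j]) next
      idx <- starts[j]:ends[j]
      # genomic left-to-right gene list over the run of linked pairs
      left_ids <- ifelse(ps$geneA_strand[idx] == "-" &
                           ps$geneB_strand[idx] == "-",
                         ps$geneB_id[idx], ps$geneA_id[idx])
      right_last <- if (ps$geneA_strand[ends[j]] == "-" &&
                          ps$geneB_strand[ends[j]] == "-")
        ps$geneA_id[ends[j]] else ps$geneB_id[ends[j]]
      members <- c(left_ids, right_last)
      strand <- ps$geneA_strand[idx[1]]
      if (strand == "-") members <- rev(members)  # transcription order
      chains[[length(chains) + 1L]] <- data.frame(
        seqid = sq, strand = strand,
        genes = paste(members, collapse = ","),
        n_genes = length(members), stringsAsFactors = FALSE)
    }
  }
  if (!length(chains))
    return(data.frame(chain_id = character(0), seqid = character(0),
                      strand = character(0), genes = character(0),
                      n_genes = integer(0)))
  out <- do.call(rbind, chains)
  out <- cbind(chain_id = sprintf("operon_%04d", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out
}
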