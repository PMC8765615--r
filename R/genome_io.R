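# On-disk formats: GFF3 annotations, per-base coverage text, pair-label,
# feature and prediction TSVs. All coordinates are 1-based inclusive
# throughout the package; conversion to R indexing happens only where
# depth arrays are subset.

.pred_cols <- function() {
  c("pair_id", "sample_id",
    as.vector(t(outer(.alg_keys, c("prob", "call"), paste, sep = "_"))))
}

.feature_table_cols <- function(with_label = TRUE) {
  base <- c("pair_id", "sample_id", operon_feature_names())
  if (with_label) c(base, "label") else base
}

#' Read gene records from a GFF3 annotation
#'
#' Imports a GFF3 file and keeps records whose type column matches
#' `feature_type`. The gene identifier is taken from the `ID` attribute,
#' falling back to `locus_tag`, then `Name`; records carrying none of the
#' three are skipped with a warning. Records are returned sorted by
#' (seqid, start).
#'
#' @param path Path to a GFF3 file (tab-separated, 9 columns, 1-based
#'   inclusive coordinates).
#' @param feature_type Type-column value to keep (default `"gene"`).
#' @return A data.frame with columns `gene_id`, `seqid`, `start`, `end`,
#'   `strand` (`"+"`/`"-"`) and `length` (= end - start + 1).
#' @export
read_gff3_genes <- function(path, feature_type = "gene") {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == feature_type]
  mc <- S4Vectors::mcols(gr)
  pick <- function(field) {
    if (field %in% colnames(mc)) as.character(mc[[field]]) else
      rep(NA_character_, length(gr))
  }
  id <- pick("ID")
  id <- ifelse(is.na(id) | id == "", pick("locus_tag"), id)
  id <- ifelse(is.na(id) | id == "", pick("Name"), id)
  drop <- is.na(id) | id == ""
  if (any(drop)) {
    warning(sum(drop), " ", feature_type,
            " record(s) without ID, locus_tag or Name attribute skipped")
    gr <- gr[!drop]
    id <- id[!drop]
  }
  # strip GFF3 "gene:" style prefixes that Ensembl adds to ID
  id <- sub("^[A-Za-z_]+:", "", id)
  if (anyDuplicated(id))
    stop("duplicate gene identifiers in ", path, ": ",
         paste(unique(id[duplicated(id)])[1:3], collapse = ", "))
  genes <- data.frame(
    gene_id = id,
    seqid = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  bad_strand <- !genes$strand %in% c("+", "-")
  if (any(bad_strand)) {
    warning(sum(bad_strand), " record(s) with strand not +/- skipped")
    genes <- genes[!bad_strand, , drop = FALSE]
  }
  genes$length <- genes$end - genes$start + 1L
  genes <- genes[order(genes$seqid, genes$start, genes$end), , drop = FALSE]
  rownames(genes) <- NULL
  genes
}

#' Write gene records as GFF3
#'
#' Inverse of [read_gff3_genes()]; used by the simulator so generated
#' annotations round-trip through the standard reader.
#'
#' @param genes Gene data.frame as returned by [read_gff3_genes()].
#' @param path Output path.
#' @param source Source column value.
#' @return `path`, invisibly.
#' @export
write_gff3_genes <- function(genes, path, source = "operonvoter") {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$seqid,
    ranges = IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand
  )
  gr$source <- source
  gr$type <- "gene"
  gr$ID <- genes$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Construct a coverage track from per-sequence depth vectors
#'
#' @param sample_id Sample identifier string.
#' @param depth Named list of non-negative numeric vectors, one per seqid,
#'   one value per base (1-based).
#' @return Object of class `coverage_track`.
#' @export
coverage_track <- function(sample_id, depth) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L,
            is.list(depth), length(depth) == 0L || !is.null(names(depth)))
  if (any(vapply(depth, function(d) any(d < 0), logical(1))))
    stop("coverage depths must be >= 0")
  structure(list(sample_id = sample_id, depth = depth),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track '", x$sample_id, "': ",
      length(x$depth), " sequence(s), ",
      format(sum(lengths(x$depth)), big.mark = ","), " bases\n", sep = "")
  invisible(x)
}

#' Read a per-base coverage file
#'
#' Parses 3-column whitespace/tab-separated text (seqid, 1-based position,
#' depth) of the kind produced by genome-coverage utilities in per-base
#' mode, into dense per-sequence depth vectors. Positions absent from the
#' file are filled with depth 0 (per-base emitters may omit zero rows).
#'
#' @param path Path to the coverage file.
#' @param sample_id Sample identifier to attach to the track.
#' @param seq_lengths Optional named integer vector of sequence lengths; if
#'   given, each depth vector is padded with zeros to that length.
#' @return A [coverage_track()].
#' @export
read_coverage <- function(path, sample_id, seq_lengths = NULL) {
  if (!file.exists(path)) stop("coverage file not found: ", path)
  raw <- tryCatch(
    read.delim(path, header = FALSE, sep = "", colClasses = "character",
               comment.char = "#"),
    error = function(e) NULL)
  if (is.null(raw) || nrow(raw) == 0L) {
    warning("empty coverage file: ", path)
    depth <- list()
    if (!is.null(seq_lengths))
      depth <- lapply(seq_lengths, function(L) integer(L))
    return(coverage_track(sample_id, depth))
  }
  if (ncol(raw) < 3L)
    stop("coverage file must have 3 columns (seqid, position, depth): ", path)
  pos <- suppressWarnings(as.integer(raw[[2]]))
  dep <- suppressWarnings(as.numeric(raw[[3]]))
  if (anyNA(pos) || any(pos < 1L))
    stop("non-integer or non-positive position in coverage file ", path,
         " (first bad line: ", which(is.na(pos) | pos < 1L)[1], ")")
  if (anyNA(dep) || any(dep < 0) || any(dep != floor(dep)))
    stop("non-integer or negative depth in coverage file ", path,
         " (first bad line: ",
         which(is.na(dep) | dep < 0 | dep != floor(dep))[1], ")")
  seqid <- raw[[1]]
  depth <- lapply(split(seq_along(pos), seqid), function(i) {
    p <- pos[i]
    if (anyDuplicated(p))
      stop("duplicate position ", p[duplicated(p)][1], " for sequence '",
           seqid[i[1]], "' in ", path)
    L <- max(p)
    if (!is.null(seq_lengths) && seqid[i[1]] %in% names(seq_lengths))
      L <- max(L, seq_lengths[[seqid[i[1]]]])
    d <- numeric(L)
    d[p] <- dep[i]
    d
  })
  coverage_track(sample_id, depth)
}

#' Write a coverage track as per-base text
#'
#' @param track A [coverage_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coverage <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sq in names(track$depth)) {
    d <- track$depth[[sq]]
    writeLines(paste(sq, seq_along(d), format(d, scientific = FALSE,
                                              trim = TRUE), sep = "\t"), con)
  }
  invisible(path)
}

#' Read an operon-pair label table
#'
#' Three-column TSV with header: `geneA_id`, `geneB_id`, `label` (0 = not
#' an operon pair, 1 = operon pair), in the style of reference operon-pair
#' calls exported from operon databases.
#'
#' @param path Path to the label TSV.
#' @return data.frame with columns `geneA_id`, `geneB_id`, `label`.
#' @export
read_pair_labels <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t",
                   colClasses = c("character", "character", "integer"))
  expected <- c("geneA_id", "geneB_id", "label")
  if (!identical(names(df), expected))
    stop("label file header must be: ", paste(expected, collapse = "\t"),
         " (got: ", paste(names(df), collapse = "\t"), ")")
  if (anyNA(df$label) || !all(df$label %in% c(0L, 1L)))
    stop("labels must be binary 0/1; offending value(s): ",
         paste(unique(df$label[!df$label %in% c(0L, 1L)]), collapse = ", "))
  if (anyDuplicated(df[c("geneA_id", "geneB_id")]))
    stop("duplicate (geneA_id, geneB_id) rows in ", path)
  df
}

#' @rdname read_pair_labels
#' @param labels data.frame with columns `geneA_id`, `geneB_id`, `label`.
#' @export
write_pair_labels <- function(labels, path) {
  .write_tsv(labels[c("geneA_id", "geneB_id", "label")], path)
}

.write_tsv <- function(df, path) {
  con <- file(path, "wb")  # binary keeps LF endings everywhere
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' Write / read a feature table
#'
#' The feature table is a TSV with header `pair_id`, `sample_id`, the 12
#' model features in the fixed order of [operon_feature_names()], and an
#' optional trailing `label` column. `read_feature_table(write_feature_table(x))`
#' reproduces `x` exactly.
#'
#' @param features Feature data.frame.
#' @param path File path.
#' @return `write_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` the data.frame.
#' @export
write_feature_table <- function(features, path) {
  cols <- .feature_table_cols(with_label = "label" %in% names(features))
  missing <- setdiff(cols, names(features))
  if (length(missing))
    stop("feature table is missing column(s): ",
         paste(missing, collapse = ", "))
  .write_tsv(features[cols], path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  for (variant in list(.feature_table_cols(TRUE), .feature_table_cols(FALSE))) {
    if (identical(names(df), variant)) return(df)
  }
  stop("feature table header mismatch.\nexpected: ",
       paste(.feature_table_cols(TRUE), collapse = "\t"),
       "\n(or the same without 'label')\ngot:      ",
       paste(names(df), collapse = "\t"))
}

#' Write / read a suite prediction table
#'
#' TSV with `pair_id`, `sample_id` and, per algorithm key, `<ALG>_prob`
#' (positive-class probability) and `<ALG>_call` (0/1).
#'
#' @param predictions Prediction data.frame from [predict_suite()].
#' @param path File path.
#' @return `write_predictions()` returns `path` invisibly;
#'   `read_predictions()` the data.frame.
#' @export
write_predictions <- function(predictions, path) {
  missing <- setdiff(.pred_cols(), names(predictions))
  if (length(missing))
    stop("prediction table is missing column(s): ",
         paste(missing, collapse = ", "))
  .write_tsv(predictions[.pred_cols()], path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!identical(names(df), .pred_cols()))
    stop("prediction table header mismatch.\nexpected: ",
         paste(.pred_cols(), collapse = "\t"), "\ngot:      ",
         paste(names(df), collapse = "\t"))
  df
}
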