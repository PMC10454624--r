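#' Normalize a taxon label for comparison
#'
#' Trims leading/trailing whitespace, collapses internal whitespace runs and
#' case-folds. Original spellings are kept for reporting; normalization is
#' used only for equality tests. An empty (or `NA`) label means "not
#' classified at this rank".
#'
#' @param x Character vector of labels.
#' @return Normalized character vector; `NA` and blank map to `""`.
#' @export
normalize_taxon <- function(x) {
  x[is.na(x)] <- ""
  tolower(gsub("\\s+", " ", trimws(x)))
}

#' Read mock community metadata
#'
#' TSV with header; required columns `species`, `genome_length_bp`,
#' `ssu_copies`, plus any of the lineage columns `phylum`, `family`, `genus`.
#'
#' @param path Path to the metadata TSV.
#' @return data.frame, one row per mock member.
#' @export
read_mock_metadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("species", "genome_length_bp", "ssu_copies")
  if (!all(need %in% names(md))) {
    stop("mock metadata must contain columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(md$species)) stop("duplicate species in mock metadata")
  if (any(md$genome_length_bp < 1) || any(md$ssu_copies < 1)) {
    stop("genome_length_bp and ssu_copies must be >= 1")
  }
  md
}

#' Write mock community metadata
#' @param metadata data.frame as from [read_mock_metadata()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mock_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a features x samples count table
#'
#' TSV with a header row of sample names; first column holds feature ids.
#'
#' @param path Path to the table.
#' @return Integer matrix, features in rows (rownames = feature ids),
#'   samples in columns.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- df[[1L]]
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  validate_feature_table(m)
  m
}

#' Write a features x samples count table
#' @param table Integer matrix with feature rownames and sample colnames.
#' @param path Output path.
#' @param id_column Name for the leading feature-id column.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, id_column = "feature_id") {
  validate_feature_table(table)
  df <- data.frame(rownames(table), table, check.names = FALSE)
  names(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_feature_table <- function(m) {
  if (is.null(rownames(m))) stop("feature table must have feature rownames")
  if (anyDuplicated(colnames(m))) stop("sample names must be unique")
  if (any(m < 0)) stop("feature table must be nonnegative")
  if (any(m != round(m))) stop("feature table must hold integer counts")
  invisible(m)
}

#' Read per-ASV taxonomy calls
#'
#' TSV with header; column `asv_id` plus rank columns (`phylum`, `family`,
#' `genus`, `species`) and an optional `confidence` column in `[0,1]`.
#'
#' @param path Path to the calls TSV.
#' @return data.frame of calls.
#' @export
read_taxonomy_calls <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"asv_id" %in% names(df)) stop("calls table must contain asv_id")
  if ("confidence" %in% names(df)) {
    ok <- is.na(df$confidence) | (df$confidence >= 0 & df$confidence <= 1)
    if (!all(ok)) stop("confidence must lie in [0,1]")
  }
  df
}

blast6_columns <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                    "gapopen", "qstart", "qend", "sstart", "send",
                    "evalue", "bitscore")

#' Read BLAST tabular hits (outfmt 6)
#'
#' Standard 12-column headerless tab format. Subject coordinates are
#' converted to 0-based half-open `sstart0`/`send0` (minus-strand hits, where
#' `sstart > send`, are normalized and flagged in `sstrand`); query coverage
#' is computed as aligned query bases / query length x 100 when `query_lengths`
#' is supplied, otherwise from `qstart`/`qend` against the maximum observed
#' query coordinate.
#'
#' @param path Path to the hits TSV.
#' @param query_lengths Optional named vector of query sequence lengths used
#'   for exact query-coverage computation.
#' @return data.frame of hits with the 12 standard columns plus `sstart0`,
#'   `send0`, `sstrand` and `query_coverage_pct`.
#' @export
read_blast6 <- function(path, query_lengths = NULL) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (!nrow(df)) {
    df <- as.data.frame(stats::setNames(rep(list(numeric(0)), 12), blast6_columns))
    df$sstart0 <- df$send0 <- integer(0)
    df$sstrand <- character(0)
    df$query_coverage_pct <- numeric(0)
    return(df)
  }
  if (ncol(df) < 12L) stop("outfmt-6 hits require 12 columns")
  names(df)[1:12] <- blast6_columns
  minus <- df$sstart > df$send
  df$sstrand <- ifelse(minus, "-", "+")
  df$sstart0 <- ifelse(minus, df$send, df$sstart) - 1L
  df$send0 <- ifelse(minus, df$sstart, df$send)
  qlen <- if (!is.null(query_lengths)) {
    unname(query_lengths[df$qseqid])
  } else {
    stats::ave(pmax(df$qstart, df$qend), df$qseqid, FUN = max)
  }
  df$query_coverage_pct <- (abs(df$qend - df$qstart) + 1) / qlen * 100
  df
}

#' Write hits in BLAST outfmt-6 layout
#' @param hits data.frame containing the 12 standard columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_blast6 <- function(hits, path) {
  utils::write.table(hits[, blast6_columns], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
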