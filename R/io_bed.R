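#' Read 16S gene annotations from BED
#'
#' BED 3-6 column, 0-based half-open, matching the internal coordinate
#' convention (no conversion is performed). Column 4 is the gene id (generated
#' as `<chrom>:<start>-<end>` when absent), column 6 the strand (default `+`).
#'
#' @param path Path to a BED file.
#' @return data.frame with columns `genome_id`, `start`, `end`, `gene_id`,
#'   `strand`. Zero rows for an empty file.
#' @seealso [write_bed()]
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#") &
                   !startsWith(lines, "track") & !startsWith(lines, "browser")]
  if (!length(lines)) return(empty_annotation())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 3L)) {
    stop("malformed BED: line ", which(ncol < 3L)[1], " has fewer than 3 columns")
  }
  get <- function(i, default = NA_character_) {
    vapply(fields, function(f) if (length(f) >= i) f[i] else default, "")
  }
  start <- suppressWarnings(as.integer(get(2L)))
  end <- suppressWarnings(as.integer(get(3L)))
  if (anyNA(start) || anyNA(end)) {
    stop("malformed BED: non-integer coordinates at line ",
         which(is.na(start) | is.na(end))[1])
  }
  bad <- start < 0L | start >= end
  if (any(bad)) {
    stop("malformed BED: start must satisfy 0 <= start < end (line ",
         which(bad)[1], ")")
  }
  gene_id <- get(4L)
  auto <- is.na(gene_id) | gene_id == "." | !nzchar(gene_id)
  gene_id[auto] <- sprintf("%s:%d-%d", get(1L)[auto], start[auto], end[auto])
  strand <- get(6L)
  strand[is.na(strand) | !strand %in% c("+", "-")] <- "+"
  ann <- data.frame(genome_id = get(1L), start = start, end = end,
                    gene_id = gene_id, strand = strand,
                    stringsAsFactors = FALSE)
  validate_annotation(ann)
  ann
}

#' Write annotations to BED (6 column)
#'
#' @param annotation data.frame as returned by [read_bed()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(annotation, path) {
  validate_annotation(annotation)
  out <- data.frame(annotation$genome_id, annotation$start, annotation$end,
                    annotation$gene_id, 0L, annotation$strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

empty_annotation <- function() {
  data.frame(genome_id = character(0), start = integer(0), end = integer(0),
             gene_id = character(0), strand = character(0),
             stringsAsFactors = FALSE)
}

# Gene ids must be unique within a genome; intervals 0-based half-open.
validate_annotation <- function(ann, genome_lengths = NULL) {
  stopifnot(is.data.frame(ann),
            all(c("genome_id", "start", "end", "gene_id", "strand") %in% names(ann)))
  if (any(ann$start < 0L | ann$start >= ann$end)) {
    stop("annotation intervals must satisfy 0 <= start < end")
  }
  dup <- duplicated(paste(ann$genome_id, ann$gene_id))
  if (any(dup)) {
    stop("duplicate gene id within a genome: ", ann$gene_id[dup][1])
  }
  if (!is.null(genome_lengths)) {
    len <- genome_lengths[ann$genome_id]
    if (anyNA(len)) stop("annotation references unknown genome")
    if (any(ann$end > len)) stop("annotation interval exceeds genome length")
  }
  invisible(ann)
}
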