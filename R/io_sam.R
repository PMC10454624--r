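#' Read alignments from a SAM text file
#'
#' Parses SAM into a data.frame of alignment records, converting the 1-based
#' reference positions to the package-wide 0-based half-open convention
#' exactly once, at this boundary. Flags are decoded into logical columns and
#' the CIGAR string is resolved into aligned reference blocks (runs of
#' M/=/X/D operations; N splits blocks; I/S/H/P consume no reference).
#'
#' @param path Path to a SAM file with a header.
#' @return data.frame of class `sam_alignments` with columns `read_id`,
#'   `flag`, `genome_id`, `start`, `end` (0-based half-open span, `NA` when
#'   unmapped), `mapq`, `cigar`, `mapped`, `paired`, `mate` (`"fwd"`,
#'   `"rev"` or `"single"`), `reverse`, `primary`, and list-column `blocks`
#'   (two-column matrices of 0-based half-open reference intervals).
#'   Reference lengths from `@SQ` lines are attached as attribute
#'   `genome_lengths`.
#' @export
read_sam <- function(path) {
  if (!file.exists(path)) stop("SAM file not found: ", path)
  lines <- readLines(path)
  hdr <- startsWith(lines, "@")
  sq <- lines[hdr][startsWith(lines[hdr], "@SQ")]
  glen <- integer(0)
  if (length(sq)) {
    sn <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
    ln <- as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq))
    glen <- stats::setNames(ln, sn)
  }
  recs <- lines[!hdr & nzchar(lines)]
  if (!length(recs)) {
    out <- empty_sam_alignments()
    attr(out, "genome_lengths") <- glen
    return(out)
  }
  fields <- strsplit(recs, "\t", fixed = TRUE)
  if (any(lengths(fields) < 11L)) {
    stop("malformed SAM: record with fewer than 11 fields")
  }
  f <- function(i) vapply(fields, `[[`, "", i)
  flag <- as.integer(f(2L))
  rname <- f(3L)
  pos1 <- as.integer(f(4L))
  cigar <- f(6L)
  mapped <- !bitwAnd(flag, 4L)
  if (any(mapped & rname != "*" & !(rname %in% names(glen))) && length(glen)) {
    bad <- rname[mapped & !(rname %in% names(glen))][1]
    stop("SAM record references genome absent from header: ", bad)
  }
  blocks <- vector("list", length(flag))
  start <- end <- rep(NA_integer_, length(flag))
  for (i in which(mapped)) {
    b <- cigar_ref_blocks(cigar[i], pos1[i] - 1L)
    blocks[[i]] <- b
    start[i] <- b[1L, 1L]
    end[i] <- b[nrow(b), 2L]
  }
  out <- data.frame(
    read_id = f(1L), flag = flag,
    genome_id = ifelse(mapped, rname, NA_character_),
    start = start, end = end,
    mapq = as.integer(f(5L)), cigar = cigar,
    mapped = mapped,
    paired = bitwAnd(flag, 1L) > 0L,
    mate = ifelse(bitwAnd(flag, 1L) == 0L, "single",
                  ifelse(bitwAnd(flag, 64L) > 0L, "fwd", "rev")),
    reverse = bitwAnd(flag, 16L) > 0L,
    primary = bitwAnd(flag, 256L) == 0L & bitwAnd(flag, 2048L) == 0L,
    stringsAsFactors = FALSE
  )
  out$blocks <- blocks
  if (length(glen)) {
    over <- out$mapped & out$end > glen[out$genome_id]
    if (any(over, na.rm = TRUE)) {
      stop("alignment extends past the end of genome ",
           out$genome_id[which(over)[1]])
    }
  }
  class(out) <- c("sam_alignments", "data.frame")
  attr(out, "genome_lengths") <- glen
  out
}

empty_sam_alignments <- function() {
  out <- data.frame(read_id = character(0), flag = integer(0),
                    genome_id = character(0), start = integer(0),
                    end = integer(0), mapq = integer(0), cigar = character(0),
                    mapped = logical(0), paired = logical(0),
                    mate = character(0), reverse = logical(0),
                    primary = logical(0), stringsAsFactors = FALSE)
  out$blocks <- list()
  class(out) <- c("sam_alignments", "data.frame")
  out
}

# Aligned reference blocks of a CIGAR string anchored at pos0 (0-based).
# M/=/X/D extend the current block, N closes it, I/S/H/P are ignored on the
# reference. Returns a k x 2 matrix of half-open intervals.
cigar_ref_blocks <- function(cigar, pos0) {
  if (cigar == "*") stop("mapped record with '*' CIGAR")
  toks <- regmatches(cigar, gregexpr("[0-9]+[A-Z=]", cigar))[[1]]
  if (sum(nchar(toks)) != nchar(cigar)) stop("malformed CIGAR: ", cigar)
  len <- as.integer(sub(".$", "", toks))
  op <- substring(toks, nchar(toks))
  bad <- !op %in% c("M", "I", "D", "N", "S", "H", "P", "=", "X")
  if (any(bad)) stop("unknown CIGAR opcode '", op[bad][1], "' in ", cigar)
  starts <- ends <- integer(0)
  cur_s <- NA_integer_
  p <- pos0
  for (i in seq_along(op)) {
    if (op[i] %in% c("M", "=", "X", "D")) {
      if (is.na(cur_s)) cur_s <- p
      p <- p + len[i]
    } else if (op[i] == "N") {
      if (!is.na(cur_s)) { starts <- c(starts, cur_s); ends <- c(ends, p) }
      cur_s <- NA_integer_
      p <- p + len[i]
    }
    # I/S/H/P: no reference advance
  }
  if (!is.na(cur_s)) { starts <- c(starts, cur_s); ends <- c(ends, p) }
  if (!length(starts)) stop("CIGAR consumes no reference: ", cigar)
  cbind(start = starts, end = ends)
}

#' Write alignment records to SAM
#'
#' Emits a minimal valid SAM file (header `@SQ` lines plus 11 mandatory
#' fields; `SEQ`/`QUAL` are written as provided or `*`). Converts internal
#' 0-based starts back to 1-based `POS`.
#'
#' @param alignments `sam_alignments` data.frame (optionally with a `seq`
#'   column of read sequences).
#' @param genome_lengths Named integer vector of reference lengths for the
#'   header; defaults to the attribute stored by [read_sam()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, path, genome_lengths = NULL) {
  if (is.null(genome_lengths)) {
    genome_lengths <- attr(alignments, "genome_lengths")
  }
  if (is.null(genome_lengths)) stop("genome_lengths required for SAM header")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(genome_lengths),
                     as.integer(genome_lengths)), con)
  if (!nrow(alignments)) return(invisible(path))
  seqs <- if ("seq" %in% names(alignments)) alignments$seq else "*"
  rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                 alignments$read_id, alignments$flag,
                 ifelse(alignments$mapped, alignments$genome_id, "*"),
                 ifelse(alignments$mapped, alignments$start + 1L, 0L),
                 ifelse(is.na(alignments$mapq), 0L, alignments$mapq),
                 ifelse(alignments$mapped, alignments$cigar, "*"),
                 seqs)
  writeLines(rec, con)
  invisible(path)
}
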