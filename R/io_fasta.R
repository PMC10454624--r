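#' Read a FASTA file
#'
#' Reads nucleotide FASTA into a named character vector, preserving record
#' order. Sequences are upper-cased and validated against the DNA alphabet
#' `{A,C,G,T,N}`. Parsing is delegated to [Biostrings::readDNAStringSet()]
#' after a light structural check so malformed input fails with the offending
#' line number rather than a parser-internal message.
#'
#' @param path Path to an existing FASTA file.
#' @return Named character vector of sequences; `character(0)` for an empty
#'   file. Names are the full header lines without the leading `>`.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank)) return(stats::setNames(character(0), character(0)))
  if (!startsWith(lines[nonblank[1]], ">")) {
    stop("malformed FASTA: line ", nonblank[1], " is not a header")
  }
  hdr <- which(startsWith(lines, ">"))
  # empty record = header immediately followed by header/EOF
  nxt <- c(hdr[-1], length(lines) + 1L)
  for (i in seq_along(hdr)) {
    body <- lines[setdiff(seq.int(hdr[i] + 1L, length.out = nxt[i] - hdr[i] - 1L), hdr)]
    if (!sum(nchar(trimws(body)))) {
      stop("malformed FASTA: empty record at line ", hdr[i])
    }
    if (!nzchar(trimws(sub("^>", "", lines[hdr[i]])))) {
      stop("malformed FASTA: empty header at line ", hdr[i])
    }
  }
  body_bad <- !startsWith(lines, ">") & grepl("[^ACGTNacgtn[:space:]]", lines)
  if (any(body_bad)) {
    stop("non-ACGTN characters at line ", which(body_bad)[1])
  }
  set <- suppressWarnings(Biostrings::readDNAStringSet(path))
  stats::setNames(toupper(as.character(set)), names(set))
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (length(seqs) && is.null(names(seqs))) stop("sequences must be named")
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Reverse-complement a DNA string
#'
#' @param seq Character scalar over `{A,C,G,T,N}`.
#' @return Reverse complement, same alphabet.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}
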