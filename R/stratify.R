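#' Group identical 16S copies within a genome
#'
#' Bacterial genomes carry multiple 16S rRNA operons, some byte-identical. A
#' read pair whose mates land on two identical copies of the same genome is
#' still unambiguous evidence for that gene sequence, so identical copies are
#' grouped; minus-strand copies are reverse-complemented before comparison.
#' Grouping is strictly per genome: identical sequences shared across genomes
#' do not merge.
#'
#' @param genome_sequence Character scalar, the genome sequence.
#' @param ssu_genes Annotation rows (see [read_bed()]) for this genome.
#' @return Named character vector mapping each `gene_id` to its group id
#'   (the lexicographically first gene id in the group, prefixed with the
#'   genome id).
#' @export
identical_copy_groups <- function(genome_sequence, ssu_genes) {
  if (!nrow(ssu_genes)) return(stats::setNames(character(0), character(0)))
  if (any(ssu_genes$end > nchar(genome_sequence)) || any(ssu_genes$start < 0)) {
    stop("16S gene interval out of genome bounds")
  }
  seqs <- substring(genome_sequence, ssu_genes$start + 1L, ssu_genes$end)
  minus <- ssu_genes$strand == "-"
  seqs[minus] <- vapply(seqs[minus], revcomp, "")
  genome <- ssu_genes$genome_id[1]
  rep_id <- vapply(seqs, function(s) {
    min(ssu_genes$gene_id[seqs == s])
  }, "")
  stats::setNames(paste0(genome, "|", rep_id), ssu_genes$gene_id)
}

#' Copy groups for every genome in a reference set
#'
#' @param genomes Named character vector of genome sequences.
#' @param annotation Full annotation data.frame.
#' @return Named character vector over all gene ids.
#' @export
copy_groups_all <- function(genomes, annotation) {
  groups <- character(0)
  for (g in unique(annotation$genome_id)) {
    if (!g %in% names(genomes)) stop("annotated genome missing from FASTA: ", g)
    groups <- c(groups,
                identical_copy_groups(genomes[[g]],
                                      annotation[annotation$genome_id == g, ]))
  }
  groups
}

# Overlap (bp) between a record's aligned blocks and one interval.
block_overlap_bp <- function(blocks, start, end) {
  if (is.null(blocks)) return(0L)
  sum(pmax(0L, pmin(blocks[, 2L], end) - pmax(blocks[, 1L], start)))
}

#' Find the 16S gene a mapped read overlaps
#'
#' Returns the annotated gene whose interval overlaps the record's aligned
#' reference blocks by at least `min_overlap_bp` (deletions count; insertions
#' and clips do not, reference-space pileup semantics). When several genes
#' qualify the one with the largest overlap wins, ties broken by position.
#'
#' @param record One alignment record (single row of a `sam_alignments`
#'   data.frame, or an equivalent list with `genome_id` and `blocks`).
#' @param annotation Annotation data.frame.
#' @param min_overlap_bp Minimum overlap to call a read on-gene; default 1
#'   (any overlap counts).
#' @return `gene_id` or `NULL` if no gene qualifies.
#' @export
overlaps_ssu <- function(record, annotation, min_overlap_bp = 1L) {
  record <- as_record(record)
  if (!isTRUE(record$mapped)) stop("overlaps_ssu requires a mapped record")
  genes <- annotation[annotation$genome_id == record$genome_id, , drop = FALSE]
  if (!nrow(genes)) return(NULL)
  ov <- vapply(seq_len(nrow(genes)), function(i) {
    as.numeric(block_overlap_bp(record$blocks, genes$start[i], genes$end[i]))
  }, 0)
  keep <- ov >= min_overlap_bp
  if (!any(keep)) return(NULL)
  genes <- genes[keep, , drop = FALSE]
  ov <- ov[keep]
  genes$gene_id[order(-ov, genes$start)][1L]
}

as_record <- function(x) {
  if (is.data.frame(x)) {
    if (nrow(x) != 1L) stop("expected a single alignment record")
    r <- as.list(x[1L, setdiff(names(x), "blocks")])
    r$blocks <- x$blocks[[1L]]
    r
  } else {
    x
  }
}

#' Classify a read pair against the 16S annotation
#'
#' Implements the pair-concordance rule for paired-end data: a pair is
#' on-target only when both mates overlap 16S genes belonging to the same
#' identical-copy group of the same genome; pairs touching target regions in
#' any other configuration (mates on non-identical copies, on different
#' genomes, or one mate off-target/unmapped) are ambiguous; pairs with at
#' least one mapped mate and no 16S contact are off-target; pairs with both
#' mates unmapped are unmapped. Only primary alignments may be passed.
#'
#' @param fwd,rev The primary alignment records of the two mates (either may
#'   be `NULL` or unmapped).
#' @param annotation Annotation data.frame.
#' @param copy_groups Named vector from [identical_copy_groups()] /
#'   [copy_groups_all()].
#' @param min_overlap_bp Passed to [overlaps_ssu()].
#' @return List with `category` (one of `"on_target"`, `"ambiguous"`,
#'   `"off_target"`, `"unmapped"`), `assigned_gene` (copy-group id, only when
#'   on-target) and `species` (the genome id, only when on-target).
#' @export
classify_pair <- function(fwd, rev, annotation, copy_groups,
                          min_overlap_bp = 1L) {
  fwd <- if (!is.null(fwd)) as_record(fwd)
  rev <- if (!is.null(rev)) as_record(rev)
  if (!is.null(fwd) && !is.null(rev) &&
      !identical(fwd$read_id, rev$read_id)) {
    stop("mates have mismatched read ids: ", fwd$read_id, " vs ", rev$read_id)
  }
  mapped <- function(r) !is.null(r) && isTRUE(r$mapped)
  if (!mapped(fwd) && !mapped(rev)) {
    return(list(category = "unmapped", assigned_gene = NULL, species = NULL))
  }
  gene_of <- function(r) {
    if (!mapped(r)) return(NULL)
    overlaps_ssu(r, annotation, min_overlap_bp)
  }
  gf <- gene_of(fwd)
  gr <- gene_of(rev)
  if (is.null(gf) && is.null(gr)) {
    return(list(category = "off_target", assigned_gene = NULL, species = NULL))
  }
  if (is.null(gf) || is.null(gr)) {
    # one mate touches a 16S gene, the other is off-target or unmapped
    return(list(category = "ambiguous", assigned_gene = NULL, species = NULL))
  }
  same_genome <- identical(fwd$genome_id, rev$genome_id)
  if (same_genome && identical(copy_groups[[gf]], copy_groups[[gr]])) {
    return(list(category = "on_target", assigned_gene = copy_groups[[gf]],
                species = fwd$genome_id))
  }
  list(category = "ambiguous", assigned_gene = NULL, species = NULL)
}

#' Classify a single (unpaired or long) read
#'
#' @param rec Primary alignment record or `NULL`.
#' @param annotation Annotation data.frame.
#' @param min_overlap_bp Passed to [overlaps_ssu()].
#' @return Same shape as [classify_pair()].
#' @export
classify_single <- function(rec, annotation, min_overlap_bp = 1L) {
  rec <- if (!is.null(rec)) as_record(rec)
  if (is.null(rec) || !isTRUE(rec$mapped)) {
    return(list(category = "unmapped", assigned_gene = NULL, species = NULL))
  }
  g <- overlaps_ssu(rec, annotation, min_overlap_bp)
  if (is.null(g)) {
    return(list(category = "off_target", assigned_gene = NULL, species = NULL))
  }
  list(category = "on_target", assigned_gene = g, species = rec$genome_id)
}

#' Stratify an alignment set into on/off-target categories
#'
#' Secondary and supplementary alignments are discarded before
#' classification and can never influence a verdict. Reads (or pairs) are
#' classified with [classify_single()] / [classify_pair()]; per-species
#' on-target relative abundances are computed over on-target units only.
#'
#' @param alignments `sam_alignments` data.frame (e.g. from [read_sam()]).
#' @param annotation Annotation data.frame.
#' @param copy_groups Named vector from [copy_groups_all()]; required when
#'   `paired = TRUE`.
#' @param paired If `TRUE`, classify read pairs; otherwise single reads.
#' @param min_overlap_bp Passed to [overlaps_ssu()].
#' @return Object of class `stratification`: list with `counts` and
#'   `percentages` over the four categories, `n` (total reads or pairs),
#'   `per_species` (on-target counts and relative abundances), and the
#'   per-unit `classification` data.frame.
#' @export
stratify <- function(alignments, annotation, copy_groups = NULL,
                     paired = FALSE, min_overlap_bp = 1L) {
  glen <- attr(alignments, "genome_lengths")
  if (length(glen)) {
    unknown <- setdiff(unique(annotation$genome_id), names(glen))
    if (length(unknown)) {
      stop("annotation references genomes absent from alignments: ",
           paste(unknown, collapse = ", "))
    }
  }
  prim <- alignments[alignments$primary, , drop = FALSE]
  rec <- function(j) {
    list(read_id = prim$read_id[j], mapped = prim$mapped[j],
         genome_id = prim$genome_id[j], mate = prim$mate[j],
         blocks = prim$blocks[[j]])
  }
  by_read <- split(seq_len(nrow(prim)), prim$read_id)
  by_read <- by_read[unique(prim$read_id)]   # keep input order
  ids <- names(by_read)
  cls <- vector("list", length(ids))
  if (paired) {
    if (is.null(copy_groups)) stop("copy_groups required for paired mode")
    for (i in seq_along(by_read)) {
      j <- by_read[[i]]
      jf <- j[prim$mate[j] == "fwd"]
      jr <- j[prim$mate[j] == "rev"]
      cls[[i]] <- classify_pair(
        if (length(jf)) rec(jf[1L]) else NULL,
        if (length(jr)) rec(jr[1L]) else NULL,
        annotation, copy_groups, min_overlap_bp)
    }
  } else {
    for (i in seq_along(by_read)) {
      cls[[i]] <- classify_single(rec(by_read[[i]][1L]), annotation,
                                  min_overlap_bp)
    }
  }
  cat_levels <- c("on_target", "ambiguous", "off_target", "unmapped")
  category <- factor(vapply(cls, `[[`, "", "category"), levels = cat_levels)
  species <- vapply(cls, function(x) {
    if (is.null(x$species)) NA_character_ else x$species
  }, "")
  gene <- vapply(cls, function(x) {
    if (is.null(x$assigned_gene)) NA_character_ else x$assigned_gene
  }, "")
  counts <- table(category)
  on <- species[category == "on_target"]
  sp_counts <- sort(table(on), decreasing = TRUE)
  per_species <- data.frame(species = names(sp_counts),
                            n_on_target = as.integer(sp_counts),
                            relative_abundance =
                              as.numeric(sp_counts) / max(1L, sum(sp_counts)),
                            stringsAsFactors = FALSE)
  out <- list(
    counts = counts,
    percentages = as.numeric(counts) / max(1L, length(ids)) * 100,
    n = length(ids),
    per_species = per_species,
    classification = data.frame(read_id = ids,
                                category = as.character(category),
                                assigned_gene = gene, species = species,
                                stringsAsFactors = FALSE)
  )
  names(out$percentages) <- cat_levels
  class(out) <- "stratification"
  out
}

#' @export
print.stratification <- function(x, ...) {
  unit <- if (x$n == 1) "unit" else "reads/pairs"
  cat("Read stratification over", x$n, unit, "\n")
  df <- data.frame(category = names(x$percentages),
                   n = as.integer(x$counts),
                   pct = sprintf("%.2f", x$percentages))
  print(df, row.names = FALSE)
  if (nrow(x$per_species)) {
    cat("\nTop on-target species:\n")
    print(utils::head(x$per_species, 5), row.names = FALSE)
  }
  invisible(x)
}

#' Per-base coverage of one 16S gene
#'
#' Depth at gene position `p` is the number of primary-alignment reference
#' blocks covering `gene$start + p` (deletions included, insertions and
#' soft-clips excluded — pileup semantics).
#'
#' @param alignments `sam_alignments` data.frame.
#' @param gene One annotation row (data.frame or list with `genome_id`,
#'   `start`, `end`, `gene_id`).
#' @return List with `gene_id` and integer vector `depth` of length
#'   `end - start`.
#' @export
gene_coverage <- function(alignments, gene) {
  if (is.data.frame(gene)) gene <- as.list(gene[1L, ])
  width <- gene$end - gene$start
  depth <- integer(width)
  keep <- alignments$primary & alignments$mapped &
    !is.na(alignments$genome_id) & alignments$genome_id == gene$genome_id
  for (b in alignments$blocks[keep]) {
    if (is.null(b)) next
    s <- pmax(b[, 1L], gene$start) - gene$start
    e <- pmin(b[, 2L], gene$end) - gene$start
    for (j in seq_len(nrow(b))) {
      if (s[j] < e[j]) {
        idx <- (s[j] + 1L):e[j]
        depth[idx] <- depth[idx] + 1L
      }
    }
  }
  list(gene_id = gene$gene_id, depth = depth)
}
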