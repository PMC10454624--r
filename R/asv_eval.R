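#' Align one ASV against the mock reference genomes
#'
#' Local affine-gap alignment (match +2, mismatch -3, gap open 5, gap extend
#' 2 — blastn-like defaults) of the ASV against each genome, on both strands;
#' the better strand per genome is kept. Identity is matches / alignment
#' columns x 100 and query coverage is aligned query bases / query length
#' x 100. The raw Smith-Waterman score fills the ranking-score slot. Meant
#' for desk-scale instances; large precomputed hit sets are ingested with
#' [read_blast6()] instead.
#'
#' @param asv_sequence Character scalar, the ASV sequence.
#' @param genomes Named character vector of genome sequences.
#' @param min_score Minimum raw alignment score to report a hit (floors out
#'   spurious short local matches of unrelated sequence).
#' @return data.frame of hits: `genome_id`, `identity_pct`,
#'   `query_coverage_pct`, `sstart0`, `send0` (0-based half-open subject
#'   span), `sstrand`, `bitscore`.
#' @export
align_asv <- function(asv_sequence, genomes, min_score = 40) {
  stopifnot(nzchar(asv_sequence), length(genomes) >= 1)
  qlen <- nchar(asv_sequence)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  q_f <- Biostrings::DNAString(gsub("N", "A", toupper(asv_sequence)))
  q_r <- Biostrings::reverseComplement(q_f)
  rows <- list()
  for (g in names(genomes)) {
    subj <- Biostrings::DNAString(gsub("N", "A", toupper(genomes[[g]])))
    best <- NULL
    for (strand in c("+", "-")) {
      q <- if (strand == "+") q_f else q_r
      aln <- Biostrings::pairwiseAlignment(q, subj, type = "local",
                                           substitutionMatrix = mat,
                                           gapOpening = 5, gapExtension = 2)
      if (is.null(best) || Biostrings::score(aln) > best$score) {
        best <- list(aln = aln, score = Biostrings::score(aln),
                     strand = strand)
      }
    }
    if (best$score < min_score) next
    aln <- best$aln
    nmat <- Biostrings::nmatch(aln)
    nmis <- Biostrings::nmismatch(aln)
    ins <- sum(unlist(Biostrings::width(
      Biostrings::insertion(Biostrings::indel(aln)))))
    del <- sum(unlist(Biostrings::width(
      Biostrings::deletion(Biostrings::indel(aln)))))
    aln_len <- nmat + nmis + ins + del
    srng <- Biostrings::subject(aln)
    qa <- Biostrings::nchar(Biostrings::pattern(aln)) - del  # aligned query bases
    rows[[length(rows) + 1L]] <- data.frame(
      genome_id = g,
      identity_pct = nmat / aln_len * 100,
      query_coverage_pct = qa / qlen * 100,
      sstart0 = Biostrings::start(srng) - 1L,
      send0 = Biostrings::end(srng),
      sstrand = best$strand,
      bitscore = best$score,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty_hits())
  do.call(rbind, rows)
}

empty_hits <- function() {
  data.frame(genome_id = character(0), identity_pct = numeric(0),
             query_coverage_pct = numeric(0), sstart0 = integer(0),
             send0 = integer(0), sstrand = character(0),
             bitscore = numeric(0), stringsAsFactors = FALSE)
}

#' Filter hits and pick the best one for an ASV
#'
#' Drops hits below the identity or query-coverage thresholds, then returns
#' the highest-scoring survivor (ties broken by identity, then by genome id
#' lexicographically).
#'
#' @param hits data.frame of hits for one ASV ([align_asv()] layout, or
#'   [read_blast6()] rows with `sseqid`/`pident` mapped in).
#' @param min_identity Identity threshold in percent (default 97).
#' @param min_qcov Query-coverage threshold in percent (default 90).
#' @return Single-row data.frame, or `NULL` when no hit survives.
#' @export
best_hit <- function(hits, min_identity = 97, min_qcov = 90) {
  hits <- normalize_hits(hits)
  keep <- hits$identity_pct >= min_identity &
    hits$query_coverage_pct >= min_qcov
  hits <- hits[keep, , drop = FALSE]
  if (!nrow(hits)) return(NULL)
  ord <- order(-hits$bitscore, -hits$identity_pct, hits$genome_id)
  hits[ord[1L], , drop = FALSE]
}

# Accept blast6 column names as synonyms of the internal hit layout.
normalize_hits <- function(hits) {
  ren <- c(sseqid = "genome_id", pident = "identity_pct")
  for (from in names(ren)) {
    if (from %in% names(hits) && !ren[[from]] %in% names(hits)) {
      names(hits)[names(hits) == from] <- ren[[from]]
    }
  }
  need <- c("genome_id", "identity_pct", "query_coverage_pct",
            "sstart0", "send0", "bitscore")
  if (!all(need %in% names(hits))) {
    stop("hits table missing columns: ",
         paste(setdiff(need, names(hits)), collapse = ", "))
  }
  hits
}

#' Default taxonomy alias table
#'
#' Reference databases sometimes label a mock organism under a synonymous or
#' legacy name; such pairs must compare equal when scoring calls. The
#' defaults cover the classic discrepancies seen with SILVA-style
#' taxonomies: \emph{Clostridium sensu stricto 1} vs \emph{Clostridium},
#' \emph{Actinomyces} vs \emph{Schaalia}, \emph{Escherichia-Shigella} vs
#' \emph{Escherichia}.
#'
#' @return data.frame with columns `label` and `canonical`.
#' @export
default_aliases <- function() {
  data.frame(
    label = c("Clostridium sensu stricto 1", "Actinomyces",
              "Escherichia-Shigella"),
    canonical = c("Clostridium", "Schaalia", "Escherichia"),
    stringsAsFactors = FALSE)
}

# Canonical comparison form of a label under an alias table.
canonical_taxon <- function(x, aliases = default_aliases()) {
  nx <- normalize_taxon(x)
  if (!is.null(aliases) && nrow(aliases)) {
    map <- stats::setNames(normalize_taxon(aliases$canonical),
                           normalize_taxon(aliases$label))
    hit <- nx %in% names(map)
    nx[hit] <- unname(map[nx[hit]])
  }
  nx
}

#' Label one ASV against the annotated truth
#'
#' Confusion-matrix assignment: an ASV whose best hit overlaps an annotated
#' 16S gene is a true positive when its taxonomic call matches the truth
#' lineage at `rank` (after alias mapping), a false positive when the call is
#' present but wrong, and a false negative when no call was made at that
#' rank; an ASV hitting the genome outside any 16S gene is a true negative;
#' an ASV with no surviving hit is reported as `unaligned` (background
#' noise), outside the matrix.
#'
#' @param call Character scalar, the ASV's taxonomic call at `rank` (empty or
#'   `NA` = unclassified).
#' @param hit Best hit row ([best_hit()]) or `NULL`.
#' @param annotation Annotation data.frame.
#' @param truth data.frame mapping `species` (genome id) to lineage columns
#'   (`phylum`, `family`, `genus`, `species`); the mock metadata works as-is.
#' @param rank Rank at which to compare (a lineage column name).
#' @param aliases Alias table (see [default_aliases()]); `NULL` disables.
#' @return One of `"TP"`, `"FP"`, `"TN"`, `"FN"`, `"unaligned"`.
#' @export
label_asv <- function(call, hit, annotation, truth, rank = "species",
                      aliases = default_aliases()) {
  if (is.null(hit)) return("unaligned")
  genome <- hit$genome_id
  tr <- truth[truth$species == genome, , drop = FALSE]
  if (!nrow(tr)) stop("no truth lineage for genome: ", genome)
  if (!rank %in% names(tr)) stop("truth table lacks rank column: ", rank)
  genes <- annotation[annotation$genome_id == genome, , drop = FALSE]
  on_gene <- nrow(genes) > 0 &&
    any(pmin(genes$end, hit$send0) - pmax(genes$start, hit$sstart0) > 0)
  if (!on_gene) return("TN")
  call_c <- canonical_taxon(call, aliases)
  if (!nzchar(call_c)) return("FN")
  truth_c <- canonical_taxon(tr[[rank]][1L], aliases)
  if (call_c == truth_c) "TP" else "FP"
}

#' Evaluate a full set of ASVs
#'
#' Runs best-hit filtering and confusion-matrix labeling over every ASV, at
#' one rank.
#'
#' @param asvs data.frame with columns `asv_id` and the call column for
#'   `rank` (e.g. from [read_taxonomy_calls()]); an optional `read_count`
#'   column is carried through for weighting, and an optional `confidence`
#'   column for ROC analysis.
#' @param hits data.frame of hits for all ASVs, with a `qseqid` or `asv_id`
#'   column identifying the ASV ([read_blast6()] output works directly).
#' @param annotation Annotation data.frame.
#' @param truth Truth lineage table (see [label_asv()]).
#' @param rank Rank to evaluate.
#' @param min_identity,min_qcov Passed to [best_hit()].
#' @param aliases Passed to [label_asv()].
#' @return data.frame with one row per ASV: `asv_id`, `label`, `genome_id`
#'   of the best hit (`NA` if unaligned), plus `read_count` and `confidence`
#'   when present in `asvs`.
#' @export
label_asvs <- function(asvs, hits, annotation, truth, rank = "species",
                       min_identity = 97, min_qcov = 90,
                       aliases = default_aliases()) {
  if (!"asv_id" %in% names(hits) && "qseqid" %in% names(hits)) {
    hits$asv_id <- hits$qseqid
  }
  hit_split <- split(seq_len(nrow(hits)), hits$asv_id)
  labels <- character(nrow(asvs))
  genome <- rep(NA_character_, nrow(asvs))
  for (i in seq_len(nrow(asvs))) {
    id <- asvs$asv_id[i]
    h <- if (id %in% names(hit_split)) {
      best_hit(hits[hit_split[[id]], , drop = FALSE], min_identity, min_qcov)
    }
    labels[i] <- label_asv(asvs[[rank]][i], h, annotation, truth, rank,
                           aliases)
    if (!is.null(h)) genome[i] <- h$genome_id
  }
  out <- data.frame(asv_id = asvs$asv_id, label = labels, genome_id = genome,
                    stringsAsFactors = FALSE)
  for (col in c("read_count", "confidence")) {
    if (col %in% names(asvs)) out[[col]] <- asvs[[col]]
  }
  out
}

#' Aggregate labels into a confusion matrix
#'
#' @param labels Character vector over `{TP, FP, TN, FN}` (unaligned ASVs
#'   must be excluded first — they sit outside the matrix).
#' @param weights Optional nonnegative weights (e.g. per-ASV read counts);
#'   default unit weights.
#' @return Object of class `confusion_matrix`: named numeric vector
#'   `c(tp, fp, tn, fn)`.
#' @export
confusion <- function(labels, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(labels))
  stopifnot(length(weights) == length(labels), all(weights >= 0))
  if (any(!labels %in% c("TP", "FP", "TN", "FN"))) {
    stop("labels must be TP/FP/TN/FN (drop unaligned ASVs first)")
  }
  cm <- vapply(c(tp = "TP", fp = "FP", tn = "TN", fn = "FN"),
               function(l) sum(weights[labels == l]), 0)
  class(cm) <- "confusion_matrix"
  cm
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix: TP =", x[["tp"]], " FP =", x[["fp"]],
      " TN =", x[["tn"]], " FN =", x[["fn"]], "\n")
  m <- prf(x)
  cat(sprintf("precision %.2f%%  accuracy %.2f%%  recall %.2f%%\n",
              m["precision"], m["accuracy"], m["recall"]))
  invisible(x)
}

#' Precision, accuracy and recall from a confusion matrix
#'
#' All three as percentages: precision = TP/(TP+FP), recall = TP/(TP+FN),
#' accuracy = (TP+TN)/(TP+TN+FP+FN). A zero denominator yields `NA` with a
#' warning.
#'
#' @param cm `confusion_matrix` (or named vector with `tp`, `fp`, `tn`, `fn`).
#' @return Named numeric vector `c(precision, accuracy, recall)` in percent.
#' @export
prf <- function(cm) {
  tp <- cm[["tp"]]; fp <- cm[["fp"]]; tn <- cm[["tn"]]; fn <- cm[["fn"]]
  safe <- function(num, den, what) {
    if (den <= 0) {
      warning(what, " undefined (zero denominator)")
      return(NA_real_)
    }
    num / den * 100
  }
  c(precision = safe(tp, tp + fp, "precision"),
    accuracy = safe(tp + tn, tp + tn + fp + fn, "accuracy"),
    recall = safe(tp, tp + fn, "recall"))
}

#' ROC curve and AUC for ASV classification confidence
#'
#' Positives are TP-labeled ASVs, negatives FP/FN-labeled ones (both classes
#' sit on annotated 16S genes; TN and unaligned ASVs are outside the
#' positive/negative contrast). The curve sweeps the confidence threshold;
#' ties are handled by grouping equal scores, which makes the trapezoidal
#' AUC equal the (weighted) Mann-Whitney statistic with ties counted 1/2.
#'
#' @param labels Character vector of labels.
#' @param scores Numeric classifier confidences, one per label.
#' @param weights Optional nonnegative weights (read counts); default unit.
#' @return List with `curve` (data.frame `threshold`, `fpr`, `tpr`) and
#'   `auc` (`NA` when either class is absent).
#' @export
roc_auc <- function(labels, scores, weights = NULL) {
  stopifnot(length(scores) == length(labels))
  if (is.null(weights)) weights <- rep(1, length(labels))
  keep <- labels %in% c("TP", "FP", "FN") & !is.na(scores)
  labels <- labels[keep]; scores <- scores[keep]; weights <- weights[keep]
  pos <- labels == "TP"
  P <- sum(weights[pos]); N <- sum(weights[!pos])
  if (P == 0 || N == 0) {
    return(list(curve = data.frame(threshold = numeric(0), fpr = numeric(0),
                                   tpr = numeric(0)),
                auc = NA_real_))
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; w <- weights[ord]; p <- pos[ord]
  grp <- cumsum(!duplicated(s))
  tp_g <- tapply(w * p, grp, sum)
  fp_g <- tapply(w * !p, grp, sum)
  tpr <- c(0, cumsum(tp_g) / P)
  fpr <- c(0, cumsum(fp_g) / N)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(curve = data.frame(threshold = c(Inf, s[!duplicated(s)]),
                          fpr = fpr, tpr = tpr),
       auc = auc)
}
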