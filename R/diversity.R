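#' Rarefy one sample to a fixed depth
#'
#' Subsamples reads without replacement down to `depth`; a single draw whose
#' seed is the caller's responsibility (pass `seed` for a self-contained
#' reproducible draw that does not disturb the session RNG).
#'
#' @param counts Nonnegative integer vector (one sample).
#' @param depth Target depth, `0 <= depth <= sum(counts)`.
#' @param seed Optional integer seed for a local RNG scope.
#' @return Integer vector of the same length and names, summing to `depth`.
#' @export
rarefy <- function(counts, depth, seed = NULL) {
  stopifnot(all(counts >= 0), depth >= 0)
  total <- sum(counts)
  if (depth > total) {
    stop("rarefaction depth ", depth, " exceeds sample total ", total,
         " (exclude the sample upstream)")
  }
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  if (depth == total) return(counts)
  pool <- rep.int(seq_along(counts), counts)
  drawn <- sample(pool, depth, replace = FALSE)
  out <- tabulate(drawn, nbins = length(counts))
  names(out) <- names(counts)
  out
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
}

restore_rng_state <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Rarefy every column of a feature table
#'
#' @param table Features x samples count matrix.
#' @param depth Target depth; samples shallower than `depth` are dropped
#'   with a warning.
#' @param seed Optional seed (one stream across all samples).
#' @return Rarefied matrix.
#' @export
rarefy_table <- function(table, depth, seed = NULL) {
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  tot <- colSums(table)
  drop <- tot < depth
  if (any(drop)) {
    warning("dropping ", sum(drop), " sample(s) below depth ", depth, ": ",
            paste(colnames(table)[drop], collapse = ", "))
    table <- table[, !drop, drop = FALSE]
  }
  apply(table, 2L, rarefy, depth = depth)
}

#' Inverse Simpson diversity
#'
#' `1 / sum(p_i^2)` with `p_i` the relative abundances; equals the number of
#' features for a perfectly even sample, 1 for a single-feature one.
#'
#' @param counts Nonnegative vector with positive total.
#' @return Diversity number `>= 1`.
#' @export
inverse_simpson <- function(counts) {
  total <- sum(counts)
  if (total <= 0) stop("empty sample: inverse Simpson undefined")
  p <- counts / total
  1 / sum(p^2)
}

#' Pielou's evenness
#'
#' Shannon entropy (natural log, zero counts dropped) normalized by its
#' maximum `ln(S)`, with `S` the observed (nonzero) richness.
#'
#' @param counts Nonnegative vector.
#' @return Evenness in `[0, 1]`, or `NA` when fewer than two features are
#'   observed (the normalizer vanishes).
#' @export
pielou <- function(counts) {
  counts <- counts[counts > 0]
  s <- length(counts)
  if (s < 2) return(NA_real_)
  p <- counts / sum(counts)
  h <- -sum(p * log(p))
  h / log(s)
}

#' Centered log-ratio transform
#'
#' `clr(x)_i = ln(x_i / g(x))` with `g` the geometric mean, after adding a
#' pseudocount to every entry (compositional zero handling). The output sums
#' to zero and is invariant to scaling of `x`.
#'
#' @param x Nonnegative numeric vector (counts or proportions).
#' @param pseudocount Positive offset added before closure (default 1).
#' @return Numeric vector summing to 0.
#' @export
clr <- function(x, pseudocount = 1) {
  stopifnot(all(x >= 0), pseudocount > 0)
  z <- x + pseudocount
  lx <- log(z)
  lx - mean(lx)
}

#' Aitchison distance matrix of a feature table
#'
#' Euclidean distance between CLR-transformed sample compositions — the
#' natural metric of compositional data.
#'
#' @param table Features x samples count matrix (`>= 2` samples).
#' @param pseudocount Passed to [clr()].
#' @return Symmetric samples x samples distance matrix with zero diagonal.
#' @export
aitchison <- function(table, pseudocount = 1) {
  if (ncol(table) < 2) stop("need at least 2 samples")
  z <- apply(table, 2L, clr, pseudocount = pseudocount)
  d <- as.matrix(stats::dist(t(z)))
  dimnames(d) <- list(colnames(table), colnames(table))
  d
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centers `-D^2/2`, eigen-decomposes, and returns coordinates on the
#' axes with positive eigenvalues, ordered by eigenvalue; explained-variance
#' fractions are eigenvalues over the positive-eigenvalue total. For a
#' Euclidean distance matrix the configuration reproduces the input
#' distances exactly.
#'
#' @param d Symmetric distance matrix.
#' @param eps Eigenvalues below `eps * max(lambda)` are treated as null.
#' @return Object of class `pcoa_result`: list with `points` (samples x
#'   axes), `eig` (positive eigenvalues) and `explained` (fractions).
#' @export
pcoa <- function(d, eps = 1e-9) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-8)) {
    stop("distance matrix must be symmetric")
  }
  if (all(d == 0)) stop("all-zero distance matrix")
  n <- nrow(d)
  a <- -0.5 * d^2
  g <- a - matrix(rowMeans(a), n, n) - matrix(colMeans(a), n, n, byrow = TRUE) +
    mean(a)
  e <- eigen(g, symmetric = TRUE)
  keep <- e$values > eps * max(e$values)
  lam <- e$values[keep]
  pts <- e$vectors[, keep, drop = FALSE] %*% diag(sqrt(lam), nrow = length(lam))
  rownames(pts) <- rownames(d)
  colnames(pts) <- paste0("PCo", seq_along(lam))
  out <- list(points = pts, eig = lam,
              explained = lam / sum(e$values[e$values > 0]))
  class(out) <- "pcoa_result"
  out
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat("PCoA:", nrow(x$points), "samples,", length(x$eig), "positive axes\n")
  cat("explained:", paste0(sprintf("%.1f%%", 100 * utils::head(x$explained, 4)),
                           collapse = ", "), "\n")
  invisible(x)
}

#' Permutational multivariate analysis of variance (one factor)
#'
#' Partitions the total sum of squared inter-sample distances into between-
#' and within-group components; the pseudo-F statistic is referenced against
#' its permutation distribution under random relabeling, with
#' `p = (1 + #{F* >= F}) / (n_perm + 1)`. `R2` is the between-group fraction
#' of the total sum of squares.
#'
#' @param d Symmetric distance matrix.
#' @param groups Factor (or coercible) of group labels, `>= 2` groups with
#'   `>= 2` samples each.
#' @param n_perm Number of label permutations (default 999).
#' @param seed Optional seed for the permutation stream (local RNG scope).
#' @return Object of class `permanova_result`: list with `f`, `r2`,
#'   `p_value`, `df`, `n_perm`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = NULL) {
  d <- as.matrix(d)
  groups <- as.factor(groups)
  stopifnot(length(groups) == nrow(d))
  if (nlevels(droplevels(groups)) < 2) stop("need at least 2 groups")
  groups <- droplevels(groups)
  if (any(table(groups) < 2)) stop("each group needs at least 2 samples")
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  n <- nrow(d)
  a <- nlevels(groups)
  d2 <- d^2
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- function(g) {
    s <- 0
    for (lev in levels(groups)) {
      i <- which(g == lev)
      s <- s + sum(d2[i, i]) / (2 * length(i))
    }
    s
  }
  f_stat <- function(g) {
    ssw <- ss_within(g)
    ssb <- ss_total - ssw
    (ssb / (a - 1)) / (ssw / (n - a))
  }
  f_obs <- f_stat(groups)
  ssb_obs <- ss_total - ss_within(groups)
  f_perm <- vapply(seq_len(n_perm), function(k) f_stat(sample(groups)), 0)
  out <- list(f = f_obs, r2 = ssb_obs / ss_total,
              p_value = (1 + sum(f_perm >= f_obs)) / (n_perm + 1),
              df = c(between = a - 1L, within = n - a),
              n_perm = n_perm)
  class(out) <- "permanova_result"
  out
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA: pseudo-F = %.3f (df %d, %d), R2 = %.4f, p = %.4g (%d permutations)\n",
    x$f, x$df[["between"]], x$df[["within"]], x$r2, x$p_value, x$n_perm))
  invisible(x)
}

#' Pairwise PERMANOVA over all group pairs
#'
#' @inheritParams permanova
#' @return data.frame with one row per group pair: `group1`, `group2`, `f`,
#'   `r2`, `p_value`.
#' @export
pairwise_permanova <- function(d, groups, n_perm = 999, seed = NULL) {
  d <- as.matrix(d)
  groups <- droplevels(as.factor(groups))
  levs <- levels(groups)
  if (length(levs) < 2) stop("need at least 2 groups")
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  pairs <- utils::combn(levs, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    sel <- groups %in% pairs[, k]
    res <- permanova(d[sel, sel, drop = FALSE], groups[sel], n_perm)
    data.frame(group1 = pairs[1, k], group2 = pairs[2, k],
               f = res$f, r2 = res$r2, p_value = res$p_value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Paired Student's t-test
#'
#' Two-sided paired t-test (delegated to [stats::t.test()]), with a clean
#' error on zero difference variance.
#'
#' @param x,y Equal-length paired numeric vectors, `n >= 2`.
#' @return Named numeric vector `c(t, p_value)`.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 2) stop("need at least 2 pairs")
  if (stats::sd(x - y) == 0) {
    stop("zero variance of paired differences: t undefined")
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  c(t = unname(tt$statistic), p_value = tt$p.value)
}

#' Collapse a feature table to a taxonomic rank
#'
#' Sums feature counts within each taxon label.
#'
#' @param table Features x samples count matrix.
#' @param labels Character vector, one label per feature row.
#' @return Taxa x samples matrix.
#' @export
collapse_table <- function(table, labels) {
  stopifnot(length(labels) == nrow(table))
  rowsum(table, group = labels)
}
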