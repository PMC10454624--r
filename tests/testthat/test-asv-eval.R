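test_that("align_asv finds exact substrings with full identity and coverage", {
  withr::local_seed(61)
  genomes <- c(g1 = rand_dna(3000), g2 = rand_dna(3000))
  asv <- substring(genomes[["g1"]], 501, 800)
  hits <- align_asv(asv, genomes["g1"])
  expect_equal(nrow(hits), 1)
  expect_equal(hits$identity_pct, 100)
  expect_equal(hits$query_coverage_pct, 100)
  expect_equal(hits$sstart0, 500L)
  expect_equal(hits$send0, 800L)

  # reverse-complemented query still hits, on the minus strand
  rc <- align_asv(revcomp(asv), genomes["g1"])
  expect_equal(rc$sstrand, "-")
  expect_equal(rc$identity_pct, 100)

  # unrelated random sequence: nothing above the score floor
  expect_equal(nrow(align_asv(rand_dna(300), genomes)), 0)
})

test_that("align_asv identity tracks a planted substitution rate", {
  withr::local_seed(62)
  genomes <- c(g1 = rand_dna(2000))
  asv <- substring(genomes[["g1"]], 301, 600)  # 300 bp
  n_mut <- 6                                   # 2% substitutions
  for (i in sample(300, n_mut)) asv <- sub_at(asv, i)
  hits <- align_asv(asv, genomes)
  expect_equal(hits$identity_pct, (300 - n_mut) / 300 * 100, tolerance = 0.01)
  expect_equal(hits$query_coverage_pct, 100, tolerance = 2)
})

test_that("best_hit enforces thresholds then ranks by score, identity, id", {
  hit <- function(genome, id, qcov, bit) {
    data.frame(genome_id = genome, identity_pct = id,
               query_coverage_pct = qcov, sstart0 = 0L, send0 = 100L,
               bitscore = bit, stringsAsFactors = FALSE)
  }
  expect_null(best_hit(hit("g1", 96.9, 100, 500)))     # identity boundary
  expect_null(best_hit(hit("g1", 99, 89.9, 500)))      # coverage boundary
  expect_null(best_hit(empty_hits()))
  # higher-score hit fails qcov -> the lower-score survivor wins
  h <- rbind(hit("g1", 98, 95, 500), hit("g2", 99, 89, 600))
  expect_equal(best_hit(h)$genome_id, "g1")
  # equal scores: identity breaks the tie, then genome id
  h <- rbind(hit("g1", 98, 95, 500), hit("g2", 99, 95, 500))
  expect_equal(best_hit(h)$genome_id, "g2")
  h <- rbind(hit("g2", 98, 95, 500), hit("g1", 98, 95, 500))
  expect_equal(best_hit(h)$genome_id, "g1")
})

truth_table <- function() {
  data.frame(species = c("genomeA", "genomeB"),
             phylum = c("PhyA", "PhyB"), family = c("FamA", "FamB"),
             genus = c("Clostridium", "Schaalia"),
             stringsAsFactors = FALSE)
}

test_that("label_asv implements the confusion-matrix definitions", {
  ref <- tiny_reference()
  truth <- truth_table()
  on_hit <- data.frame(genome_id = "genomeA", identity_pct = 99,
                       query_coverage_pct = 100, sstart0 = 210L,
                       send0 = 480L, bitscore = 500)
  off_hit <- data.frame(genome_id = "genomeA", identity_pct = 99,
                        query_coverage_pct = 100, sstart0 = 0L, send0 = 150L,
                        bitscore = 500)
  ann <- ref$annotation
  expect_equal(label_asv("genomeA", on_hit, ann, truth, "species"), "TP")
  expect_equal(label_asv("genomeB", on_hit, ann, truth, "species"), "FP")
  expect_equal(label_asv("", on_hit, ann, truth, "species"), "FN")
  expect_equal(label_asv(NA, on_hit, ann, truth, "species"), "FN")
  expect_equal(label_asv("anything", off_hit, ann, truth, "species"), "TN")
  expect_equal(label_asv("genomeA", NULL, ann, truth, "species"), "unaligned")
  bad <- on_hit; bad$genome_id <- "genomeX"
  expect_error(label_asv("x", bad, ann, truth, "species"), "no truth lineage")
})

test_that("reference-taxonomy aliases compare equal at genus rank", {
  ref <- tiny_reference()
  truth <- truth_table()
  on_hit <- data.frame(genome_id = "genomeA", identity_pct = 99,
                       query_coverage_pct = 100, sstart0 = 210L,
                       send0 = 480L, bitscore = 500)
  expect_equal(label_asv("Clostridium sensu stricto 1", on_hit,
                         ref$annotation, truth, "genus"), "TP")
  on_hit$genome_id <- "genomeB"
  on_hit$sstart0 <- 110L; on_hit$send0 <- 390L
  expect_equal(label_asv("Actinomyces", on_hit, ref$annotation, truth,
                         "genus"), "TP")
  # alias mapping disabled -> mismatch
  expect_equal(label_asv("Actinomyces", on_hit, ref$annotation, truth,
                         "genus", aliases = NULL), "FP")
})

test_that("confusion tallies labels with unit and read weights", {
  expect_equal(unclass(confusion(c("TP", "TP", "FP", "TN", "FN"))),
               c(tp = 2, fp = 1, tn = 1, fn = 1))
  expect_equal(unclass(confusion(c("TP", "FP"), weights = c(10, 5))),
               c(tp = 10, fp = 5, tn = 0, fn = 0))
  expect_error(confusion(c("TP", "unaligned")), "unaligned")

  withr::local_seed(63)
  labels <- sample(c("TP", "FP", "TN", "FN"), 500, TRUE)
  w <- runif(500, 0, 20)
  cm <- confusion(labels, w)
  for (l in c("TP", "FP", "TN", "FN")) {
    expect_equal(cm[[tolower(l)]], sum(w[labels == l]))
  }
})

test_that("precision/accuracy/recall match closed forms", {
  expect_equal(unname(prf(c(tp = 1, fp = 0, tn = 0, fn = 0))),
               c(100, 100, 100))
  expect_equal(unname(prf(c(tp = 50, fp = 50, tn = 0, fn = 0))),
               c(50, 50, 100))
  w <- testthat::capture_warnings(m <- prf(c(tp = 0, fp = 0, tn = 5, fn = 0)))
  expect_length(w, 2)                       # precision and recall both warn
  expect_match(w, "undefined", all = TRUE)
  expect_true(is.na(m[["precision"]]))
  expect_equal(m[["accuracy"]], 100)
  expect_true(is.na(m[["recall"]]))
  # unit vs read weights agree when all read counts are equal
  labels <- c("TP", "TP", "FP", "FN", "TN")
  expect_equal(prf(confusion(labels)),
               prf(confusion(labels, rep(7, 5))))
})

test_that("AUC equals the Mann-Whitney normalization (brute-force oracle)", {
  # perfect separation and the degenerate single-threshold case
  expect_equal(roc_auc(c("TP", "TP", "FP", "FP"), c(0.9, 0.8, 0.2, 0.1))$auc, 1)
  expect_equal(roc_auc(c("TP", "FP", "FN"), c(0.5, 0.5, 0.5))$auc, 0.5)
  expect_true(is.na(roc_auc(c("TP", "TP"), c(0.5, 0.7))$auc))

  withr::local_seed(64)
  n <- 200
  labels <- sample(c("TP", "FP", "FN"), n, TRUE, prob = c(0.5, 0.3, 0.2))
  scores <- round(runif(n), 2)   # rounding forces ties
  auc <- roc_auc(labels, scores)$auc
  pos <- scores[labels == "TP"]
  neg <- scores[labels != "TP"]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  expect_equal(auc, mean(cmp), tolerance = 1e-12)
})

test_that("AUC of random scores is near 1/2 and pROC agrees on one instance", {
  withr::local_seed(65)
  n <- 2000
  labels <- sample(c("TP", "FP"), n, TRUE)
  scores <- runif(n)
  expect_lt(abs(roc_auc(labels, scores)$auc - 0.5), 0.05)

  skip_if_not_installed("pROC")
  small <- 150
  l2 <- sample(c("TP", "FP"), small, TRUE)
  s2 <- round(runif(small), 1)
  ours <- roc_auc(l2, s2)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(
    response = l2 == "TP", predictor = s2, quiet = TRUE, direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-9)
})

test_that("label partition conserves ASV counts end to end", {
  b <- tiny_bundle()
  sim <- simulate_asvs(b)
  lab <- label_asvs(sim$asvs, sim$hits, b$annotation, b$metadata,
                    rank = "species")
  expect_equal(nrow(lab), nrow(sim$asvs))
  expect_true(all(lab$label %in% c("TP", "FP", "TN", "FN", "unaligned")))
  cm <- confusion(lab$label[lab$label != "unaligned"])
  expect_equal(sum(unclass(cm)), sum(lab$label != "unaligned"))
})
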