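test_that("identical copies group together; near-identical do not", {
  ref <- tiny_reference()
  grpA <- identical_copy_groups(ref$genomes[["genomeA"]],
                                ref$annotation[1:3, ])
  # ssuA1/ssuA2 byte-identical, ssuA3 one substitution away
  expect_equal(unname(grpA["ssuA1"]), unname(grpA["ssuA2"]))
  expect_false(grpA[["ssuA3"]] == grpA[["ssuA1"]])
  # grouping is per genome: genomeB's identical sequence stays separate
  expect_false(ref$groups[["ssuB1"]] == ref$groups[["ssuA1"]])
})

test_that("minus-strand copies are reverse-complemented before comparison", {
  withr::local_seed(33)
  gene <- rand_dna(100)
  genome <- paste0(rand_dna(50), gene, rand_dna(50), revcomp(gene),
                   rand_dna(50))
  ann <- data.frame(genome_id = "g", start = c(50L, 200L),
                    end = c(150L, 300L), gene_id = c("f", "r"),
                    strand = c("+", "-"), stringsAsFactors = FALSE)
  grp <- identical_copy_groups(genome, ann)
  expect_equal(unname(grp["f"]), unname(grp["r"]))
})

test_that("planted identical and mutated copies recover the expected partition", {
  withr::local_seed(34)
  gene <- rand_dna(200)
  k <- 3L; m <- 2L
  copies <- c(rep(gene, k), vapply(1:m, function(i) sub_at(gene, i), ""))
  spacer <- function() rand_dna(30)
  genome <- paste0(spacer(),
                   paste0(vapply(copies, function(s) paste0(s, spacer()), ""),
                          collapse = ""))
  starts <- 30L + (seq_along(copies) - 1L) * 230L
  ann <- data.frame(genome_id = "g", start = starts, end = starts + 200L,
                    gene_id = sprintf("c%d", seq_along(copies)),
                    strand = "+", stringsAsFactors = FALSE)
  grp <- identical_copy_groups(genome, ann)
  sizes <- sort(unname(table(grp)), decreasing = TRUE)
  expect_equal(as.integer(sizes), c(k, 1L, 1L))
  expect_error(identical_copy_groups(substr(genome, 1, 100), ann),
               "out of genome bounds")
})

test_that("overlaps_ssu applies the min-overlap boundary exactly", {
  ann <- data.frame(genome_id = "g", start = 100L, end = 200L,
                    gene_id = "ssuA", strand = "+", stringsAsFactors = FALSE)
  rec <- function(s, e) list(read_id = "r", mapped = TRUE, genome_id = "g",
                             blocks = cbind(start = s, end = e))
  expect_equal(overlaps_ssu(rec(120L, 180L), ann), "ssuA")   # containment
  expect_null(overlaps_ssu(rec(0L, 50L), ann))               # outside
  m <- 5L
  # overlap exactly m-1 -> null; exactly m -> gene (boundary enumeration)
  expect_null(overlaps_ssu(rec(100L - 50L, 100L + m - 1L), ann,
                           min_overlap_bp = m))
  expect_equal(overlaps_ssu(rec(100L - 50L, 100L + m), ann,
                            min_overlap_bp = m), "ssuA")
  expect_null(overlaps_ssu(rec(200L - m + 1L, 260L), ann, min_overlap_bp = m))
  expect_equal(overlaps_ssu(rec(200L - m, 260L), ann, min_overlap_bp = m),
               "ssuA")
})

test_that("classify_pair covers all mate-placement combinations", {
  ref <- tiny_reference()
  ann <- ref$annotation
  grp <- ref$groups
  rec <- function(genome, s, e, mate, mapped = TRUE) {
    list(read_id = "p", mapped = mapped, genome_id = genome, mate = mate,
         blocks = if (mapped) cbind(start = s, end = e))
  }
  on <- function(gene, mate) {
    g <- ann[ann$gene_id == gene, ]
    rec(g$genome_id, g$start + 10L, g$start + 110L, mate)
  }
  offrec <- function(mate) rec("genomeA", 0L, 100L, mate)   # intergenic
  unm <- function(mate) rec(NA, NA, NA, mate, mapped = FALSE)

  cls <- function(f, r) classify_pair(f, r, ann, grp)$category

  expect_equal(cls(on("ssuA1", "fwd"), on("ssuA1", "rev")), "on_target")
  # mates on different byte-identical copies: still on-target
  res <- classify_pair(on("ssuA1", "fwd"), on("ssuA2", "rev"), ann, grp)
  expect_equal(res$category, "on_target")
  expect_equal(res$species, "genomeA")
  # non-identical copies of the same genome -> ambiguous
  expect_equal(cls(on("ssuA1", "fwd"), on("ssuA3", "rev")), "ambiguous")
  # identical sequence on another genome -> ambiguous (per-genome rule)
  expect_equal(cls(on("ssuA1", "fwd"), on("ssuB1", "rev")), "ambiguous")
  # one mate on-gene, other off-target or unmapped -> ambiguous
  expect_equal(cls(on("ssuA1", "fwd"), offrec("rev")), "ambiguous")
  expect_equal(cls(on("ssuA1", "fwd"), unm("rev")), "ambiguous")
  expect_equal(cls(unm("fwd"), on("ssuB1", "rev")), "ambiguous")
  # no 16S contact but mapped -> off-target; both unmapped -> unmapped
  expect_equal(cls(offrec("fwd"), offrec("rev")), "off_target")
  expect_equal(cls(offrec("fwd"), unm("rev")), "off_target")
  expect_equal(cls(unm("fwd"), unm("rev")), "unmapped")

  bad <- rec("genomeA", 0L, 10L, "rev"); bad$read_id <- "other"
  expect_error(classify_pair(on("ssuA1", "fwd"), bad, ann, grp),
               "mismatched read ids")
})

test_that("classify_single stratifies long reads", {
  ref <- tiny_reference()
  g <- ref$annotation[1, ]
  rec <- list(read_id = "r", mapped = TRUE, genome_id = "genomeA",
              blocks = cbind(start = g$start - 10L, end = g$end + 10L))
  expect_equal(classify_single(rec, ref$annotation)$category, "on_target")
  rec$blocks <- cbind(start = 0L, end = 100L)
  expect_equal(classify_single(rec, ref$annotation)$category, "off_target")
  expect_equal(classify_single(NULL, ref$annotation)$category, "unmapped")
})

test_that("stratification conserves counts and ignores secondary alignments", {
  b <- tiny_bundle()
  grp <- copy_groups_all(b$genomes, b$annotation)
  sim <- simulate_reads(b, "short_pe", n_reads = 300)
  s <- stratify(sim$alignments, b$annotation, grp, paired = TRUE)
  expect_equal(sum(s$counts), 300)
  expect_equal(sum(s$percentages), 100, tolerance = 1e-6)
  expect_equal(unname(s$counts["on_target"]), 300L)  # error-free, all on-gene

  # inject decoy secondary/supplementary alignments on intergenic loci
  decoy <- sim$alignments[1:20, ]
  decoy$flag <- decoy$flag + 256L
  decoy$primary <- FALSE
  decoy$start <- 0L
  decoy$end <- 50L
  decoy$blocks <- rep(list(cbind(start = 0L, end = 50L)), 20)
  with_decoys <- rbind(sim$alignments, decoy)
  class(with_decoys) <- class(sim$alignments)
  attr(with_decoys, "genome_lengths") <- attr(sim$alignments, "genome_lengths")
  s2 <- stratify(with_decoys, b$annotation, grp, paired = TRUE)
  expect_equal(as.integer(s2$counts), as.integer(s$counts))
})

test_that("all-unmapped input yields 100% unmapped", {
  p <- make_sam(list(
    list(read_id = "r1", flag = 77L, genome = "*", pos0 = 0L, cigar = "*"),
    list(read_id = "r1", flag = 141L, genome = "*", pos0 = 0L, cigar = "*")
  ), c(g1 = 1000L))
  al <- read_sam(p)
  ann <- data.frame(genome_id = "g1", start = 0L, end = 100L,
                    gene_id = "ssu", strand = "+", stringsAsFactors = FALSE)
  s <- stratify(al, ann, c(ssu = "g1|ssu"), paired = TRUE)
  expect_equal(unname(s$percentages["unmapped"]), 100)
})

test_that("single-read mixtures recover the planted on/off-target fractions", {
  b <- tiny_bundle()
  b$config$off_target_fraction <- 0.2
  n <- 1500
  sim <- simulate_reads(b, "long", n_reads = n)
  s <- stratify(sim$alignments, b$annotation, paired = FALSE)
  p_hat <- s$percentages[["off_target"]] / 100
  se <- sqrt(0.2 * 0.8 / n)
  expect_lt(abs(p_hat - 0.2), 3 * se + 1e-9)
  expect_equal(s$percentages[["on_target"]] / 100, 1 - p_hat,
               tolerance = 1e-9)
  # category assignments agree with the simulator's truth labels
  truth <- sim$truth[match(s$classification$read_id, sim$truth$read_id), ]
  expect_equal(s$classification$category, truth$category)
})

test_that("gene coverage equals a brute-force per-position recount", {
  ref <- tiny_reference()
  gene <- ref$annotation[1, ]
  withr::local_seed(55)
  n <- 60
  pos0 <- sample(0:(nchar(ref$genomes[["genomeA"]]) - 120), n, TRUE)
  recs <- lapply(seq_len(n), function(i) {
    list(read_id = paste0("r", i), flag = 0L, genome = "genomeA",
         pos0 = pos0[i], cigar = "120M")
  })
  al <- read_sam(make_sam(recs, setNames(nchar(ref$genomes), names(ref$genomes))))
  cov <- gene_coverage(al, gene)
  # naive oracle: count reads covering each genomic position
  oracle <- vapply(gene$start:(gene$end - 1L), function(p) {
    sum(pos0 <= p & p < pos0 + 120L)
  }, 0L)
  expect_equal(cov$depth, oracle)
  expect_equal(sum(cov$depth),
               sum(pmax(0, pmin(pos0 + 120L, gene$end) - pmax(pos0, gene$start))))

  # no overlapping reads -> all zero; one spanning read -> constant 1
  empty <- read_sam(make_sam(list(list(read_id = "r", flag = 0L,
                                       genome = "genomeB", pos0 = 0L,
                                       cigar = "50M")),
                             c(genomeB = nchar(ref$genomes[["genomeB"]]))))
  expect_true(all(gene_coverage(empty, ref$annotation[4, ])$depth[51:300] == 0))
  span <- read_sam(make_sam(list(list(read_id = "r", flag = 0L,
                                      genome = "genomeA", pos0 = gene$start,
                                      cigar = "300M")),
                            c(genomeA = nchar(ref$genomes[["genomeA"]]))))
  expect_equal(gene_coverage(span, gene)$depth, rep(1L, 300))
})
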