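# Small in-code fixtures shared across the suite.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# Write SAM text from a record spec and return the path.
# records: list of lists with read_id, flag, genome, pos0 (0-based), cigar.
make_sam <- function(records, genome_lengths,
                     path = withr::local_tempfile(fileext = ".sam",
                                                  .local_envir = parent.frame())) {
  lines <- c("@HD\tVN:1.6",
             sprintf("@SQ\tSN:%s\tLN:%d", names(genome_lengths),
                     as.integer(genome_lengths)))
  for (r in records) {
    mapped <- !bitwAnd(r$flag, 4L)
    lines <- c(lines, sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t*\t*",
                              r$read_id, r$flag,
                              if (mapped) r$genome else "*",
                              if (mapped) r$pos0 + 1L else 0L,
                              if (mapped) r$cigar else "*"))
  }
  writeLines(lines, path)
  path
}

# A two-genome fixture: genomeA carries three 16S copies (ssuA1 and ssuA2
# byte-identical, ssuA3 one substitution away), genomeB one copy identical in
# sequence to A's (cross-genome identity must NOT merge groups).
tiny_reference <- function(gene_len = 300L, seed = 42L) {
  withr::local_seed(seed)
  gene <- rand_dna(gene_len)
  gene_mut <- sub_at(gene, 7L)
  gA <- paste0(rand_dna(200), gene, rand_dna(150), gene, rand_dna(150),
               gene_mut, rand_dna(200))
  gB <- paste0(rand_dna(100), gene, rand_dna(100))
  s1 <- 200L; s2 <- s1 + gene_len + 150L; s3 <- s2 + gene_len + 150L
  ann <- data.frame(
    genome_id = c("genomeA", "genomeA", "genomeA", "genomeB"),
    start = c(s1, s2, s3, 100L),
    end = c(s1, s2, s3, 100L) + gene_len,
    gene_id = c("ssuA1", "ssuA2", "ssuA3", "ssuB1"),
    strand = "+", stringsAsFactors = FALSE)
  genomes <- c(genomeA = gA, genomeB = gB)
  list(genomes = genomes, annotation = ann, gene = gene,
       groups = copy_groups_all(genomes, ann))
}

# Substitute position i (1-based) with a different base.
sub_at <- function(seq, i) {
  ch <- substring(seq, i, i)
  repl <- setdiff(c("A", "C", "G", "T"), ch)[1]
  paste0(substring(seq, 1, i - 1), repl, substring(seq, i + 1))
}

# Tiny simulated community for pipeline-level tests (fast to build).
tiny_bundle <- function(seed = 7L, ...) {
  args <- utils::modifyList(
    list(n_species = 5, genome_length = c(15000L, 25000L),
         ssu_copies = c(2L, 4L), seed = seed),
    list(...))
  simulate_mock(do.call(sim_config, args))
}
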