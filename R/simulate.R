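#' Simulation configuration for a synthetic mock community
#'
#' Bundles every knob of the generator: an even genomic-mass mock of
#' `n_species` members with variable genome lengths and 16S copy numbers
#' (a configurable fraction of copies byte-identical within a genome, the
#' rest mutated at one or more sites), short paired-end or full-length
#' reads with truth alignments, ASVs with sequence noise and per-rank call
#' error, and multi-sample count tables with group structure. All 16S genes
#' descend from one shared ancestral sequence, so low `divergence` between
#' designated species reproduces co-generic near-identity.
#'
#' @param n_species Number of mock members (default 20, the classic even-mix
#'   design).
#' @param genome_length Two-element range of genome lengths in bp. Compact
#'   desk-scale genomes; only the `ssu_copies / length` ratio feeds the
#'   expected profile.
#' @param ssu_copies Two-element range of per-genome 16S copy counts.
#' @param identical_copy_fraction Fraction of a genome's copies that are
#'   byte-identical to its canonical 16S sequence.
#' @param divergence Per-site substitution rate between a species' 16S gene
#'   and the shared ancestral sequence.
#' @param ssu_length Length of the 16S gene, bp.
#' @param read_length Short-read length, bp.
#' @param fragment_range Insert-size range for paired-end fragments, bp.
#' @param long_read_range Length window of full-length reads, bp.
#' @param n_reads Number of reads (or pairs) per simulated run.
#' @param read_error Per-base substitution error rate applied to reads.
#' @param off_target_fraction Fraction of reads drawn from intergenic loci.
#' @param asvs_per_gene ASVs generated per annotated 16S copy.
#' @param asv_length ASV window length, bp.
#' @param asv_noise Per-site substitution rate applied to ASV sequences.
#' @param call_error Per-rank probability of an incorrect taxonomic call
#'   (named vector over phylum/family/genus/species, or a scalar recycled).
#' @param blank_fraction Fraction of call errors that are blanks
#'   (unclassified) rather than wrong labels; default 0.5.
#' @param n_samples Number of samples in simulated count tables.
#' @param depth Sequencing depth per simulated sample.
#' @param dirichlet_conc Dirichlet concentration of per-sample compositions
#'   around their group mean (larger = tighter).
#' @param group_separation Log-scale perturbation between group mean
#'   compositions; 0 = identically distributed groups (null).
#' @param seed Default seed used by the simulators.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_species = 20,
                       genome_length = c(30000L, 90000L),
                       ssu_copies = c(1L, 10L),
                       identical_copy_fraction = 0.5,
                       divergence = 0.10,
                       ssu_length = 1500L,
                       read_length = 250L,
                       fragment_range = c(380L, 460L),
                       long_read_range = c(1000L, 1600L),
                       n_reads = 2000L,
                       read_error = 0.001,
                       off_target_fraction = 0,
                       asvs_per_gene = 2L,
                       asv_length = 420L,
                       asv_noise = 0.01,
                       call_error = c(phylum = 0.02, family = 0.05,
                                      genus = 0.08, species = 0.15),
                       blank_fraction = 0.5,
                       n_samples = 12L,
                       depth = 50000L,
                       dirichlet_conc = 200,
                       group_separation = 1,
                       seed = 20230901L) {
  cfg <- as.list(environment())
  fr <- c("identical_copy_fraction", "divergence", "read_error",
          "off_target_fraction", "asv_noise", "blank_fraction")
  for (f in fr) {
    if (any(cfg[[f]] < 0) || any(cfg[[f]] > 1)) stop(f, " must lie in [0,1]")
  }
  if (any(cfg$call_error < 0) || any(cfg$call_error > 1)) {
    stop("call_error must lie in [0,1]")
  }
  ranks <- c("phylum", "family", "genus", "species")
  if (length(cfg$call_error) == 1L) {
    cfg$call_error <- stats::setNames(rep(cfg$call_error, 4), ranks)
  }
  stopifnot(all(ranks %in% names(cfg$call_error)),
            diff(cfg$genome_length) >= 0, diff(cfg$ssu_copies) >= 0,
            cfg$n_species >= 1, cfg$ssu_length > cfg$read_length)
  class(cfg) <- "sim_config"
  cfg
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Uniform integer draw on [lo, hi]; safe when lo == hi (unlike sample(lo:hi)).
sample_range <- function(lo, hi) lo + sample.int(hi - lo + 1L, 1L) - 1L

# Substitute each site independently with probability rate (always to a
# different base). Returns list(seq, n_sub).
mutate_seq <- function(seq, rate, at_least_one = FALSE) {
  chars <- strsplit(seq, NULL)[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  if (at_least_one && !length(hit)) hit <- sample.int(length(chars), 1)
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  }
  list(seq = paste(chars, collapse = ""), n_sub = length(hit))
}

#' Simulate a mock community with annotated 16S copies
#'
#' Generates, per species, a random genome hosting its 16S copies at
#' non-overlapping loci on random strands: a configured fraction of copies
#' byte-identical to the species' canonical 16S sequence, the rest mutated
#' at one or more sites (guaranteed pairwise distinct). Species 16S
#' sequences descend from one shared ancestor under `divergence`. Output is
#' deterministic under the configured seed.
#'
#' @param config A [sim_config()].
#' @param seed Seed override (defaults to `config$seed`).
#' @return Object of class `truth_bundle`: list with `genomes` (named
#'   character), `annotation` ([read_bed()] layout), `metadata` (mock
#'   metadata with lineage columns), `gene_seqs` (canonical 16S sequence per
#'   species) and `config`.
#' @export
simulate_mock <- function(config = sim_config(), seed = config$seed) {
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  n <- config$n_species
  ancestral <- random_dna(config$ssu_length)
  species <- sprintf("Species_%02d", seq_len(n))
  # two co-generic pairs when the community is large enough, rest unique
  genus_idx <- seq_len(n)
  if (n >= 4) genus_idx[2] <- 1
  if (n >= 5) genus_idx[4] <- 3
  genus <- sprintf("Genus_%02d", genus_idx)
  family <- sprintf("Family_%02d", genus_idx)
  phylum <- sprintf("Phylum_%02d", ((genus_idx - 1) %% 5) + 1)
  lengths_bp <- integer(n)
  copies <- integer(n)
  genomes <- character(n)
  ann <- list()
  gene_seqs <- character(n)
  for (i in seq_len(n)) {
    gene_seqs[i] <- mutate_seq(ancestral, config$divergence)$seq
    L <- sample_range(config$genome_length[1], config$genome_length[2])
    k <- sample_range(config$ssu_copies[1], config$ssu_copies[2])
    if (k * config$ssu_length * 2 > L) {
      stop("genome too short to host ", k, " 16S copies")
    }
    # one copy per equal-width segment, at a random in-segment offset
    seg <- floor(L / k)
    starts <- integer(k)
    copy_seq <- character(k)
    n_ident <- round(config$identical_copy_fraction * k)
    for (j in seq_len(k)) {
      starts[j] <- (j - 1L) * seg +
        sample.int(seg - config$ssu_length, 1)
      copy_seq[j] <- if (j <= n_ident) {
        gene_seqs[i]
      } else {
        # mutate at site j (unique per copy) plus random extras: pairwise distinct
        chars <- strsplit(gene_seqs[i], NULL)[[1]]
        chars[j] <- sample(setdiff(c("A", "C", "G", "T"), chars[j]), 1)
        mutate_seq(paste(chars, collapse = ""), 0.002)$seq
      }
    }
    strand <- sample(c("+", "-"), k, replace = TRUE)
    genome_chars <- strsplit(random_dna(L), NULL)[[1]]
    for (j in seq_len(k)) {
      s <- if (strand[j] == "-") revcomp(copy_seq[j]) else copy_seq[j]
      genome_chars[(starts[j] + 1L):(starts[j] + config$ssu_length)] <-
        strsplit(s, NULL)[[1]]
    }
    genomes[i] <- paste(genome_chars, collapse = "")
    lengths_bp[i] <- L
    copies[i] <- k
    ann[[i]] <- data.frame(genome_id = species[i],
                           start = as.integer(starts),
                           end = as.integer(starts + config$ssu_length),
                           gene_id = sprintf("%s_ssu%02d", species[i],
                                             seq_len(k)),
                           strand = strand, stringsAsFactors = FALSE)
  }
  names(genomes) <- species
  bundle <- list(
    genomes = genomes,
    annotation = do.call(rbind, ann),
    metadata = data.frame(species = species, phylum = phylum,
                          family = family, genus = genus,
                          genome_length_bp = lengths_bp,
                          ssu_copies = copies, stringsAsFactors = FALSE),
    gene_seqs = stats::setNames(gene_seqs, species),
    config = config)
  class(bundle) <- "truth_bundle"
  validate_annotation(bundle$annotation, nchar(genomes))
  bundle
}

#' @export
print.truth_bundle <- function(x, ...) {
  cat("Synthetic mock community:", length(x$genomes), "species,",
      nrow(x$annotation), "annotated 16S copies\n")
  cat("genome lengths:", min(x$metadata$genome_length_bp), "-",
      max(x$metadata$genome_length_bp), "bp; copies:",
      min(x$metadata$ssu_copies), "-", max(x$metadata$ssu_copies), "\n")
  invisible(x)
}

#' Write a truth bundle's files to a directory
#'
#' Emits `genomes.fasta`, `ssu.bed` and `mock_metadata.tsv`.
#'
#' @param bundle A `truth_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_truth_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(bundle$genomes, file.path(dir, "genomes.fasta"))
  write_bed(bundle$annotation, file.path(dir, "ssu.bed"))
  write_mock_metadata(bundle$metadata, file.path(dir, "mock_metadata.tsv"))
  invisible(dir)
}

# Intergenic intervals (0-based half-open) of one genome.
intergenic_intervals <- function(bundle, genome) {
  L <- nchar(bundle$genomes[[genome]])
  g <- bundle$annotation[bundle$annotation$genome_id == genome, , drop = FALSE]
  g <- g[order(g$start), , drop = FALSE]
  starts <- c(0L, g$end)
  ends <- c(g$start, L)
  keep <- ends - starts > 0
  cbind(start = starts[keep], end = ends[keep])
}

#' Simulate reads with truth alignments
#'
#' Draws on-target reads from the annotated 16S genes with species
#' probabilities equal to the even genomic-mass [expected_profile()] of the
#' bundle's metadata (copy chosen uniformly within the species), and a
#' configured fraction of off-target reads from intergenic loci. Applies
#' per-base substitution errors and emits the generating locus as a truth
#' alignment, so no external aligner is needed downstream.
#'
#' @param bundle A `truth_bundle` from [simulate_mock()].
#' @param mode `"short_pe"` (paired-end) or `"long"` (full-length single
#'   reads, lengths inside the configured window).
#' @param n_reads Number of reads or pairs (default from config).
#' @param seed Seed (default from config, offset per mode).
#' @return List with `alignments` (a `sam_alignments` data.frame identical
#'   in shape to [read_sam()] output, including a `seq` column) and `truth`
#'   (data.frame `read_id`, `category`, `species`, `gene_id`).
#' @export
simulate_reads <- function(bundle, mode = c("short_pe", "long"),
                           n_reads = bundle$config$n_reads,
                           seed = bundle$config$seed + 1L) {
  mode <- match.arg(mode)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  cfg <- bundle$config
  prof <- expected_profile(bundle$metadata)
  if (n_reads == 0) {
    al <- empty_sam_alignments()
    attr(al, "genome_lengths") <- nchar(bundle$genomes)
    return(list(alignments = al,
                truth = data.frame(read_id = character(0),
                                   category = character(0),
                                   species = character(0),
                                   gene_id = character(0))))
  }
  off <- stats::runif(n_reads) < cfg$off_target_fraction
  sp <- sample(prof$species, n_reads, replace = TRUE, prob = prof$expected_ra)
  rows <- vector("list", 2L * n_reads)
  truth <- vector("list", n_reads)
  nr <- 0L
  take <- function(genome, s, e) {
    mutate_seq(substring(bundle$genomes[[genome]], s + 1L, e),
               cfg$read_error)$seq
  }
  for (i in seq_len(n_reads)) {
    rid <- sprintf("read_%06d", i)
    if (off[i]) {
      genome <- sample(names(bundle$genomes), 1)
      iv <- intergenic_intervals(bundle, genome)
      w <- iv[, 2] - iv[, 1]
      span <- if (mode == "short_pe") max(cfg$fragment_range) else
        max(cfg$long_read_range)
      ok <- w >= span
      if (!any(ok)) stop("no intergenic interval can host an off-target read")
      j <- sample(rep(which(ok), 2), 1)   # rep(): stable when one interval
      lo <- iv[j, 1]; hi <- iv[j, 2]
      gene <- NA_character_
      category <- "off_target"
      gstart <- lo + sample.int(hi - lo - span + 1L, 1) - 1L
      gend <- gstart + span
      sp_i <- genome
    } else {
      sp_i <- sp[i]
      genes <- bundle$annotation[bundle$annotation$genome_id == sp_i, ,
                                 drop = FALSE]
      j <- sample.int(nrow(genes), 1)
      gene <- genes$gene_id[j]
      category <- "on_target"
      genome <- sp_i
      gstart <- genes$start[j]
      gend <- genes$end[j]
    }
    if (mode == "short_pe") {
      frag <- sample_range(cfg$fragment_range[1], cfg$fragment_range[2])
      frag <- min(frag, gend - gstart)
      fs <- gstart + sample.int(gend - gstart - frag + 1L, 1) - 1L
      rl <- min(cfg$read_length, frag)
      f_start <- fs; f_end <- fs + rl
      r_start <- fs + frag - rl; r_end <- fs + frag
      rows[[nr + 1L]] <- list(read_id = rid, flag = 99L, genome_id = genome,
                              start = f_start, end = f_end,
                              cigar = paste0(rl, "M"),
                              mate = "fwd", reverse = FALSE,
                              seq = take(genome, f_start, f_end))
      rows[[nr + 2L]] <- list(read_id = rid, flag = 147L, genome_id = genome,
                              start = r_start, end = r_end,
                              cigar = paste0(rl, "M"),
                              mate = "rev", reverse = TRUE,
                              seq = take(genome, r_start, r_end))
      nr <- nr + 2L
    } else {
      span <- gend - gstart
      lo <- max(cfg$long_read_range[1], 1L)
      hi <- min(cfg$long_read_range[2], span)
      rl <- sample_range(lo, hi)
      s <- gstart + sample.int(span - rl + 1L, 1) - 1L
      strand_rev <- stats::runif(1) < 0.5
      rows[[nr + 1L]] <- list(read_id = rid,
                              flag = if (strand_rev) 16L else 0L,
                              genome_id = genome, start = s, end = s + rl,
                              cigar = paste0(rl, "M"),
                              mate = "single", reverse = strand_rev,
                              seq = take(genome, s, s + rl))
      nr <- nr + 1L
    }
    truth[[i]] <- data.frame(read_id = rid, category = category,
                             species = sp_i, gene_id = gene,
                             stringsAsFactors = FALSE)
  }
  rows <- rows[seq_len(nr)]
  al <- data.frame(
    read_id = vapply(rows, `[[`, "", "read_id"),
    flag = vapply(rows, `[[`, 0L, "flag"),
    genome_id = vapply(rows, `[[`, "", "genome_id"),
    start = as.integer(vapply(rows, `[[`, 0, "start")),
    end = as.integer(vapply(rows, `[[`, 0, "end")),
    mapq = 60L,
    cigar = vapply(rows, `[[`, "", "cigar"),
    mapped = TRUE,
    paired = mode == "short_pe",
    mate = vapply(rows, `[[`, "", "mate"),
    reverse = vapply(rows, `[[`, TRUE, "reverse"),
    primary = TRUE,
    stringsAsFactors = FALSE)
  al$blocks <- lapply(rows, function(r) {
    cbind(start = as.integer(r$start), end = as.integer(r$end))
  })
  al$seq <- vapply(rows, `[[`, "", "seq")
  class(al) <- c("sam_alignments", "data.frame")
  attr(al, "genome_lengths") <- nchar(bundle$genomes)
  list(alignments = al, truth = do.call(rbind, truth))
}

#' Simulate ASVs with calls, counts and truth hits
#'
#' Generates `asvs_per_gene` ASVs from every annotated 16S copy: a window of
#' the copy sequence with per-site substitution noise, a taxonomic call that
#' equals the truth lineage with probability `1 - call_error[rank]` per rank
#' (errors split 50/50 between a wrong label and a blank), a log-normal read
#' count, and a classifier confidence stochastically higher for calls whose
#' species rank is correct. A truth hit table (BLAST outfmt-6 layout, with
#' identity computed from the realized substitutions) is emitted so the
#' evaluation needs no aligner.
#'
#' @param bundle A `truth_bundle`.
#' @param seed Seed (default from config, offset).
#' @return List with `asvs` (data.frame `asv_id`, `sequence`, `read_count`,
#'   `confidence`, rank call columns, plus truth columns `true_species`,
#'   `true_gene`), and `hits` (outfmt-6 data.frame plus the
#'   [read_blast6()] convenience columns).
#' @export
simulate_asvs <- function(bundle, seed = bundle$config$seed + 2L) {
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  cfg <- bundle$config
  ranks <- c("phylum", "family", "genus", "species")
  md <- bundle$metadata
  ann <- bundle$annotation
  n_asv <- nrow(ann) * cfg$asvs_per_gene
  rows <- vector("list", n_asv)
  hit_rows <- vector("list", n_asv)
  k <- 0L
  for (g in seq_len(nrow(ann))) {
    genome <- ann$genome_id[g]
    gseq <- substring(bundle$genomes[[genome]], ann$start[g] + 1L, ann$end[g])
    if (ann$strand[g] == "-") gseq <- revcomp(gseq)
    width <- min(cfg$asv_length, nchar(gseq))
    tr <- md[md$species == genome, , drop = FALSE]
    for (a in seq_len(cfg$asvs_per_gene)) {
      k <- k + 1L
      off <- sample.int(nchar(gseq) - width + 1L, 1) - 1L
      window <- substring(gseq, off + 1L, off + width)
      mut <- mutate_seq(window, cfg$asv_noise)
      call <- stats::setNames(character(4), ranks)
      correct <- logical(4)
      for (r in ranks) {
        if (stats::runif(1) >= cfg$call_error[[r]]) {
          call[r] <- tr[[r]]
          correct[match(r, ranks)] <- TRUE
        } else if (stats::runif(1) < cfg$blank_fraction) {
          call[r] <- ""                      # blank: not classified
        } else {
          pool <- setdiff(unique(md[[r]]), tr[[r]])
          call[r] <- if (length(pool)) sample(rep(pool, 2), 1) else ""
        }
      }
      conf <- if (correct[4]) stats::rbeta(1, 8, 2) else stats::rbeta(1, 2, 4)
      # subject coords of the window on the genome (strand-aware)
      if (ann$strand[g] == "+") {
        s0 <- ann$start[g] + off
      } else {
        s0 <- ann$end[g] - off - width
      }
      rows[[k]] <- data.frame(
        asv_id = sprintf("asv_%05d", k), sequence = mut$seq,
        read_count = 1L + round(stats::rlnorm(1, meanlog = 4, sdlog = 1)),
        confidence = conf,
        phylum = call["phylum"], family = call["family"],
        genus = call["genus"], species = call["species"],
        true_species = genome, true_gene = ann$gene_id[g],
        stringsAsFactors = FALSE)
      pid <- (width - mut$n_sub) / width * 100
      hit_rows[[k]] <- data.frame(
        qseqid = rows[[k]]$asv_id, sseqid = genome, pident = pid,
        length = width, mismatch = mut$n_sub, gapopen = 0L,
        qstart = 1L, qend = width,
        sstart = if (ann$strand[g] == "+") s0 + 1L else s0 + width,
        send = if (ann$strand[g] == "+") s0 + width else s0 + 1L,
        evalue = 0, bitscore = 2 * (width - mut$n_sub) - 3 * mut$n_sub,
        stringsAsFactors = FALSE)
    }
  }
  hits <- do.call(rbind, hit_rows)
  minus <- hits$sstart > hits$send
  hits$sstrand <- ifelse(minus, "-", "+")
  hits$sstart0 <- ifelse(minus, hits$send, hits$sstart) - 1L
  hits$send0 <- ifelse(minus, hits$sstart, hits$send)
  hits$query_coverage_pct <- 100
  list(asvs = do.call(rbind, rows), hits = hits)
}

#' Simulate grouped multi-sample count tables
#'
#' Per-sample compositions are Dirichlet draws around group-specific mean
#' compositions (the bundle's expected profile, perturbed per group on the
#' log scale by `group_separation`); counts are multinomial at the
#' configured depth. `group_separation = 0` makes all groups identically
#' distributed — the PERMANOVA null.
#'
#' @param bundle A `truth_bundle`.
#' @param n_groups Number of groups (default 2); samples are split evenly.
#' @param seed Seed (default from config, offset).
#' @return List with `table` (features x samples integer matrix), `groups`
#'   (factor, one level per group) and `means` (per-group mean
#'   compositions).
#' @export
simulate_counts <- function(bundle, n_groups = 2L,
                            seed = bundle$config$seed + 3L) {
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  cfg <- bundle$config
  stopifnot(cfg$n_samples >= 2, n_groups >= 1)
  base <- expected_profile(bundle$metadata)$expected_ra
  n_feat <- length(base)
  means <- matrix(NA_real_, n_feat, n_groups)
  means[, 1] <- base
  if (n_groups > 1) {
    for (g in 2:n_groups) {
      m <- base * exp(cfg$group_separation * stats::rnorm(n_feat))
      means[, g] <- m / sum(m)
    }
  }
  grp <- rep(seq_len(n_groups), length.out = cfg$n_samples)
  grp <- sort(grp)
  tab <- matrix(0L, n_feat, cfg$n_samples)
  for (s in seq_len(cfg$n_samples)) {
    alpha <- cfg$dirichlet_conc * means[, grp[s]]
    gam <- stats::rgamma(n_feat, shape = pmax(alpha, 1e-6))
    p <- gam / sum(gam)
    tab[, s] <- stats::rmultinom(1, cfg$depth, p)
  }
  rownames(tab) <- bundle$metadata$species
  colnames(tab) <- sprintf("sample_%02d", seq_len(cfg$n_samples))
  list(table = tab,
       groups = factor(sprintf("group_%d", grp)),
       means = means)
}
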