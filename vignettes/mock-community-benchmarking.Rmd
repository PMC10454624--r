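---
title: "Benchmarking amplicon sequencing against a mock community"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking amplicon sequencing against a mock community}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mockbench)
```

## The problem

A 16S rRNA metabarcoding workflow stacks many steps — extraction, primer
choice, sequencing chemistry, denoising, classification — and each can
distort the community it reports. A mock community of known membership and
proportion makes the distortion measurable: we can state what *should* be
observed and score what *was*. This package provides that scoring
machinery, plus a synthetic-data generator so every component can be
validated against exact ground truth without any sequencing run.

## The expected-abundance model

An even genomic-mass mock mixes the same DNA mass per member species. A
species with a small genome therefore contributes *more genome copies*, and
its 16S contribution is further scaled by its per-genome 16S rDNA copy
number. The chain implemented in `expected_profile()` is

$$GMW_i = L_i \times 607.4,\qquad
  nGM_i = \frac{GMW_i}{N_A}\times 10^{9},\qquad
  m = \frac{cV}{S},\qquad
  GCN_i = \frac{m}{nGM_i},$$

$$E_i = GCN_i \times k_i,\qquad RA_i = E_i \Big/ \textstyle\sum_j E_j,$$

with $L_i$ the genome length (bp), $607.4$ g/mol the average weight of a
double-stranded base pair, $N_A$ Avogadro's number, $c$ and $V$ the mix
concentration (ng/µL) and volume (µL), $S$ the number of species and $k_i$
the 16S copy number. For the canonical 20-member even mix at 2.6 ng/µL in
50 µL, $m = 6.5$ ng per species (5% of total mass each).

Two consequences shape the implementation:

* every constant cancels in the ratio, so $RA_i \propto k_i/L_i$ — the
  tests verify this closed form on randomized mocks and the invariance of
  $RA$ to $c$, $V$ and the per-bp weight;
* $GCN_i$ is kept real-valued, never rounded to whole genomes. Rounding
  would break the closed-form identity, and nothing downstream needs an
  integer copy count.

Genus-level expectations are obtained by summing member species' $RA_i$
(`collapse_profile()`), the only aggregation consistent with comparing
against genus-level observations.

## Read stratification

Reads mapped onto the mock reference genomes are classified against the
BED annotation of 16S genes:

* **on-target** — the primary alignment overlaps an annotated 16S gene;
  for pairs, *both* mates must land on the same gene or on byte-identical
  copies of it in the same genome (`identical_copy_groups()` compares
  extracted copy sequences, reverse-complementing minus-strand copies);
* **ambiguous** — any other configuration touching a 16S gene: mates on
  non-identical copies, on different genomes, or one mate on-gene with the
  other off-target/unmapped;
* **off-target** — mapped, no 16S contact;
* **unmapped** — no mate mapped.

Design choices worth spelling out:

* Only primary alignments are considered; secondary and supplementary
  records are dropped before classification, and a test injects decoy
  secondaries to assert they can never change a verdict.
* A mate pair with one on-gene and one off-gene mate is *ambiguous*, not
  on-target: only concordant same-gene/identical-copy pairs count as
  unambiguous evidence. This is also why identical-copy grouping is
  restricted to a single genome — the same sequence on two genomes cannot
  disambiguate which organism produced the pair.
* The on-gene test uses a minimum-overlap threshold `min_overlap_bp`
  (default 1: any overlap counts). No consensus threshold exists in the
  field; it is exposed as a parameter and its boundary is tested exactly.
* Reference-space semantics everywhere: CIGAR `M/=/X/D` operations count
  toward overlap and coverage, `I/S/H/P` do not, `N` splits aligned
  blocks. `gene_coverage()` is checked against a naive per-position
  recount.
* All internal coordinates are 0-based half-open; the single 1-based
  boundary (SAM `POS`) is converted exactly once at ingestion.

The four category counts always sum to the number of input reads or pairs
— conservation is asserted, not assumed. Per-species abundances are
computed over on-target units only.

## ASV confusion matrix

Each ASV is aligned to the mock genomes; hits must reach **identity ≥ 97%
and query coverage ≥ 90%**, and the best survivor is taken by score, ties
broken by identity then genome id. Labels follow from where the best hit
lands and whether the taxonomic call matches the truth lineage at the
evaluated rank:

| best hit | call vs truth | label |
|---|---|---|
| on a 16S gene | match | TP |
| on a 16S gene | present, mismatch | FP |
| on a 16S gene | absent at rank | FN |
| outside all 16S genes | (ignored) | TN |
| none | — | `unaligned` |

`unaligned` ASVs sit outside the matrix and are reported separately as
background noise. The TN definition — an ASV that maps to the reference
but outside any 16S gene — is unusual for classification scoring but is
the definition this benchmarking design calls for, and it is implemented
verbatim.

Label comparison is normalized (trim, collapse whitespace, case-fold) and
routed through an alias table, because reference taxonomies label some
organisms under synonymous names (`Clostridium sensu stricto 1` /
`Clostridium`, `Actinomyces` / `Schaalia`, `Escherichia-Shigella` /
`Escherichia` by default; user-extensible).

Precision, accuracy and recall are percentages of the (optionally
read-count-weighted) matrix. ROC curves treat TP-labeled ASVs as positives
and FP/FN as negatives, sweeping the classifier-confidence threshold; the
trapezoidal AUC with grouped ties equals the weighted Mann–Whitney
statistic, and the tests assert that identity against a brute-force
pairwise comparison.

The bundled aligner (`align_asv()`) is a local affine-gap alignment with
blastn-like scores (match +2, mismatch −3, gap open 5, gap extend 2),
adequate for desk-scale instances; production-scale hit sets are ingested
from BLAST outfmt-6 files (`read_blast6()`), and the simulator emits a
truth hit table in the same layout so large evaluations need no aligner
at all.

## Concordance and diversity

`concordance()` compares expected and observed relative abundances on the
percentage scale, entering taxa absent from the observation as zeros —
an undetected mock member is evidence against the workflow and must count.
It reports the Pearson correlation with its $t$-based two-sided p-value
and the OLS slope/intercept with adjusted $R^2$ (both delegated to base
R's `cor.test()`/`lm()`).

The diversity statistics are deliberately authored in-package (they are
the quantities under study) and cross-checked in the tests against
independent references (`vegan`, `ape`, `cmdscale`):

* **rarefaction** — one draw without replacement to a fixed depth, exact
  total, reproducible under a seed (a single draw, not an average, matching
  the single-threshold normalization practice);
* **inverse Simpson** $1/\sum p_i^2$ and **Pielou** $H/\ln S$ with natural
  logs and zero counts dropped; Pielou is `NA` below two observed features;
* **CLR** with a pseudocount (default 1) added to all counts before
  closure — the standard zero strategy when none is prescribed; exposed as
  a parameter;
* **Aitchison distance** = Euclidean distance of CLR-transformed samples;
* **PCoA** by double-centering $-D^2/2$ and eigen-decomposition, keeping
  positive axes; explained fractions are over the positive spectrum;
* **PERMANOVA** partitions the squared-distance sum of squares;
  $p = (1 + \#\{F^* \ge F\})/(n_{perm}+1)$ under label permutation
  (999 by default), with `pairwise_permanova()` for per-pair contrasts;
* **paired t-test** via `t.test(paired = TRUE)` with an explicit error on
  zero difference variance.

## The synthetic-data generator

`simulate_mock()` builds the community the scoring machinery is validated
against: by default 20 species, genome lengths 30–90 kb, 1–10 16S copies
each, half of a genome's copies byte-identical and the rest mutated at one
or more sites (pairwise distinct by construction), copies placed on random
strands at non-overlapping loci. All 16S genes descend from one ancestral
sequence at 10% per-site divergence, so near-identical co-generic genes
are reproducible by lowering the divergence. The compact genome scale is a
deliberate choice: only the $k_i/L_i$ ratio enters the expected profile,
so desk-scale genomes preserve every property under test while keeping
examples fast; the length *variability* (3× range) is what matters and is
retained.

`simulate_reads()` draws fragments from 16S genes with species
probabilities equal to the bundle's expected profile (uniform across a
species' copies), plus an optional intergenic off-target fraction, applies
substitution errors, and emits the generating locus as a truth alignment
in SAM layout — reads never need to be re-aligned to be stratified.
Short-read mode produces 2×250 bp proper pairs from ~380–460 bp
fragments; long mode produces single reads within the 1000–1600 bp
full-length filter window.

`simulate_asvs()` yields ASVs per annotated copy with configurable
per-site noise; identity in the emitted truth-hit table is computed from
the *realized* substitution count, so the 97% identity filter behaves
exactly as it would on real hits. Taxonomic calls are correct per rank
with probability $1-\varepsilon_r$; errors split between wrong labels and
blanks (`blank_fraction`), which separates the recall-degrading misses
from the precision-degrading mislabels. Confidences are Beta-distributed,
stochastically higher for correct species calls, giving the ROC machinery
a signal of known direction.

`simulate_counts()` draws per-sample compositions from a Dirichlet around
group-specific means (log-normal perturbations of the expected profile,
scaled by `group_separation`) and multinomial counts at fixed depth;
`group_separation = 0` yields identically distributed groups — the null
used to calibrate PERMANOVA's type-I error (the suite checks a rejection
rate within [0.03, 0.07] at $\alpha = 0.05$ over 2000 replicates of 12
samples with 199 permutations).

What the generator does *not* emulate — chimeras, platform quality-score
profiles, PCR amplification bias, contamination — bounds what a passing
suite shows: the *scoring* machinery is correct against its definitions;
it does not certify any wet-lab workflow.

## Numerical and degenerate-input choices

* Zero denominators in precision/accuracy/recall return `NA` with a
  warning rather than an error; an all-zero matrix yields all `NA`.
* `roc_auc()` returns `NA` when either class is absent; identical scores
  for all items give AUC 0.5 by the tie convention.
* `pcoa()` treats eigenvalues below $10^{-9}\lambda_{max}$ as null and
  errors on an all-zero matrix; `permanova()` requires ≥ 2 groups of ≥ 2.
* `best_hit()` ties break by identity then lexicographic genome id, making
  results deterministic across platforms.
* Rarefaction beyond a sample's total is an error; `rarefy_table()` drops
  such samples with a warning, mirroring how shallow samples are excluded
  before α-diversity comparison.
* Simulation problem sizes in the tests (10 000 pairs for conservation,
  ~2 000 ASVs for recall recovery, 2 000 null replicates for PERMANOVA
  calibration) were chosen as the smallest sizes at which three binomial
  standard errors give sharp bounds.

## Limitations

The confusion-matrix definitions evaluate classification *given* an ASV
that aligns to the mock reference; they say nothing about denoising
quality upstream. The bundled local aligner is not a blastn replacement
(no word seeding or E-values) — the thresholds, not the aligner, dominate
the labels, and precomputed hits are first-class input. PERMANOVA here is
one-factor; multifactor designs should use `vegan::adonis2` directly on
the `aitchison()` matrix, with which the one-factor statistics agree to
numerical precision.
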