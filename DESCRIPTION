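Package: mockbench
Title: Mock-Community Benchmarking of Amplicon Sequencing Strategies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Benchmarks 16S rRNA amplicon sequencing strategies against a
    mock community of known composition. Predicts expected 16S rDNA copy
    abundances from genome length and per-genome 16S copy number under
    even genomic-mass mixing, stratifies aligned reads and read pairs into
    on-target, ambiguous, off-target and unmapped classes against annotated
    reference genomes (honouring identical 16S copies within a genome),
    scores amplicon sequence variants (ASVs) with a confusion matrix at
    genus and species rank (precision, accuracy, recall, ROC/AUC, optionally
    read-weighted), measures expected-versus-observed abundance concordance,
    and compares compositional diversity (rarefaction, inverse Simpson,
    Pielou evenness, centered log-ratio transform, Aitchison distance,
    principal coordinates analysis, pairwise PERMANOVA). A synthetic-data
    generator produces genomes, annotations, reads with truth alignments,
    ASVs and count tables with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    ape,
    pROC
Config/testthat/edition: 3
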