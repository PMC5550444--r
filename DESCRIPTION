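Package: trapscore
Title: Transcript-Inferred Pathogenicity Scoring for Synonymous and
    Intronic Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Scores single-nucleotide variants in synonymous and intronic
    positions for their potential to damage a gene's transcripts.  Builds
    donor and acceptor splice-site position-specific scoring matrices
    (PSSMs) from annotated G[T/C]..AG introns, extracts a 20-feature
    vector per variant-in-transcript (splice-site strength changes,
    cryptic splice-site creation and disruption, splice interaction
    summaries, exonic splicing enhancer/silencer motif gains and losses,
    conservation, distance to the nearest splice site), and classifies
    variants with a 1,000-tree random forest whose vote fraction is the
    transcript-inferred pathogenicity (TraP) score.  Ships the
    evaluation toolkit used for such scores (ROC/AUC, sensitivity and
    specificity at a threshold, Mann-Whitney comparisons, score-binned
    allele-frequency correlation, non-parametric quantile-quantile
    comparison, gene-list enrichment) and a synthetic mini-genome
    generator so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    vcfR,
    randomForest,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
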