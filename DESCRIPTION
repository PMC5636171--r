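Package: ripsi
Title: Retained-Intron Quantification, PTC Annotation, and Splice-Site
    Features for Two-Condition RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies intron retention from junction and intron-body read
    counts in a two-condition RNA-seq design (percent spliced in, delta-Psi,
    Bayes factors with detection and significance filters), annotates
    intron-retained transcripts for premature termination codons and
    nonsense-mediated-decay susceptibility under the 50-nt rule, scores
    3' splice-site strength with a trainable position-specific first-order
    Markov model, extracts simple cis sequence features (GC differential,
    nearest upstream AG, motif occurrences), and provides the associated
    statistical decision procedures (normality-gated group comparison,
    two-sample proportion tests, Benjamini-Hochberg FDR, gene-level
    roll-up). A synthetic-data generator emits a toy genome, annotation,
    truth table, and replicated negative-binomial count tables with planted
    retention effects so the whole pipeline is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
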