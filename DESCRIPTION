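Package: grcscan
Title: Detection of Germline-Restricted Chromosomes from Paired Germline and Soma Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers germline-restricted chromosome (GRC) content from paired
    germline and soma sequencing of the same individuals. Implements
    coverage-ratio amplification calling with normalisation, outlier removal,
    slope correction, mode centering and GC/percentile filters; germline-specific
    single-nucleotide variant calling with a soma-swap negative control;
    per-gene copy-number estimation from read depth with cytogenetic
    corrections; gonad-expression enrichment by randomisation against a
    hypergeometric oracle; and evolutionary stratum assignment from rooted gene
    trees. Ships a parameterised synthetic-data generator that emulates a GRC
    (paralog dosage, divergence SNVs, sequencing error, GC-varying windows,
    expression panels, gene trees) with machine-readable truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    phytools,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    VariantAnnotation,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
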