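Package: riboPatterns
Title: Decoding Translation Deregulation from Ribosome Profiling and RNA-Seq
Version: 0.3.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for decoding translation-deregulation patterns from
    matched ribosome profiling (Ribo-seq) and RNA-seq experiments in
    transcript coordinates. Implements read-length diagnostics, metagene
    P-site offset estimation and 3-nt periodicity profiling, codon-level
    E/P/A-site occupancy with differential codon usage tests, ribosome
    stall-site detection with frameshift and disome (collided ribosome)
    checks, upstream/downstream open reading frame (uORF/dORF) discovery
    by Thomson multitaper spectral testing of untranslated-region
    coverage, differential translation efficiency with a negative
    binomial interaction model, subset cumulative-distribution
    comparisons, internal gene-set enrichment and a network-aware gene
    prioritization score. A fully parameterised two-condition simulator
    with programmed stalls, frameshifts, disomes, uORFs/dORFs and
    translation-efficiency shifts provides ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    rtracklayer,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    DESeq2,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
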