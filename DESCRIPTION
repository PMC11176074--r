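Package: cireScreen
Title: Tiling CRISPRi Screen Analysis, Boundary Deletion Scans and 4C
    Viewpoint Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for tiling CRISPR interference (CRISPRi)
    screens read out by FACS sorting of cells into low and high
    target-protein expression bins. Provides guide library design from raw
    sequence (NGG protospacer enumeration with restriction-site
    exclusion), a generative simulator of bin-sorted screens over an
    annotated locus model, negative-binomial Wald statistics per guide
    with median-of-ratios normalization and trended dispersion,
    CRISPRi-responsive element (CiRE) calling by merging runs of
    significant guides, in-silico boundary-element deletion scans over a
    pluggable contact-map predictor scored by matrix MSE, and 4C-seq
    viewpoint signal processing (per-million normalization, running
    window, spline smoothing, gene-body comparison with Bonferroni
    corrected t-tests, and track QC).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    MASS,
    zoo,
    withr,
    jsonlite,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
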