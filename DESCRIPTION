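Package: recesscan
Title: Carrier Screening and Molecular Diagnostic Calling for Recessive
    Disease Gene Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computational pipeline for a targeted hybrid-capture carrier
    screening and molecular diagnostic test covering hundreds of recessive
    childhood diseases. Implements the automated decision-tree variant
    caller with allele-fraction zygosity assignment, gross-deletion
    detection by breakpoint-junction read matching and normalized read
    depth, per-disease genotype assembly with carrier versus diagnostic
    reporting, a pileup/coverage simulator, and an analytic-validity
    harness (sensitivity, specificity, predictive values, ROC/AUC and
    sequencing-depth sweeps) against simulated truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
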