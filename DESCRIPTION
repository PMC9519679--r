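Package: svharvest
Title: Structural-Variant Ensemble Benchmarking, Cross-Sample Clustering,
    and Kernel-Based Phenotype Prediction for Inbred Diversity Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for benchmarking structural-variant (SV) call sets
    against a truth set with breakpoint-tolerance matching, selecting an
    optimal boolean combination of callers under a precision floor,
    merging per-sample SV calls into genotyped cross-sample SV clusters,
    annotating clusters by gene context and transposable-element overlap,
    detecting SV hotspots with a Poisson model, computing linkage
    disequilibrium and windowed nucleotide diversity for presence/absence
    variants, testing SV-expression associations with permutation and
    kinship mixed-model (PK) procedures, and predicting phenotypes with
    weighted-kernel GBLUP under replicated cross-validation. A synthetic
    cohort generator emulates multi-caller call sets, a 23-line inbred
    panel, expression, and multi-environment phenotypes so the whole
    pipeline can be exercised without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    rtracklayer,
    GenomeInfoDb,
    BiocGenerics,
    vcfR,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
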