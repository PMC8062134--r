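Package: sceQTL
Title: One-Pot Single-Cell eQTL Mapping in Experimental Crosses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for expression quantitative trait locus (eQTL) mapping at
    cellular resolution from a single pooled ("one-pot") single-cell RNA-seq
    experiment on a large recombinant population. Provides probabilistic
    genotyping of individual cells from sparse transcribed-variant UMI counts
    with a hidden Markov model, negative-binomial generalized linear model
    eQTL mapping across cell types with likelihood-ratio LOD scores and
    permutation-based false discovery rates, trans-eQTL hotspot detection by
    genome binning with Poisson excess tests, a penalized multinomial
    cell-type classifier with doublet and low-quality calling rules, and a
    full cross-design simulator (obligate-outcrossing intercross pedigrees,
    sparse allele counts, gamma-Poisson expression with planted effects) so
    the pipeline can be exercised end-to-end on synthetic data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    glmnet,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
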