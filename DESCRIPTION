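Package: stressfactor
Title: Factorial Decomposition and Multi-Omics Integration of Combined
    Drought-Heat Stress Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for paired transcriptome-metabolome analysis of combined
    abiotic stress experiments. Implements matrix-level preprocessing of
    microarray-like expression data and FT-ICR-MS-like metabolite peak tables
    (quantile and total-ion-current normalization, detection filtering,
    floor imputation, batch correction), a two-factor drought-by-heat linear
    model with empirical-Bayes moderated statistics and classification of
    every variable into additive, enhanced, reduced and combined-stress
    specific response groups, per-condition contrasts with Venn
    decomposition of low- versus high-air-humidity heat responses,
    regularized canonical correlation analysis with analytic
    shrinkage-estimated ridge parameters, thresholded gene-metabolite
    correlation networks with label-propagation communities and maximal
    clique enumeration, and hypergeometric term-set enrichment. A synthetic
    paired-omics generator with exported ground truth makes every stage
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    limma,
    igraph,
    mclust,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown,
    mixOmics
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
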