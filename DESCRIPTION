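Package: ProteoTurn
Title: Joint Abundance and Turnover-Rate Proteostasis Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers whether differences in protein abundance between
    experimental conditions are driven by synthesis or by degradation, by
    combining label-free quantification (LFQ) fold changes with protein
    turnover rates fitted from heavy-water (D2O) metabolic-labeling time
    courses. Implements the first-order turnover model and its closed-form
    labeling kinetics, per-peptide exponential curve fitting with quality
    filters, the LFQ normalization chain (missingness filtering, log2
    transform, mean centering, slope normalization, k-nearest-neighbour
    imputation, variance-test-gated differential tests), fold-change
    scaling, aggregation of scaled fold changes to functional-ontology
    terms with one-sample testing and Benjamini-Hochberg correction,
    quadrant classification of regulation mode, and a synthetic-data
    generator that emulates the full multi-genotype, multi-dataset study
    design for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    S4Vectors,
    SummarizedExperiment,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Proteomics, MassSpectrometry, Normalization, Software
RoxygenNote: 7.3.3
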