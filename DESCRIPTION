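Package: herbimeta
Title: Meta-Analysis of Plant Transcriptomic Responses to Arthropod Herbivory
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reproducible pipeline for comparative transcriptomics of the
    plant response to arthropod herbivores. Assembles per-experiment
    differential-expression tables into a gene-by-experiment log2
    fold-change matrix, finds recurrently regulated genes and their
    Pearson-correlation coexpression modules, clusters experiments by
    Ward linkage, ranks genes by their contribution to the leading
    principal components, flags cluster-specific genes with
    bias-corrected and accelerated (BCa) bootstrap confidence intervals,
    extracts minimum connected protein-protein interaction subnetworks
    around seed genes with betweenness-based hub discovery, and
    integrates the resulting gene sets. Includes a synthetic-data
    generator with planted structure so every stage can be tested
    without external downloads.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    boot,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
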