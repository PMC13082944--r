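Package: compartmentBias
Title: Monte Carlo-Wilcoxon Bias Tests and Isochore Compartment-Bias
    Transcriptomics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements the Monte Carlo-Wilcoxon (MCW) family of
    rearrangement tests (unmatched, matched-bivariate, and
    biased-measures variants) built on signed-rank bias indexes, and an
    isochore-based analysis of heterochromatin/euchromatin compartment
    bias in bulk RNA-seq data. Segments genomes into GC-content
    isochores from 100-kb windows, assigns genes to isochore classes,
    computes per-gene expression bias indexes across exposure-versus-
    control contrasts, runs pre-ranked gene set enrichment, and detects
    concerted opposite-signed expression shifts between AT-rich and
    GC-rich compartments. Includes metabolic phenotype analyses
    (matched-pair fasting and consumption tests, plasma panel cleaning,
    PCA, dosing arithmetic) and a synthetic-data generator that plants
    known compartment structure so every stage can be validated against
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea,
    rtracklayer
Config/testthat/edition: 3
RoxygenNote: 7.3.3
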