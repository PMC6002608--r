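Package: phagoScreen
Title: Simulation and Analysis of FACS-Sorted CRISPR Knockout Phagocytosis
    Screens
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for pooled CRISPR/Cas9 loss-of-function screens read out by
    fluorescence-activated cell sorting, modeled on an SLC-focused phagocytosis
    screen in macrophage-like cells. Provides an sgRNA library container with
    exact spacer lookup, a generative simulator of the full screen (infection,
    knockout phenotype, sorting into acidification-positive and
    phagocytosis-negative populations, PCR/sequencing overdispersion), spacer
    extraction and exact-match counting from FASTQ, a negative-binomial Wald
    test for per-sgRNA differential abundance with median-of-ratios
    normalization, gene-level aggregation by a weighted Kolmogorov-Smirnov
    enrichment statistic with a permutation null, quadrant gating of
    two-channel flow-cytometry events with the accompanying assay statistics,
    and ratiometric BCECF cytoplasmic pH quantification via a sigmoidal
    in-situ calibration curve.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    BiocGenerics,
    SummarizedExperiment,
    Biostrings,
    MASS,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    DESeq2,
    fgsea
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: CRISPR, PooledScreens, FunctionalGenomics, Software
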