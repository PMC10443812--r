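Package: cfOrigins
Title: Cell-Type Deconvolution of Cell-Free DNA from Fragment-Level
    Methylation Patterns
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for decoding the cell types of origin of circulating
    cell-free DNA (cfDNA) from bisulfite capture sequencing. Implements
    multichannel dynamic-programming segmentation of the CpG-indexed genome
    into homogeneously methylated blocks, one-vs-all discovery of
    cell-type-specific differentially methylated blocks (soft-margin and
    delta-beta criteria), fourth-order Markov modelling of within-fragment
    CpG co-methylation with Bayesian hard assignment of each fragment to a
    cell type, aggregation to normalized cell-type fractions and genome
    equivalents per mL serum, and an in-silico mix-in protocol for
    validating detection limits. Includes a synthetic-data generator that
    emulates reference whole-genome bisulfite methylomes with planted
    markers, serum-like cfDNA mixtures, and unmethylated lambda phage
    spike-ins, with full ground truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    data.table,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: DNAMethylation, Epigenetics, Sequencing, CellBiology
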