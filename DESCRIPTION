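Package: phagecoev
Title: Analysis of Spatially Structured Bacterium-Phage Coevolution Experiments
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for quantifying bacterium-phage coevolution on
    spatially structured plates: growth-lysis cycle detection from dark-field
    time-lapse stacks, plaque-image infectivity and turbidity scoring,
    cross-infection network assembly with nestedness (NODF) and Barber
    bipartite modularity under an equiprobable null, sparse (Lasso)
    genotype-phenotype association from mutation tables, and permutation tests
    for adaptive evolution (dN/dS preserving transition/transversion classes,
    multiply-mutated-gene simulation). A synthetic-data module generates every
    input with known ground truth so all stages are testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    glmnet,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    EBImage,
    png,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    seqinr,
    withr,
    optparse,
    knitr
biocViews: Software, Phylogenetics, StatisticalMethod, Network, Regression
Config/testthat/edition: 3
RoxygenNote: 7.3.3
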