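Package: ystrpop
Title: Forensic and Population-Genetic Analysis of Y-STR Haplotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for forensic and population-genetic analysis of Y-chromosomal
    short tandem repeat (Y-STR) haplotype tables typed on the 17-locus Yfiler
    panel. Computes haplotype and gene diversity, match probabilities,
    discrimination capacity and microvariant prevalence; squared repeat-count
    distances, within/between-population average pairwise differences and
    AMOVA-based pairwise R_ST; classical and nonmetric multidimensional scaling
    with Kruskal stress and UPGMA dendrograms with Newick export;
    median-joining haplotype networks; rarefaction-standardized counts of
    distinct and private alleles; F_ST/F_ST^max ancestry-variability statistics
    for STRUCTURE-style Q matrices with bootstrap resampling; a configurable
    naive-Bayes haplogroup predictor; and a stepwise-mutation-model simulator
    generating study-shaped haplotype tables and Dirichlet Q matrices so every
    analysis stage can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    igraph,
    MASS,
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
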