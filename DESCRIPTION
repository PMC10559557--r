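Package: svforge
Title: Population-Scale Structural Variant Merging, Breed Stratification,
    and Mixed-Model Association
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for population-scale structural variant (SV)
    analysis in a two-breed resource population: union merging of multi-caller
    SV callsets with breakpoint-distance clustering and a reciprocal-overlap
    merge for inversions, locus quality and length filtering, positional
    annotation against a gene model, per-locus Weir-Cockerham F_ST between
    breeds with top-quantile stratified-locus selection, genomic-relationship
    PCA and allele-sharing neighbor-joining trees, a two-condition
    breed-differential genotype screen on founders, position-based candidate
    genotyping in offspring, and EMMAX-style mixed-linear-model genome-wide
    association with Bonferroni correction. Includes a synthetic-data module
    that simulates diverged founder breeds, noisy multi-caller observations,
    an F2 intercross with Haldane recombination, and phenotypes with planted
    causal SVs, so every stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    vcfR,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
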