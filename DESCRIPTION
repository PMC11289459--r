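Package: trilayer
Title: Trilayer Regulatory Association Analysis for Progressive Disease
    Genetics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for the joint analysis of genotype, DNA methylation and
    gene expression in a case-control disease-course setting: bump-hunting
    detection of differentially methylated regions with resampling-based
    family-wise error control, additive minor-allele dosage models for
    methylation and expression quantitative trait loci, genotype quality
    control with exact Hardy-Weinberg testing, case-control logistic
    association with linkage-disequilibrium block clumping and block-wise
    Bonferroni correction, fixed- and random-effects meta-analysis of odds
    ratios, direction-of-effect concordance triage across the three layers,
    and a co-expression network pipeline (permutation-FDR edge filtering,
    planar maximally filtered graphs, multiscale module detection and module
    eigengene-trait association). A seeded synthetic-data generator emulates
    the full genotype-to-phenotype causal structure with recorded ground
    truth, so every stage is testable without restricted-access cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    cluster,
    jsonlite,
    Rcpp,
    yaml,
    vcfR
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr,
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
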