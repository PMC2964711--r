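Package: mtN1a
Title: Phylogeography of Mitochondrial Haplogroup N1a: Motif Parsing,
    Subclade Classification, Reduced Median Networks and Rho-Statistic Dating
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for control-region motif based analysis of human
    mitochondrial DNA haplogroup N1a. Parses and emits HVS-I/HVS-II
    mutation-motif nomenclature scored against the revised Cambridge
    reference coordinate system, variant-calls complete mitogenomes with a
    banded global aligner, assigns haplotypes to nested N1a subclades by a
    motif matching and near-matching strategy, reconstructs reduced median
    networks and extracts most-parsimonious rooted mutation trees, estimates
    coalescence ages with the rho statistic and Saillard standard errors
    under configurable molecular-clock calibrations, computes regional
    haplotype-heterogeneity chi-square statistics, and simulates
    ground-truth genealogies, mitogenomes and motif tables for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    ape,
    igraph,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
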