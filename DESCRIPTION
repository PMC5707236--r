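Package: neurogenet
Title: Imaging Genetics of Resting-State Brain Network Organization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for graph-theoretic imaging-genetics analyses
    of associations between serotonin-transporter (5-HTTLPR) and COMT genetic
    risk, resting-state functional brain network organization, and
    neuroticism. Covers genotype processing (Hardy-Weinberg tests, two-marker
    EM haplotype phasing, risk-group assignment), ROI time-series cleanup
    (nuisance regression, band-pass filtering, motion scrubbing), weighted
    connectivity construction with proportional thresholding across a density
    grid, seeded Louvain community detection with fine-tuning, weighted and
    binary network measures (global and local efficiency, maximized
    modularity, participation coefficient), and AUC-based permutation
    inference for group-difference and slope-difference statistics. A
    synthetic-cohort generator with planted modular structure and planted
    genetic effects makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    pracma,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
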