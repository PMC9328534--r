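Package: calseg
Title: Sequence and Cluster Analysis of Contraceptive Calendar Histories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Behavioral segmentation of retrospective contraceptive calendar
    data of the kind collected by Demographic and Health Surveys.  Parses
    month-by-month calendar strings into five-state sequences (nonuse,
    short-term modern method, long-acting/permanent method, traditional
    method, pregnancy), computes optimal-matching edit distances between
    sequences, clusters women with a weighted k-medoid (PAM) algorithm with
    data-driven selection of the number of clusters via average silhouette
    width, point-biserial correlation and Hubert's Gamma, derives per-cluster
    descriptives (state distributions, mean time per state, cross-sectional
    entropy, turbulence, medoids), and profiles cluster membership with
    survey-weighted logistic regression using Taylor-linearized variance for
    stratified multistage designs.  Includes a synthetic-data generator that
    emulates the archetypal Burundi cluster structure so the full pipeline is
    testable without restricted microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    cluster,
    mclust,
    sandwich,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
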