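Package: ocmix
Title: Oncogene Candidate Discovery from Paired Tumour-Normal RNA-Seq by
    Gaussian Mixture Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects oncogene candidates - genes with uniformly low
    expression in adjacent normal tissue but high expression in a distinct
    subgroup of tumours - from paired bulk RNA-seq cohorts. Fits a
    two-component, equal-variance Gaussian mixture to each gene's
    log2(TPM + 1) values in tumour and normal tissue independently via
    expectation maximisation, derives the posterior-0.5 decision boundary,
    computes a selectivity index and an oncogene-likeness score, and ranks
    candidates. Also provides Fisher-exact gene-set overrepresentation with
    Benjamini-Hochberg adjustment, and a Monte-Carlo harness that calibrates
    the score threshold to a target type-I level on simulated null genes and
    estimates detection power for planted candidates.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
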