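Package: mrci
Title: Reciprocal Causation Inference from Bivariate GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Jointly estimates reciprocal causal effects between two phenotypes
    from genome-scale bivariate GWAS summary statistics and reference linkage
    disequilibrium (LD) information. SNPs are modelled as a four-component
    mixture (trait-specific, pleiotropic, null); marginal effect estimates are
    fitted by a composite likelihood maximised with an EM algorithm, with
    robust sandwich standard errors that account for LD between SNPs, and
    sub-model averaging for robustness when mixture components are absent.
    Includes a synthetic-data generator that emulates the generative model
    (block LD, four-component architecture, reciprocal causal mixing, sample
    overlap) so every stage can be tested without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    rlang,
    Matrix,
    readr,
    jsonlite,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
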