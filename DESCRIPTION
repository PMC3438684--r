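Package: pleiobayes
Title: Bayesian Discovery of Pleiotropic SNP Associations and Genetic Risk
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two-phase Bayesian analysis of case-control genome-wide
    association studies with two dichotomous phenotypes.  Phase I scores
    every SNP against null, single-trait and pleiotropic association
    models under four inheritance codings using Dirichlet-multinomial
    marginal likelihoods, and ranks SNPs by the log Bayes factor of the
    selected model.  Phase II selects the number of ranked SNPs by
    cross-validated AUC.  Nested naive-Bayes classifiers built on the
    ranked SNPs provide marginal, conditional and naive genetic risk
    prediction, as single classifiers or ensembles.  Includes a
    case-control GWAS simulator with per-SNP minor allele frequency,
    odds ratio, inheritance mode and disease allele, and readers/writers
    for PLINK 1 binary files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
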