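Package: tetragebv
Title: Genomic Prediction for Autotetraploid Breeding Programs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genomic selection in autotetraploid clonal crops such
    as potato. Provides a simulator of finite-size breeding programs with
    tetrasomic inheritance and double reduction, quality control for SNP
    allele-dosage matrices (missingness filtering, population-mode
    imputation, minor-allele-frequency filtering, duplicate concordance),
    principal coordinate analysis of Euclidean genetic distances, a Gibbs
    sampler for Bayesian Ridge Regression yielding genomic estimated
    breeding values, EM-REML variance components with broad-sense
    heritability on an entry-mean basis, and cross-generation, cross-family
    and repeated k-fold cross-validation accuracy evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
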