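Package: yakGP
Title: Genomic Prediction of Early Growth Traits in Yak
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genomic-prediction workbench for small livestock populations,
    built around the analysis of early growth traits (body weight, withers
    height, body length, chest girth at weaning and yearling ages) in Ashidan
    yak. Provides SNP quality control (call rate, Hardy-Weinberg equilibrium,
    minor allele frequency), the VanRaden genomic relationship matrix,
    average-information REML estimation of variance components and
    heritability, GBLUP via the mixed-model equations, single-site Gibbs
    samplers for the Bayes A, Bayes B, Bayes C and Bayesian Lasso
    marker-effect models, repeated k-fold cross-validation with predictive
    ability and heritability-scaled accuracy, and a synthetic herd generator
    that emulates the population structure the analysis assumes, so that
    every stage is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'yakGP-package.R'
    'AllClasses.R'
    'RcppExports.R'
    'accessors.R'
    'bayes.R'
    'evaluation.R'
    'gblup.R'
    'io.R'
    'kinship.R'
    'pipeline.R'
    'qc.R'
    'reference-tables.R'
    'simulate.R'
    'varcomp.R'
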