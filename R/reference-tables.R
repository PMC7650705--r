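#' @include AllClasses.R
NULL

refPath <- function(file) {
  system.file("extdata", file, package = "yakGP", mustWork = TRUE)
}

#' Reference tables from the published yak genomic-prediction study
#'
#' Summary tables of a published genomic-prediction analysis of early
#' growth traits (body weight, withers height, body length, chest girth at
#' 6 and 12 months) in 354 Ashidan yaks: per-trait phenotype summaries,
#' REML variance components with heritabilities, cross-validated predictive
#' ability and accuracy for GBLUP and the four Bayesian models, and the
#' correlation between 6-month body-weight predictions and 30-month
#' observations. The package uses them as frozen inputs for its
#' internal-consistency checks (heritability and accuracy identities,
#' column means, the ability-on-heritability regression) and as the
#' calibration targets of the synthetic-herd generator.
#'
#' @return a `data.frame`:
#' * `yakTraitSummary()`: `trait`, `n`, `mean`, `sd`, `minimum`,
#'   `maximum`, `definition` (12 rows: four traits at 6, 12, 30 months).
#' * `yakVarianceComponents()`: `trait`, `sigma_a2`, `sigma_e2`, `h2`,
#'   `se_h2` (8 early-growth traits).
#' * `yakCVResults()`: `trait`, `method`, `ability`, `accuracy` (8 traits
#'   x 5 methods).
#' * `yakLaterAgeCorrelations()`: `method`, `pearson_r` (predictions at 6
#'   months vs observations at 30 months).
#' @export
yakTraitSummary <- function() read.csv(refPath("yak_trait_summary.csv"),
                                       stringsAsFactors = FALSE)

#' @rdname yakTraitSummary
#' @export
yakVarianceComponents <- function()
  read.csv(refPath("yak_variance_components.csv"), stringsAsFactors = FALSE)

#' @rdname yakTraitSummary
#' @export
yakCVResults <- function() read.csv(refPath("yak_cv_results.csv"),
                                    stringsAsFactors = FALSE)

#' @rdname yakTraitSummary
#' @export
yakLaterAgeCorrelations <- function()
  read.csv(refPath("yak_later_age_correlations.csv"),
           stringsAsFactors = FALSE)
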