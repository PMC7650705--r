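#' @include yakGP-package.R
NULL

#' GenotypePanel: animals-by-markers SNP genotypes with a marker map
#'
#' Container for a biallelic SNP panel coded as minor-allele counts
#' \{0, 1, 2\} with `NA` for missing calls. Rows are animals, columns are
#' markers. The marker map carries chromosome, identifier, base-pair
#' position (1-based, strictly increasing within chromosome) and the two
#' allele labels.
#'
#' @slot geno integer/numeric matrix, animals x markers, values in
#'   \{0, 1, 2, NA\}; dimnames give animal and marker identifiers.
#' @slot map `data.frame` with columns `chrom`, `id`, `pos`, `alleleA`,
#'   `alleleB`; one row per marker, in column order of `geno`.
#'
#' @seealso [GenotypePanel()], [simulateGenotypes()], [readPlinkText()]
#' @export
setClass("GenotypePanel",
  representation(geno = "matrix", map = "data.frame"))

setValidity("GenotypePanel", function(object) {
  g <- object@geno
  map <- object@map
  msgs <- character()
  if (ncol(g) != nrow(map))
    msgs <- c(msgs, "number of marker-map rows must equal number of genotype columns")
  need <- c("chrom", "id", "pos", "alleleA", "alleleB")
  if (!all(need %in% names(map)))
    msgs <- c(msgs, paste("marker map must have columns:", paste(need, collapse = ", ")))
  vals <- g[!is.na(g)]
  if (length(vals) && !all(vals %in% c(0, 1, 2)))
    msgs <- c(msgs, "genotype codes must be 0, 1, 2 or NA")
  if (is.null(rownames(g)))
    msgs <- c(msgs, "genotype matrix must have animal identifiers as rownames")
  if (all(need %in% names(map)) && nrow(map) > 1) {
    bad <- vapply(split(map$pos, map$chrom),
                  function(p) any(diff(p) <= 0), logical(1))
    if (any(bad))
      msgs <- c(msgs, "bp positions must be strictly increasing within chromosome")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a GenotypePanel
#'
#' @param geno animals x markers matrix of \{0,1,2,NA\} codes. Rownames are
#'   animal ids (generated as `an_1..an_n` if absent), colnames marker ids.
#' @param map marker map `data.frame` (`chrom`, `id`, `pos`, `alleleA`,
#'   `alleleB`). If `NULL`, a single-chromosome map with unit spacing is
#'   synthesised.
#' @return a [GenotypePanel-class] object.
#' @examples
#' g <- matrix(c(0, 1, 2, 1), 2, 2, dimnames = list(c("a1", "a2"), NULL))
#' GenotypePanel(g)
#' @export
GenotypePanel <- function(geno, map = NULL) {
  geno <- as.matrix(geno)
  if (is.null(rownames(geno)))
    rownames(geno) <- paste0("an_", seq_len(nrow(geno)))
  if (is.null(map)) {
    map <- data.frame(chrom = 1L, id = paste0("snp_", seq_len(ncol(geno))),
                      pos = seq_len(ncol(geno)),
                      alleleA = "A", alleleB = "B",
                      stringsAsFactors = FALSE)
  }
  if (is.null(colnames(geno))) colnames(geno) <- map$id
  new("GenotypePanel", geno = geno, map = map)
}

#' GRM: genomic relationship matrix
#'
#' VanRaden (method 1) genomic relationship matrix
#' \eqn{G = MM'/(2\sum_j p_j(1-p_j))} where `M` is the genotype matrix
#' centered by twice the allele frequency, optionally blended with the
#' identity for numerical positive definiteness.
#'
#' @slot mat symmetric animals x animals numeric matrix.
#' @slot freq allele frequencies used for centering (one per marker).
#' @slot blend blending weight `w` applied as `(1-w) G + w I` (0 if none).
#' @seealso [vanRadenGRM()], [blendGRM()]
#' @export
setClass("GRM",
  representation(mat = "matrix", freq = "numeric", blend = "numeric"))

setValidity("GRM", function(object) {
  m <- object@mat
  if (nrow(m) != ncol(m)) return("relationship matrix must be square")
  if (max(abs(m - t(m))) > 1e-8 * (1 + max(abs(m))))
    return("relationship matrix must be symmetric")
  TRUE
})

#' VarianceComponents: REML estimates of a single-trait GBLUP model
#'
#' Additive genetic and residual variances under
#' \eqn{y = 1\mu + g + e,\; g \sim N(0, G\sigma_a^2),\; e \sim N(0, I\sigma_e^2)},
#' with narrow-sense heritability
#' \eqn{h^2 = \sigma_a^2 / (\sigma_a^2 + \sigma_e^2)}.
#'
#' @slot sigmaA2 additive genetic variance (trait units squared).
#' @slot sigmaE2 residual variance (trait units squared).
#' @slot h2 heritability.
#' @slot seH2 delta-method standard error of the heritability.
#' @slot converged logical convergence flag.
#' @slot nIterations iterations used.
#' @slot logLik restricted log-likelihood at the optimum.
#' @seealso [remlFit()], [heritability()]
#' @export
setClass("VarianceComponents",
  representation(sigmaA2 = "numeric", sigmaE2 = "numeric", h2 = "numeric",
                 seH2 = "numeric", converged = "logical",
                 nIterations = "integer", logLik = "numeric"))

#' PosteriorSummary: posterior summaries of a Bayesian marker-effect model
#'
#' Output of the single-site Gibbs samplers for Bayes A, Bayes B, Bayes C
#' and the Bayesian Lasso. Marker effects are on the scale of centered
#' genotype codes; `effects[j]` is the posterior mean of (indicator x
#' effect) for marker j.
#'
#' @slot model one of `"BayesA"`, `"BayesB"`, `"BayesC"`, `"BayesLasso"`.
#' @slot effects posterior mean marker effects (trait units per allele copy).
#' @slot inclusionProb posterior inclusion probabilities (all 1 for
#'   Bayes A / Lasso).
#' @slot mu posterior mean intercept.
#' @slot sigmaE2 posterior mean residual variance.
#' @slot pi posterior mean proportion of zero-effect markers (`NA` for
#'   Bayes A / Lasso; the fixed constant for Bayes B).
#' @slot lambda posterior mean of the Lasso regularisation parameter
#'   \eqn{\lambda} (`NA` otherwise).
#' @slot markerIds marker identifiers, in effect order.
#' @slot freq allele frequencies used to center genotype codes (needed to
#'   score new animals consistently).
#' @slot fitted posterior mean genetic value of each training animal.
#' @slot fittedSD posterior standard deviation of the genetic values.
#' @slot chain list with the chain settings actually used and split-chain
#'   diagnostics (`halfFitted`: genetic-value means from each chain half).
#' @seealso [fitBayes()], [gebvFromEffects()]
#' @export
setClass("PosteriorSummary",
  representation(model = "character", effects = "numeric",
                 inclusionProb = "numeric", mu = "numeric",
                 sigmaE2 = "numeric", pi = "numeric", lambda = "numeric",
                 markerIds = "character", freq = "numeric",
                 fitted = "numeric", fittedSD = "numeric", chain = "list"))

#' CVResult: repeated k-fold cross-validation results
#'
#' Per-cell predictive abilities (Pearson correlation between GEBV and
#' phenotype in the validation fold) for each repeat x fold x method, with
#' the whole-data heritability used to scale abilities into accuracies.
#'
#' @slot cells `data.frame` with columns `rep`, `fold`, `method`, `ability`,
#'   `nValidation`.
#' @slot folds `data.frame` with columns `rep`, `fold`, `animal`.
#' @slot h2 whole-data heritability estimate used for the accuracy scaling.
#' @slot k folds per repeat.
#' @slot repeats number of repeats.
#' @slot seed RNG seed used for the fold partition.
#' @seealso [runCV()], [cvSummary()]
#' @export
setClass("CVResult",
  representation(cells = "data.frame", folds = "data.frame", h2 = "numeric",
                 k = "integer", repeats = "integer", seed = "integer"))
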