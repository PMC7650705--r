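#' @include AllClasses.R
NULL

#' Accessors for yakGP objects
#'
#' Small accessor functions in place of direct slot access.
#'
#' @param x a yakGP object ([GenotypePanel-class], [GRM-class],
#'   [VarianceComponents-class], [PosteriorSummary-class],
#'   [CVResult-class], as appropriate).
#' @name accessors
NULL

#' @rdname accessors
#' @return `genoMatrix`: the animals x markers code matrix.
#' @export
genoMatrix <- function(x) x@geno

#' @rdname accessors
#' @return `markerMap`: the marker map `data.frame`.
#' @export
markerMap <- function(x) x@map

#' @rdname accessors
#' @return `nAnimals` / `nMarkers`: panel dimensions.
#' @export
nAnimals <- function(x) nrow(x@geno)

#' @rdname accessors
#' @export
nMarkers <- function(x) ncol(x@geno)

#' @rdname accessors
#' @return `animalIds`: animal identifiers.
#' @export
animalIds <- function(x) rownames(x@geno)

#' @rdname accessors
#' @return `grmMatrix`: the dense relationship matrix.
#' @export
grmMatrix <- function(x) x@mat

#' @rdname accessors
#' @return `alleleFreqs`: centering allele frequencies.
#' @export
alleleFreqs <- function(x) x@freq

#' @rdname accessors
#' @return `blendWeight`: identity blending weight of a [GRM-class].
#' @export
blendWeight <- function(x) x@blend

#' @rdname accessors
#' @return `sigmaA2` / `sigmaE2`: variance-component estimates.
#' @export
sigmaA2 <- function(x) x@sigmaA2

#' @rdname accessors
#' @export
sigmaE2 <- function(x) x@sigmaE2

#' @rdname accessors
#' @return `h2`: the heritability estimate.
#' @export
h2 <- function(x) x@h2

#' @rdname accessors
#' @return `seH2`: its delta-method standard error.
#' @export
seH2 <- function(x) x@seH2

#' @rdname accessors
#' @return `isConverged`: REML convergence flag.
#' @export
isConverged <- function(x) x@converged

#' @rdname accessors
#' @return `markerEffects`: posterior mean marker effects.
#' @export
markerEffects <- function(x) x@effects

#' @rdname accessors
#' @return `inclusionProb`: posterior inclusion probabilities.
#' @export
inclusionProb <- function(x) x@inclusionProb

#' @rdname accessors
#' @return `cvCells`: the per repeat x fold x method ability table.
#' @export
cvCells <- function(x) x@cells

setMethod("show", "GenotypePanel", function(object) {
  g <- object@geno
  cat("GenotypePanel:", nrow(g), "animals x", ncol(g), "markers on",
      length(unique(object@map$chrom)), "chromosome(s)\n")
  miss <- mean(is.na(g))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(object)
})

setMethod("show", "GRM", function(object) {
  cat("GRM:", nrow(object@mat), "x", ncol(object@mat),
      sprintf("(blend w = %.3g, mean diagonal = %.3f)\n",
              object@blend, mean(diag(object@mat))))
  invisible(object)
})

setMethod("show", "VarianceComponents", function(object) {
  cat(sprintf(
    "VarianceComponents: sigma_a2 = %.4g, sigma_e2 = %.4g, h2 = %.3f +/- %.3f\n",
    object@sigmaA2, object@sigmaE2, object@h2, object@seH2))
  cat(sprintf("  REML %s in %d iterations\n",
              if (object@converged) "converged" else "did NOT converge",
              object@nIterations))
  invisible(object)
})

setMethod("show", "PosteriorSummary", function(object) {
  cat(sprintf("PosteriorSummary (%s): %d markers, mu = %.4g, sigma_e2 = %.4g\n",
              object@model, length(object@effects), object@mu, object@sigmaE2))
  if (!is.na(object@pi)) cat(sprintf("  pi = %.3f\n", object@pi))
  if (!is.na(object@lambda)) cat(sprintf("  lambda = %.4g\n", object@lambda))
  ch <- object@chain
  cat(sprintf("  chain: %d iterations, %d burn-in, thin %d\n",
              ch$chainLength, ch$burnIn, ch$thin))
  invisible(object)
})

setMethod("show", "CVResult", function(object) {
  cat(sprintf("CVResult: %d-fold x %d repeats, h2 = %.3f\n",
              object@k, object@repeats, object@h2))
  print(cvSummary(object))
  invisible(object)
})
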