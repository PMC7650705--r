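#' @include AllClasses.R
NULL

#' VanRaden genomic relationship matrix
#'
#' Method-1 construction \eqn{G = MM' / (2 \sum_j p_j (1 - p_j))}, where
#' `M` is the genotype code matrix with column j centered by `2 p_j`.
#' Frequencies default to the observed sample frequencies (the only ones
#' available without an external reference), in which case the column sums
#' of `M` — and hence the row sums of `G` — are exactly zero. Missing
#' genotypes are mean-imputed per marker (replaced by `2 p_j`) before
#' centering, the standard chip-panel default.
#'
#' @param panel a [GenotypePanel-class].
#' @param freqs `"observed"` (default) or a numeric vector of per-marker
#'   allele frequencies used for centering and scaling.
#' @return a [GRM-class] (blend weight 0).
#' @examples
#' p <- GenotypePanel(matrix(c(0, 2), 2, 1, dimnames = list(c("a", "b"), "s1")))
#' grmMatrix(vanRadenGRM(p))  # [[2, -2], [-2, 2]]
#' @export
vanRadenGRM <- function(panel, freqs = "observed") {
  stopifnot(is(panel, "GenotypePanel"))
  Z <- genoMatrix(panel)
  pObs <- colMeans(Z, na.rm = TRUE) / 2
  p <- if (identical(freqs, "observed")) pObs else {
    stopifnot(is.numeric(freqs), length(freqs) == ncol(Z))
    freqs
  }
  if (anyNA(Z)) {
    for (j in which(colSums(is.na(Z)) > 0))
      Z[is.na(Z[, j]), j] <- 2 * pObs[j]
  }
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0)
    stop("vanRadenGRM: all markers monomorphic (zero VanRaden denominator)",
         call. = FALSE)
  M <- sweep(Z, 2, 2 * p)
  G <- tcrossprod(M) / denom
  G <- (G + t(G)) / 2
  new("GRM", mat = G, freq = unname(p), blend = 0)
}

#' Blend a GRM with the identity
#'
#' `G* = (1 - w) G + w I`. A small identity blend bounds the smallest
#' eigenvalue away from zero so the mixed-model equations and REML are
#' well posed even when the marker-derived matrix is singular (e.g.,
#' duplicate animals, or more animals than informative markers).
#'
#' @param grm a [GRM-class].
#' @param weight blending weight in `[0, 0.25]` (default 0.05).
#' @return a [GRM-class] with the blend recorded.
#' @export
blendGRM <- function(grm, weight = 0.05) {
  stopifnot(is(grm, "GRM"))
  if (weight < 0 || weight > 0.25)
    stop("blendGRM: weight must be in [0, 0.25]", call. = FALSE)
  if (weight == 0) return(grm)
  G <- (1 - weight) * grmMatrix(grm)
  diag(G) <- diag(G) + weight
  new("GRM", mat = G, freq = grm@freq, blend = weight)
}
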