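#' @include AllClasses.R
NULL

gebvTable <- function(id, gebv, method, sd = NA_real_) {
  data.frame(id = as.character(id), gebv = as.numeric(gebv),
             sd = rep_len(sd, length(id)), method = rep_len(method, length(id)),
             stringsAsFactors = FALSE)
}

#' GBLUP breeding values from the mixed-model equations
#'
#' Solves Henderson's mixed-model equations for \eqn{y = 1\mu + g + e}
#' with \eqn{g \sim N(0, G\sigma_a^2)} and shrinkage ratio
#' \eqn{\lambda = \sigma_e^2/\sigma_a^2}, via the equivalent
#' phenotypic-covariance form \eqn{\hat g = \sigma_a^2 G V^{-1}(y - 1\hat\mu)}
#' with \eqn{V = \sigma_a^2 G + \sigma_e^2 I} and GLS intercept.
#'
#' @param y phenotype vector (names taken as animal ids if present,
#'   otherwise the GRM rownames are used).
#' @param grm positive-definite [GRM-class].
#' @param varcomps a [VarianceComponents-class] (typically from [remlFit()]).
#' @return GEBV `data.frame` (`id`, `gebv`, `sd`, `method`) with the GLS
#'   intercept as attribute `mu`.
#' @export
fitGBLUP <- function(y, grm, varcomps) {
  stopifnot(is(grm, "GRM"), is(varcomps, "VarianceComponents"))
  G <- grmMatrix(grm)
  n <- length(y)
  stopifnot(n == nrow(G))
  sa <- sigmaA2(varcomps); se <- sigmaE2(varcomps)
  V <- sa * G
  diag(V) <- diag(V) + se
  Vi <- tryCatch(chol2inv(chol(V)), error = function(e)
    stop("fitGBLUP: singular covariance; blend the GRM (see blendGRM)",
         call. = FALSE))
  one <- rep(1, n)
  mu <- sum(Vi %*% y) / sum(Vi %*% one)
  g <- as.vector(sa * G %*% (Vi %*% (y - mu)))
  ids <- if (!is.null(names(y))) names(y) else rownames(G)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  out <- gebvTable(ids, g, "GBLUP")
  attr(out, "mu") <- mu
  out
}

#' GEBVs for animals whose phenotypes are masked
#'
#' Predicts genomic breeding values for a validation set from the joint
#' mixed-model equations in which the validation phenotypes are treated as
#' unknown: only the training animals contribute records, and
#' \eqn{\hat g_v = \sigma_a^2 G_{vt} V_{tt}^{-1} (y_t - 1\hat\mu)}. The
#' algebraically equivalent projection route
#' \eqn{\hat g_v = G_{vt} G_{tt}^{-1} \hat g_t} is available for
#' cross-checking.
#'
#' @param yTrain named phenotype vector of the training animals.
#' @param grmFull [GRM-class] covering training and validation animals.
#' @param varcomps a [VarianceComponents-class].
#' @param validationIds ids of animals to predict (disjoint from training).
#' @param route `"joint"` (default) or `"projection"`.
#' @return GEBV `data.frame` for the validation animals (empty if
#'   `validationIds` is empty).
#' @export
predictMasked <- function(yTrain, grmFull, varcomps, validationIds,
                          route = c("joint", "projection")) {
  route <- match.arg(route)
  stopifnot(is(grmFull, "GRM"), !is.null(names(yTrain)))
  G <- grmMatrix(grmFull)
  ids <- rownames(G)
  trainIds <- names(yTrain)
  if (!length(trainIds)) stop("predictMasked: empty training set", call. = FALSE)
  if (length(intersect(trainIds, validationIds)))
    stop("predictMasked: training and validation ids overlap", call. = FALSE)
  if (!all(c(trainIds, validationIds) %in% ids))
    stop("predictMasked: ids missing from the GRM", call. = FALSE)
  if (!length(validationIds))
    return(gebvTable(character(0), numeric(0), "GBLUP"))
  ti <- match(trainIds, ids); vi <- match(validationIds, ids)
  sa <- sigmaA2(varcomps); se <- sigmaE2(varcomps)
  if (route == "joint") {
    Vtt <- sa * G[ti, ti]
    diag(Vtt) <- diag(Vtt) + se
    Vi <- chol2inv(chol(Vtt))
    mu <- sum(Vi %*% yTrain) / sum(Vi)
    gv <- as.vector(sa * G[vi, ti, drop = FALSE] %*% (Vi %*% (yTrain - mu)))
  } else {
    sub <- new("GRM", mat = G[ti, ti], freq = grmFull@freq, blend = grmFull@blend)
    gt <- fitGBLUP(yTrain, sub, varcomps)$gebv
    gv <- as.vector(G[vi, ti, drop = FALSE] %*% solve(G[ti, ti], gt))
  }
  gebvTable(validationIds, gv, "GBLUP")
}
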