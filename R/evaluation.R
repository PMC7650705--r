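#' @include AllClasses.R
NULL

#' Random fold assignments for repeated k-fold cross-validation
#'
#' Per repeat, a fresh random partition of the animals into `k` folds with
#' sizes differing by at most one. Reproducible from the seed.
#'
#' @param animalIds character vector of animal ids.
#' @param k folds per repeat (default 5).
#' @param repeats number of repeats (default 10).
#' @param seed RNG seed.
#' @return `data.frame` with columns `rep`, `fold`, `animal`.
#' @export
makeFolds <- function(animalIds, k = 5L, repeats = 10L, seed = 1L) {
  n <- length(animalIds)
  k <- as.integer(k); repeats <- as.integer(repeats)
  if (k < 2L) stop("makeFolds: k must be at least 2", call. = FALSE)
  if (k > n) stop("makeFolds: k cannot exceed the number of animals",
                  call. = FALSE)
  set.seed(seed)
  do.call(rbind, lapply(seq_len(repeats), function(r) {
    data.frame(rep = r, fold = rep(seq_len(k), length.out = n),
               animal = sample(animalIds), stringsAsFactors = FALSE)
  }))
}

#' Predictive ability: correlation between GEBV and phenotype
#'
#' @param gebv,y paired vectors (at least 3 pairs, both with nonzero
#'   variance).
#' @return Pearson correlation.
#' @export
predictiveAbility <- function(gebv, y) {
  if (length(gebv) != length(y) || length(y) < 3)
    stop("predictiveAbility: need at least 3 paired observations",
         call. = FALSE)
  if (sd(gebv) == 0 || sd(y) == 0)
    stop("predictiveAbility: undefined under zero variance", call. = FALSE)
  cor(gebv, y)
}

#' Predictive accuracy: ability scaled by the square root of heritability
#'
#' `ability / sqrt(h2)` — an estimate of the correlation between GEBV and
#' true breeding value. The square-root denominator is the form under
#' which every published ability/accuracy pair in the reference tables
#' reconciles (e.g., 0.164/sqrt(0.35) = 0.277).
#'
#' @param ability predictive ability (correlation).
#' @param h2 heritability in (0, 1].
#' @return accuracy; vectorised.
#' @export
predictiveAccuracy <- function(ability, h2) {
  if (any(h2 <= 0) || any(h2 > 1))
    stop("predictiveAccuracy: h2 must be in (0, 1]", call. = FALSE)
  ability / sqrt(h2)
}

#' Repeated k-fold cross-validation of genomic prediction methods
#'
#' For every repeat x fold, the chosen methods are fitted on the training
#' animals and the validation animals' phenotypes are withheld; predictive
#' ability is the Pearson correlation between validation GEBVs and
#' phenotypes. GBLUP predicts through the masked mixed-model equations
#' ([predictMasked()]); Bayesian models are refitted per training set and
#' validation GEBVs accumulated from the posterior mean marker effects
#' ([gebvFromEffects()]). Fold assignments are shared across methods.
#' Animals missing the phenotype are dropped (with a message) before
#' partitioning. Accuracy uses the whole-data REML heritability.
#'
#' @param y named phenotype vector (NAs dropped per trait).
#' @param panel a [GenotypePanel-class] covering the animals in `y`.
#' @param methods subset of `c("GBLUP", "BayesA", "BayesB", "BayesC",
#'   "BayesLasso")`.
#' @param k,repeats,seed cross-validation controls (defaults 5, 10, 1).
#' @param grm optional precomputed [GRM-class] (otherwise a blended
#'   VanRaden matrix is built from the panel).
#' @param varcomps optional [VarianceComponents-class]; otherwise fitted by
#'   [remlFit()] on the whole data.
#' @param hyper [bayesHyperparams()] for the Bayesian methods.
#' @param blend identity blending weight for an internally built GRM.
#' @return a [CVResult-class].
#' @export
runCV <- function(y, panel, methods = "GBLUP", k = 5L, repeats = 10L,
                  seed = 1L, grm = NULL, varcomps = NULL,
                  hyper = bayesHyperparams(), blend = 0.05) {
  allMethods <- c("GBLUP", "BayesA", "BayesB", "BayesC", "BayesLasso")
  if (!length(methods)) stop("runCV: empty method list", call. = FALSE)
  methods <- match.arg(methods, allMethods, several.ok = TRUE)
  stopifnot(is(panel, "GenotypePanel"), !is.null(names(y)))

  keep <- names(y)[!is.na(y)]
  if (length(keep) < length(y))
    message("runCV: dropping ", length(y) - length(keep),
            " animal(s) missing the trait")
  y <- y[keep]
  Z <- genoMatrix(panel)
  stopifnot(all(keep %in% rownames(Z)))
  panelUsed <- new("GenotypePanel", geno = Z[keep, , drop = FALSE],
                   map = markerMap(panel))

  if (is.null(grm)) grm <- blendGRM(vanRadenGRM(panelUsed), blend)
  if (is.null(varcomps)) varcomps <- remlFit(y, grm)

  folds <- makeFolds(keep, k = k, repeats = repeats, seed = seed)
  cells <- list()
  for (r in seq_len(repeats)) {
    fr <- folds[folds$rep == r, ]
    for (f in seq_len(k)) {
      valIds <- fr$animal[fr$fold == f]
      trainIds <- setdiff(keep, valIds)
      bayesFit <- list()
      for (meth in methods) {
        if (meth == "GBLUP") {
          pred <- predictMasked(y[trainIds], grm, varcomps, valIds)
        } else {
          code <- sub("^Bayes", "", meth)
          trPanel <- new("GenotypePanel",
                         geno = Z[trainIds, , drop = FALSE],
                         map = markerMap(panel))
          hyperFold <- hyper
          hyperFold$seed <- hyper$seed + 7919L * r + 101L * f
          post <- fitBayes(y[trainIds], trPanel, model = code,
                           hyper = hyperFold)
          vaPanel <- new("GenotypePanel",
                         geno = Z[valIds, , drop = FALSE],
                         map = markerMap(panel))
          pred <- gebvFromEffects(vaPanel, post)
        }
        ability <- predictiveAbility(pred$gebv[match(valIds, pred$id)],
                                     y[valIds])
        cells[[length(cells) + 1L]] <-
          data.frame(rep = r, fold = f, method = meth, ability = ability,
                     nValidation = length(valIds), stringsAsFactors = FALSE)
      }
    }
  }
  new("CVResult", cells = do.call(rbind, cells), folds = folds,
      h2 = h2(varcomps), k = as.integer(k), repeats = as.integer(repeats),
      seed = as.integer(seed))
}

#' Aggregate a CVResult into mean ability and accuracy per method
#'
#' Mean of the per-fold correlations over all repeat x fold cells, and the
#' corresponding accuracy using the stored whole-data heritability.
#'
#' @param x a [CVResult-class].
#' @return `data.frame` with `method`, `meanAbility`, `meanAccuracy`,
#'   `nCells`.
#' @export
cvSummary <- function(x) {
  stopifnot(is(x, "CVResult"))
  sp <- split(x@cells$ability, x@cells$method)
  out <- data.frame(method = names(sp),
                    meanAbility = vapply(sp, mean, numeric(1)),
                    meanAccuracy = vapply(sp, function(a)
                      predictiveAccuracy(mean(a), x@h2), numeric(1)),
                    nCells = vapply(sp, length, numeric(1)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Ordinary least-squares regression of predictive ability on heritability
#'
#' The slope summarises how ability rises with trait heritability across a
#' set of traits (the published regression coefficients are 0.40-0.44).
#'
#' @param abilities per-trait predictive abilities (>= 3 traits).
#' @param h2s matching per-trait heritabilities (nonconstant).
#' @return named vector `c(intercept, slope)`.
#' @export
abilityH2Regression <- function(abilities, h2s) {
  if (length(abilities) != length(h2s) || length(h2s) < 3)
    stop("abilityH2Regression: need at least 3 traits", call. = FALSE)
  if (sd(h2s) == 0)
    stop("abilityH2Regression: zero variance in h2", call. = FALSE)
  cf <- coef(lm(abilities ~ h2s))
  c(intercept = unname(cf[1]), slope = unname(cf[2]))
}

#' Correlation between early-age predictions and later-age observations
#'
#' Pearson correlation (with the two-sided t-transform p-value) between
#' phenotype predictions made at the early age stage and observed
#' phenotypes at the later stage; animals lacking the later record are
#' dropped.
#'
#' @param predictions named or plain vector of early-age predictions.
#' @param observations matching later-age observations (NA allowed).
#' @return list with `r` and `p.value`.
#' @export
laterAgeCorrelation <- function(predictions, observations) {
  ok <- !is.na(predictions) & !is.na(observations)
  x <- predictions[ok]; z <- observations[ok]
  if (length(x) < 3)
    stop("laterAgeCorrelation: need at least 3 complete pairs", call. = FALSE)
  if (sd(x) == 0 || sd(z) == 0)
    stop("laterAgeCorrelation: undefined under zero variance", call. = FALSE)
  ct <- cor.test(x, z, method = "pearson")
  list(r = unname(ct$estimate), p.value = ct$p.value)
}
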