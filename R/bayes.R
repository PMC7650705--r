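#' @include AllClasses.R
NULL

#' Hyperparameters and chain settings for the Bayesian samplers
#'
#' Defaults: prior degrees of freedom `nu = 4.2` (conventional for
#' scaled-inverse-chi-square marker-variance priors); prior scale `S`
#' solved at fit time (when `scale = NA`) so the prior mean marker variance
#' matches \eqn{\sigma_a^2 / ((1-\pi)\, 2\sum_j p_j(1-p_j))} with
#' \eqn{\sigma_a^2} from a REML pre-fit; `pi = 0.95` for Bayes B (fixed)
#' and a uniform(0,1) prior (initialised at 0.5) for Bayes C; Gamma(0.1,
#' 0.1) prior on the Lasso \eqn{\lambda^2}. Chains default to 20,000
#' iterations with 5,000 burn-in and thinning 5.
#'
#' @param nu marker-variance prior degrees of freedom (> 2).
#' @param scale marker-variance prior scale; `NA` = solve from a REML
#'   pre-fit (see above).
#' @param pi proportion of zero-effect markers; `NA` = model default
#'   (0 for A/Lasso, 0.95 for B, initial 0.5 for C).
#' @param lassoShape,lassoRate Gamma prior on \eqn{\lambda^2}.
#' @param chainLength,burnIn,thin MCMC controls
#'   (`chainLength > burnIn >= 0`).
#' @param seed chain RNG seed; fixed seed gives bit-identical chains.
#' @return list of class `BayesHyperparams`.
#' @export
bayesHyperparams <- function(nu = 4.2, scale = NA_real_, pi = NA_real_,
                             lassoShape = 0.1, lassoRate = 0.1,
                             chainLength = 20000L, burnIn = 5000L,
                             thin = 5L, seed = 1L) {
  if (nu <= 2) stop("bayesHyperparams: nu must exceed 2", call. = FALSE)
  if (!is.na(pi) && (pi < 0 || pi > 1))
    stop("bayesHyperparams: pi must be in [0, 1]", call. = FALSE)
  chainLength <- as.integer(chainLength); burnIn <- as.integer(burnIn)
  thin <- as.integer(thin)
  if (!(chainLength > burnIn && burnIn >= 0L && thin >= 1L))
    stop("bayesHyperparams: need chainLength > burnIn >= 0, thin >= 1",
         call. = FALSE)
  structure(list(nu = nu, scale = scale, pi = pi, lassoShape = lassoShape,
                 lassoRate = lassoRate, chainLength = chainLength,
                 burnIn = burnIn, thin = thin, seed = as.integer(seed)),
            class = "BayesHyperparams")
}

#' Fit a Bayesian marker-effect model by single-site Gibbs sampling
#'
#' Samples the intercept, per-marker effects and variances, the residual
#' variance, the inclusion indicators (Bayes B/C, via the standard joint
#' indicator-effect update), \eqn{\pi} (Bayes C) and \eqn{\lambda^2}
#' (Bayesian Lasso). Genotype codes enter on the \{0,1,2\} scale and are
#' centered internally by twice the observed allele frequency; the
#' intercept is sampled, not profiled. Posterior summaries are means over
#' the post-burn-in thinned samples.
#'
#' @param y phenotype vector (training animals, in panel row order).
#' @param panel a complete [GenotypePanel-class] for the training animals.
#' @param model `"A"`, `"B"`, `"C"` or `"Lasso"`.
#' @param hyper a [bayesHyperparams()] object.
#' @param fixed optional list for degenerate runs: `markerVar` and/or
#'   `sigmaE2` hold the corresponding variances fixed (used by the
#'   conjugate-posterior checks).
#' @return a [PosteriorSummary-class].
#' @export
fitBayes <- function(y, panel, model = c("A", "B", "C", "Lasso"),
                     hyper = bayesHyperparams(), fixed = NULL) {
  model <- match.arg(model)
  stopifnot(is(panel, "GenotypePanel"), inherits(hyper, "BayesHyperparams"))
  Z <- genoMatrix(panel)
  if (anyNA(Z)) stop("fitBayes: genotype matrix must be complete", call. = FALSE)
  if (length(y) != nrow(Z))
    stop("fitBayes: length(y) must match the panel", call. = FALSE)
  p <- colMeans(Z) / 2
  W <- sweep(Z, 2, 2 * p)
  modelCode <- match(model, c("A", "B", "C", "Lasso")) - 1L

  # pi is a fixed constant except in Bayes C, where it carries a
  # uniform(0,1) prior; supplying an explicit pi for Bayes C pins it
  # (used by the degenerate conjugate checks)
  piVal <- hyper$pi
  piFixed <- model != "C" || !is.na(piVal)
  if (is.na(piVal)) piVal <- switch(model, A = 0, B = 0.95, C = 0.5, Lasso = 0)

  fixMarkerVar <- if (!is.null(fixed$markerVar)) fixed$markerVar else NA_real_
  fixSigmaE <- if (!is.null(fixed$sigmaE2)) fixed$sigmaE2 else NA_real_

  scale <- hyper$scale
  sumpq <- 2 * sum(p * (1 - p))
  targetVar <- NA_real_
  if (is.na(scale) || model == "Lasso") {
    sa2 <- if (!is.na(fixMarkerVar)) fixMarkerVar * sumpq
    else if (var(y) <= 0) sumpq  # degenerate flat phenotype: unit marker scale
    else sigmaA2(remlFit(y, blendGRM(vanRadenGRM(panel), 0.05)))
    targetVar <- sa2 / (max(1 - piVal, 0.01) * sumpq)
    if (is.na(scale)) scale <- targetVar * (hyper$nu - 2) / hyper$nu
  }
  lambda2Init <- if (!is.na(fixMarkerVar)) {
    2 / fixMarkerVar
  } else if (is.finite(targetVar) && targetVar > 0) 2 / targetVar else 1

  nuE <- 4
  SE <- 0.5 * max(var(y), 1e-6) * (nuE - 2) / nuE

  set.seed(hyper$seed)
  res <- .bayes_gibbs_cpp(as.numeric(y), W, modelCode,
                          hyper$nu, scale, piVal, piFixed,
                          hyper$lassoShape, hyper$lassoRate, lambda2Init,
                          nuE, SE,
                          hyper$chainLength, hyper$burnIn, hyper$thin,
                          fixMarkerVar, fixSigmaE)

  new("PosteriorSummary",
      model = paste0("Bayes", model),
      effects = as.numeric(res$gMean),
      inclusionProb = as.numeric(res$inclusionProb),
      mu = res$mu, sigmaE2 = res$sigmaE2,
      pi = if (model %in% c("B", "C")) res$pi else NA_real_,
      lambda = if (model == "Lasso") res$lambda else NA_real_,
      markerIds = colnames(Z), freq = unname(p),
      fitted = setNames(as.numeric(res$fitted), rownames(Z)),
      fittedSD = as.numeric(res$fittedSD),
      chain = list(chainLength = hyper$chainLength, burnIn = hyper$burnIn,
                   thin = hyper$thin, seed = hyper$seed,
                   nSaved = res$nSaved, scale = scale, piInit = piVal,
                   halfFitted = rbind(first = as.numeric(res$halfFitted1),
                                      second = as.numeric(res$halfFitted2))))
}

#' Accumulate marker effects into GEBVs
#'
#' \eqn{GEBV_i = \sum_j w_{ij}\,\hat g_j} with genotype codes centered by
#' the training allele frequencies stored in the posterior summary, so the
#' operation applies equally to animals unseen in training.
#'
#' @param panel a [GenotypePanel-class] whose markers match the posterior
#'   summary (ids and order).
#' @param posterior a [PosteriorSummary-class] from [fitBayes()].
#' @return GEBV `data.frame` (`id`, `gebv`, `sd`, `method`).
#' @export
gebvFromEffects <- function(panel, posterior) {
  stopifnot(is(panel, "GenotypePanel"), is(posterior, "PosteriorSummary"))
  Z <- genoMatrix(panel)
  if (!identical(colnames(Z), posterior@markerIds))
    stop("gebvFromEffects: marker sets of panel and posterior do not match",
         call. = FALSE)
  W <- sweep(Z, 2, 2 * posterior@freq)
  g <- as.vector(W %*% markerEffects(posterior))
  gebvTable(rownames(Z), g, posterior@model)
}
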