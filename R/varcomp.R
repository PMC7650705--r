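#' @include AllClasses.R
NULL

#' Heritability from variance components
#'
#' \eqn{h^2 = \sigma_a^2 / (\sigma_a^2 + \sigma_e^2)}.
#'
#' @param sigmaA2 additive genetic variance (>= 0).
#' @param sigmaE2 residual variance (> 0; 0 allowed when `sigmaA2 > 0`).
#' @return heritability in `[0, 1]`; vectorised.
#' @examples
#' heritability(37.506, 68.848)  # 0.353
#' @export
heritability <- function(sigmaA2, sigmaE2) {
  if (any(sigmaA2 < 0) || any(sigmaE2 < 0))
    stop("heritability: variances must be non-negative", call. = FALSE)
  tot <- sigmaA2 + sigmaE2
  if (any(tot == 0))
    stop("heritability: undefined when both variances are zero", call. = FALSE)
  sigmaA2 / tot
}

#' REML variance components and heritability under the GBLUP model
#'
#' Average-information REML for \eqn{y = 1\mu + g + e}, \eqn{g \sim N(0,
#' G\sigma_a^2)}, \eqn{e \sim N(0, I\sigma_e^2)} (intercept as the only
#' fixed effect). The relationship matrix is eigen-decomposed once, after
#' which every iteration works on a diagonal covariance and costs O(n).
#' AI updates that leave the parameter space fall back to an EM step;
#' estimates pinned at the lower boundary are floored at a tiny multiple
#' of the phenotypic variance and reported with the convergence flag, not
#' as an error. The heritability standard error comes from the inverse
#' average-information matrix by the delta method.
#'
#' @param y phenotype vector, complete for the included animals (names, if
#'   present, must match the GRM ids).
#' @param grm a positive-definite [GRM-class] (blend first if needed, see
#'   [blendGRM()]).
#' @param tol convergence tolerance on the relative parameter change
#'   (default 1e-8).
#' @param maxIter iteration cap (default 200).
#' @return a [VarianceComponents-class].
#' @export
remlFit <- function(y, grm, tol = 1e-8, maxIter = 200L) {
  stopifnot(is(grm, "GRM"), is.numeric(y))
  G <- grmMatrix(grm)
  n <- length(y)
  if (n != nrow(G)) stop("remlFit: length(y) must match the GRM", call. = FALSE)
  if (anyNA(y)) stop("remlFit: y must be complete", call. = FALSE)
  eg <- eigen(G, symmetric = TRUE)
  d <- eg$values
  if (min(d) <= 1e-10)
    stop("remlFit: G is not positive definite; blend it first (see blendGRM)",
         call. = FALSE)
  yt <- as.vector(crossprod(eg$vectors, y))
  xt <- as.vector(crossprod(eg$vectors, rep(1, n)))
  vy <- var(y)
  floorVal <- 1e-8 * vy

  theta <- c(a = vy / 2, e = vy / 2)
  Pfun <- function(w, vi, xt, XtViX) vi * w - vi * xt * sum(xt * vi * w) / XtViX
  conv <- FALSE
  AIlast <- NULL
  for (it in seq_len(maxIter)) {
    v <- theta[1] * d + theta[2]
    vi <- 1 / v
    XtViX <- sum(xt^2 * vi)
    Py <- Pfun(yt, vi, xt, XtViX)
    aList <- list(d, rep(1, n))          # dV/d sigma_a2 = D, dV/d sigma_e2 = I
    score <- numeric(2)
    yPAPy <- numeric(2)
    trPA <- numeric(2)
    for (k in 1:2) {
      ak <- aList[[k]]
      trPA[k] <- sum(vi * ak) - sum(xt^2 * vi^2 * ak) / XtViX
      yPAPy[k] <- sum(ak * Py^2)
      score[k] <- -0.5 * (trPA[k] - yPAPy[k])
    }
    w1 <- aList[[1]] * Py
    w2 <- aList[[2]] * Py
    Pw1 <- Pfun(w1, vi, xt, XtViX)
    Pw2 <- Pfun(w2, vi, xt, XtViX)
    AI <- 0.5 * matrix(c(sum(w1 * Pw1), sum(w1 * Pw2),
                         sum(w1 * Pw2), sum(w2 * Pw2)), 2, 2)
    AIlast <- AI
    step <- tryCatch(solve(AI, score), error = function(e) NULL)
    thetaNew <- if (is.null(step)) rep(-1, 2) else theta + step
    if (any(thetaNew <= 0)) {
      # EM fallback: sigma_k^2 <- sigma_k^2 + sigma_k^4 / n (y'PA_kPy - tr(PA_k))
      thetaNew <- theta + theta^2 / n * (yPAPy - trPA)
      thetaNew[thetaNew <= 0] <- floorVal
    }
    delta <- max(abs(thetaNew - theta) / (abs(theta) + 1e-12))
    theta <- thetaNew
    if (delta < tol) { conv <- TRUE; break }
  }
  names(theta) <- NULL
  v <- theta[1] * d + theta[2]
  vi <- 1 / v
  XtViX <- sum(xt^2 * vi)
  Py <- Pfun(yt, vi, xt, XtViX)
  ll <- -0.5 * (sum(log(v)) + log(XtViX) + sum(yt * Py))

  h2hat <- theta[1] / sum(theta)
  se <- NA_real_
  vc <- tryCatch(solve(AIlast), error = function(e) NULL)
  if (!is.null(vc)) {
    gr <- c(theta[2], -theta[1]) / sum(theta)^2
    se2 <- drop(t(gr) %*% vc %*% gr)
    if (is.finite(se2) && se2 >= 0) se <- sqrt(se2)
  }
  new("VarianceComponents", sigmaA2 = theta[1], sigmaE2 = theta[2],
      h2 = h2hat, seH2 = se, converged = conv, nIterations = as.integer(it),
      logLik = ll)
}
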