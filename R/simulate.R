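#' @include AllClasses.R
NULL

#' Configuration for the synthetic herd generator
#'
#' Defaults emulate the study population the package was built around:
#' 354 female Ashidan yaks genotyped on a bovine HD chip, with post-QC
#' minor-allele frequencies approximately uniform from 0.06 to 0.5,
#' growth-trait heritabilities spanning 0.07-0.57, an additive architecture
#' of a few large QTL on a polygenic background, and a later-age (30-month)
#' trait genetically correlated with the early one. The SNP count defaults
#' to 10,000 — a desk-scale stand-in for the study's ~98.7k post-QC panel
#' that preserves the features the methods are sensitive to (MAF spectrum,
#' LD, architecture) at a fraction of the cost.
#'
#' @param nAnimals number of animals (default 354).
#' @param nSnps number of SNPs (default 10000).
#' @param nChromosomes chromosomes the markers are spread over (default 29,
#'   the bovid autosome count).
#' @param mafLow,mafHigh bounds of the uniform allele-frequency draw,
#'   `0 < mafLow < mafHigh <= 0.5` (defaults 0.06, 0.5).
#' @param ldDecay adjacent-marker dependence in `[0, 1)`: the probability
#'   that a haplotype copies its latent allele state from the previous
#'   marker rather than drawing it afresh (default 0.95, emulating the
#'   strong adjacent-marker LD of a dense bovine chip segregating in a
#'   small closed herd).
#' @param nQtl number of large-effect loci (default 20).
#' @param qtlVarFrac fraction of genetic variance carried by the QTL
#'   (default 0.5).
#' @param h2Target narrow-sense heritability in (0, 1) (default 0.35, the
#'   6-month body-weight value).
#' @param geneticCorrelationLater additive-value correlation between the
#'   early and later age stages, in `[-1, 1]` (default 0.9, the upper
#'   range of reported weaning-to-adult weight genetic correlations in
#'   bovids, chosen so whole-herd early-age GEBVs correlate with
#'   later-age phenotypes at roughly 0.4).
#' @param traitMean,traitSd phenotype scale in trait units (defaults 84.18
#'   kg and 10.31 kg, the 6-month body-weight summary).
#' @param seed RNG seed; identical seeds give bit-identical output.
#' @return a validated `list` of class `SimConfig`.
#' @examples
#' cfg <- simConfig(nAnimals = 100, nSnps = 500)
#' panel <- simulateGenotypes(cfg)
#' @export
simConfig <- function(nAnimals = 354L, nSnps = 10000L, nChromosomes = 29L,
                      mafLow = 0.06, mafHigh = 0.5, ldDecay = 0.95,
                      nQtl = 20L, qtlVarFrac = 0.5, h2Target = 0.35,
                      geneticCorrelationLater = 0.9,
                      traitMean = 84.18, traitSd = 10.31, seed = 1L) {
  nAnimals <- as.integer(nAnimals); nSnps <- as.integer(nSnps)
  nChromosomes <- as.integer(nChromosomes); nQtl <- as.integer(nQtl)
  if (nAnimals <= 0L || nSnps <= 0L || nChromosomes <= 0L)
    stop("simConfig: dimensions must be positive", call. = FALSE)
  if (!(mafLow > 0 && mafLow < mafHigh && mafHigh <= 0.5))
    stop("simConfig: need 0 < mafLow < mafHigh <= 0.5", call. = FALSE)
  if (ldDecay < 0 || ldDecay >= 1)
    stop("simConfig: ldDecay must be in [0, 1)", call. = FALSE)
  if (h2Target <= 0 || h2Target >= 1)
    stop("simConfig: h2Target must be in (0, 1)", call. = FALSE)
  if (nQtl > nSnps)
    stop("simConfig: nQtl cannot exceed nSnps", call. = FALSE)
  if (abs(geneticCorrelationLater) > 1)
    stop("simConfig: geneticCorrelationLater must be in [-1, 1]", call. = FALSE)
  if (qtlVarFrac < 0 || qtlVarFrac > 1)
    stop("simConfig: qtlVarFrac must be in [0, 1]", call. = FALSE)
  structure(list(nAnimals = nAnimals, nSnps = nSnps,
                 nChromosomes = nChromosomes, mafLow = mafLow,
                 mafHigh = mafHigh, ldDecay = ldDecay, nQtl = nQtl,
                 qtlVarFrac = qtlVarFrac, h2Target = h2Target,
                 geneticCorrelationLater = geneticCorrelationLater,
                 traitMean = traitMean, traitSd = traitSd,
                 seed = as.integer(seed)),
            class = "SimConfig")
}

#' Simulate a genotype panel
#'
#' Per-marker allele frequencies are drawn uniform(`mafLow`, `mafHigh`).
#' Each animal carries two haplotypes; a haplotype's allele at marker j is
#' the indicator `u < p_j` of a latent uniform `u` that, with probability
#' `ldDecay`, is copied from the previous marker on the same chromosome
#' (first-order haplotype copying on the quantile scale). Copying on the
#' latent scale keeps the marginal allele frequency of every marker exactly
#' at its drawn `p_j` while inducing positive correlation between adjacent
#' markers. Markers are split evenly across chromosomes with strictly
#' increasing bp positions.
#'
#' @param config a [simConfig()] object.
#' @return a [GenotypePanel-class] with complete (no missing) codes.
#' @export
simulateGenotypes <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  n <- config$nAnimals; m <- config$nSnps
  p <- runif(m, config$mafLow, config$mafHigh)

  chrom <- rep(seq_len(config$nChromosomes), length.out = m)
  chrom <- sort(chrom)
  pos <- unlist(lapply(split(seq_len(m), chrom), function(ix) {
    cumsum(sample(1000:100000, length(ix), replace = TRUE))
  }), use.names = FALSE)
  newChrom <- c(TRUE, chrom[-1] != chrom[-m])

  geno <- matrix(0L, n, m)
  for (hap in 1:2) {
    u <- runif(n)
    for (j in seq_len(m)) {
      if (newChrom[j]) {
        u <- runif(n)
      } else {
        fresh <- runif(n) >= config$ldDecay
        if (any(fresh)) u[fresh] <- runif(sum(fresh))
      }
      geno[, j] <- geno[, j] + (u < p[j])
    }
  }
  rownames(geno) <- sprintf("an_%03d", seq_len(n))
  map <- data.frame(chrom = chrom,
                    id = sprintf("snp_%05d", seq_len(m)),
                    pos = pos, alleleA = "A", alleleB = "B",
                    stringsAsFactors = FALSE)
  colnames(geno) <- map$id
  new("GenotypePanel", geno = geno, map = map)
}

#' Simulate early- and later-age phenotypes with known genetic truth
#'
#' Additive model: a handful of QTL (`nQtl`) receive large effects and all
#' remaining markers small polygenic effects; components are scaled so the
#' QTL carry `qtlVarFrac` of the genetic variance and the total genetic
#' standard deviation is `traitSd * sqrt(h2Target)`. The residual variance
#' is set so the expected heritability equals `h2Target`. A later-age
#' phenotype is built from a genetic value correlated with the early one at
#' `geneticCorrelationLater` (same heritability and scale as the early
#' stage), with independent residuals.
#'
#' @param panel a complete [GenotypePanel-class] (no missing calls).
#' @param config the [simConfig()] used (its `seed + 1` seeds this step, so
#'   phenotype draws are reproducible independently of genotype draws).
#' @return a list with `phenotypes` (`data.frame`: `animal_id`, `trait`,
#'   `stage` in `early`/`later`, `value`) and `truth` (list: per-animal
#'   additive values, per-marker true effects, QTL indices, realized
#'   heritabilities computed from the realized additive and residual
#'   variances, residual variances used).
#' @export
simulatePhenotypes <- function(panel, config) {
  stopifnot(is(panel, "GenotypePanel"), inherits(config, "SimConfig"))
  Z <- genoMatrix(panel)
  if (anyNA(Z)) stop("simulatePhenotypes: genotype matrix has missing calls",
                     call. = FALSE)
  set.seed(config$seed + 1L)
  n <- nrow(Z); m <- ncol(Z)
  pHat <- colMeans(Z) / 2
  W <- sweep(Z, 2, 2 * pHat)

  qtl <- sort(sample.int(m, config$nQtl))
  poly <- setdiff(seq_len(m), qtl)
  sigmaA <- config$traitSd * sqrt(config$h2Target)

  drawEffects <- function() {
    beta <- numeric(m)
    beta[qtl] <- rnorm(length(qtl))
    if (length(poly)) beta[poly] <- rnorm(length(poly))
    aQ <- as.vector(W[, qtl, drop = FALSE] %*% beta[qtl])
    aP <- if (length(poly)) as.vector(W[, poly, drop = FALSE] %*% beta[poly]) else 0
    sQ <- sd(aQ); sP <- if (length(poly)) sd(aP) else 1
    fQ <- if (sQ > 0) sqrt(config$qtlVarFrac) * sigmaA / sQ else 0
    fP <- if (sP > 0) sqrt(1 - config$qtlVarFrac) * sigmaA / sP else 0
    beta[qtl] <- beta[qtl] * fQ
    if (length(poly)) beta[poly] <- beta[poly] * fP
    list(beta = beta, a = as.vector(W %*% beta))
  }

  early <- drawEffects()
  indep <- drawEffects()
  rho <- config$geneticCorrelationLater
  zE <- early$a / sd(early$a)
  zI <- indep$a / sd(indep$a)
  aLater <- sigmaA * (rho * zE + sqrt(1 - rho^2) * zI)
  betaLater <- (rho * sigmaA / sd(early$a)) * early$beta +
    (sqrt(1 - rho^2) * sigmaA / sd(indep$a)) * indep$beta

  h2 <- config$h2Target
  sigmaE2Early <- var(early$a) * (1 - h2) / h2
  sigmaE2Later <- var(aLater) * (1 - h2) / h2
  eEarly <- rnorm(n, 0, sqrt(sigmaE2Early))
  eLater <- rnorm(n, 0, sqrt(sigmaE2Later))

  ids <- rownames(Z)
  phen <- rbind(
    data.frame(animal_id = ids, trait = "trait", stage = "early",
               value = config$traitMean + early$a + eEarly,
               stringsAsFactors = FALSE),
    data.frame(animal_id = ids, trait = "trait", stage = "later",
               value = config$traitMean + aLater + eLater,
               stringsAsFactors = FALSE))

  truth <- list(
    additiveEarly = setNames(early$a, ids),
    additiveLater = setNames(aLater, ids),
    markerEffects = early$beta,
    markerEffectsLater = betaLater,
    qtlIndices = qtl,
    realizedH2Early = var(early$a) / (var(early$a) + var(eEarly)),
    realizedH2Later = var(aLater) / (var(aLater) + var(eLater)),
    sigmaE2Early = sigmaE2Early,
    sigmaE2Later = sigmaE2Later)
  list(phenotypes = phen, truth = truth)
}

#' Inject QC-relevant defects into a clean panel
#'
#' Produces fixtures for the quality-control filters: markers with missing
#' calls (call rate `1 - missingRate`), markers forced to sample MAF
#' < 0.01, and markers with a complete heterozygote deficit (half the
#' animals coded 0, half coded 2), which drives the Hardy-Weinberg
#' chi-square statistic to n and its p-value far below 1e-6. Injection
#' sets are disjoint, chosen in precedence order missing > maf > hwe.
#'
#' @param panel a complete [GenotypePanel-class].
#' @param nMissing number of markers receiving missing calls.
#' @param missingRate per-animal missing probability on those markers
#'   (default 0.15, failing a 0.90 call-rate filter).
#' @param nLowMaf number of markers forced below MAF 0.01.
#' @param nHweViolating number of Hardy-Weinberg-violating markers.
#' @param seed RNG seed.
#' @return list with `panel` (corrupted copy) and `manifest` (`data.frame`:
#'   `markerIndex`, `markerId`, `type` in `missing`/`maf`/`hwe`).
#' @export
corruptForQC <- function(panel, nMissing = 10L, missingRate = 0.15,
                         nLowMaf = 50L, nHweViolating = 5L, seed = 1L) {
  stopifnot(is(panel, "GenotypePanel"))
  g <- genoMatrix(panel)
  n <- nrow(g); m <- ncol(g)
  total <- nMissing + nLowMaf + nHweViolating
  if (total > m)
    stop("corruptForQC: injection counts exceed the number of markers",
         call. = FALSE)
  if (nHweViolating > 0L && n < 25L)
    stop("corruptForQC: need >= 25 animals for a deterministic HWE violation",
         call. = FALSE)
  set.seed(seed)
  pick <- sample.int(m, total)
  iMiss <- pick[seq_len(nMissing)]
  iMaf <- pick[nMissing + seq_len(nLowMaf)]
  iHwe <- pick[nMissing + nLowMaf + seq_len(nHweViolating)]

  nDrop <- max(ceiling(missingRate * n), if (nMissing) 1L else 0L)
  for (j in iMiss) g[sample.int(n, nDrop), j] <- NA
  for (j in iMaf) {
    col <- integer(n)
    if (1 / (2 * n) < 0.01) col[sample.int(n, 1L)] <- 1L
    g[, j] <- col
  }
  for (j in iHwe) {
    col <- integer(n)
    col[seq_len(floor(n / 2))] <- 2L
    g[, j] <- col[sample.int(n)]
  }
  manifest <- data.frame(
    markerIndex = c(iMiss, iMaf, iHwe),
    markerId = markerMap(panel)$id[c(iMiss, iMaf, iHwe)],
    type = rep(c("missing", "maf", "hwe"),
               times = c(nMissing, nLowMaf, nHweViolating)),
    stringsAsFactors = FALSE)
  list(panel = new("GenotypePanel", geno = g, map = markerMap(panel)),
       manifest = manifest)
}
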