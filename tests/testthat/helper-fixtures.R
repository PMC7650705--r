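# Shared fixtures, built once per test run and cached.

.fixtureCache <- new.env(parent = emptyenv())

cachedFixture <- function(name, expr) {
  if (!exists(name, envir = .fixtureCache))
    assign(name, force(expr), envir = .fixtureCache)
  get(name, envir = .fixtureCache)
}

# a mid-sized herd with phenotypes, GRM and REML fit
smallHerd <- function() cachedFixture("smallHerd", {
  cfg <- simConfig(nAnimals = 200, nSnps = 800, seed = 42)
  panel <- simulateGenotypes(cfg)
  sim <- simulatePhenotypes(panel, cfg)
  ph <- sim$phenotypes
  y <- setNames(ph$value[ph$stage == "early"],
                ph$animal_id[ph$stage == "early"])
  yLater <- setNames(ph$value[ph$stage == "later"],
                     ph$animal_id[ph$stage == "later"])
  grm <- blendGRM(vanRadenGRM(panel), 0.05)
  vc <- remlFit(y, grm)
  list(cfg = cfg, panel = panel, truth = sim$truth, y = y,
       yLater = yLater, grm = grm, vc = vc)
})

# tiny panel for cheap interface tests
tinyPanel <- function(n = 30, m = 40, seed = 7) {
  cfg <- simConfig(nAnimals = n, nSnps = m, nChromosomes = 3,
                   nQtl = min(5, m), seed = seed)
  simulateGenotypes(cfg)
}

simulatedTrait <- function(panel, cfg) {
  sim <- simulatePhenotypes(panel, cfg)
  ph <- sim$phenotypes
  list(y = setNames(ph$value[ph$stage == "early"],
                    ph$animal_id[ph$stage == "early"]),
       yLater = setNames(ph$value[ph$stage == "later"],
                         ph$animal_id[ph$stage == "later"]),
       truth = sim$truth)
}

# expected bin probabilities for the realized sample MAF of a marker with
# p ~ uniform(lo, hi) and allele counts Binomial(2n, p), folded at 0.5 —
# an exact mixture oracle, independent of the generator's code path
mafBinProbs <- function(breaks, n, lo, hi, grid = 400) {
  ps <- seq(lo, hi, length.out = grid)
  cnt <- 0:(2 * n)
  maf <- pmin(cnt, 2 * n - cnt) / (2 * n)
  probs <- rep(0, length(breaks) - 1)
  for (p in ps) {
    f <- dbinom(cnt, 2 * n, p)
    probs <- probs + vapply(seq_len(length(breaks) - 1), function(b)
      sum(f[maf >= breaks[b] & maf < breaks[b + 1]]), numeric(1))
  }
  probs / length(ps)
}

# closed-form 1-df Hardy-Weinberg chi-square from the count identity,
# independent of the package's expected-count route
hweChisqOracle <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  na <- 2 * naa + nAa
  if (nA == 0 || na == 0) return(0)
  n * (4 * nAA * naa - nAa^2)^2 / (nA^2 * na^2)
}

varComps <- function(sa, se) {
  new("VarianceComponents", sigmaA2 = sa, sigmaE2 = se,
      h2 = sa / (sa + se), seH2 = NA_real_, converged = TRUE,
      nIterations = 1L, logLik = 0)
}
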