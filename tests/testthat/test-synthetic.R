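test_that("simConfig validates its invariants", {
  expect_error(simConfig(nAnimals = 0), "positive")
  expect_error(simConfig(mafLow = 0), "mafLow")
  expect_error(simConfig(mafLow = 0.3, mafHigh = 0.2), "mafLow")
  expect_error(simConfig(h2Target = 1), "h2Target")
  expect_error(simConfig(nSnps = 10, nQtl = 11), "nQtl")
  expect_error(simConfig(ldDecay = 1), "ldDecay")
})

test_that("simulated genotypes respect codes, map order and the MAF floor", {
  cfg <- simConfig(nAnimals = 354, nSnps = 600, seed = 11)
  panel <- simulateGenotypes(cfg)
  g <- genoMatrix(panel)
  expect_true(all(g %in% 0:2))
  map <- markerMap(panel)
  expect_true(all(tapply(map$pos, map$chrom, function(p) all(diff(p) > 0))))
  maf <- apply(g, 2, snpMaf)
  # binomial slack around the hard floor of the frequency draw at n=354
  expect_true(all(maf >= cfg$mafLow - 3 * sqrt(0.06 * 0.94 / (2 * 354))))
})

test_that("the three generator operations are deterministic under a fixed seed", {
  cfg <- simConfig(nAnimals = 60, nSnps = 120, seed = 9)
  p1 <- simulateGenotypes(cfg)
  p2 <- simulateGenotypes(cfg)
  expect_identical(genoMatrix(p1), genoMatrix(p2))
  expect_identical(markerMap(p1), markerMap(p2))
  s1 <- simulatePhenotypes(p1, cfg)
  s2 <- simulatePhenotypes(p2, cfg)
  expect_identical(s1$phenotypes, s2$phenotypes)
  expect_identical(s1$truth, s2$truth)
  c1 <- corruptForQC(p1, 4, 0.15, 6, 2, seed = 3)
  c2 <- corruptForQC(p2, 4, 0.15, 6, 2, seed = 3)
  expect_identical(genoMatrix(c1$panel), genoMatrix(c2$panel))
  expect_identical(c1$manifest, c2$manifest)
})

test_that("ldDecay = 0 gives independent adjacent markers, high ldDecay strong dependence", {
  adjCor <- function(ld, seeds) {
    vapply(seeds, function(s) {
      cfg <- simConfig(nAnimals = 354, nSnps = 60, nChromosomes = 1,
                       ldDecay = ld, seed = s)
      g <- genoMatrix(simulateGenotypes(cfg))
      r <- vapply(seq_len(ncol(g) - 1), function(j)
        suppressWarnings(cor(g[, j], g[, j + 1])), numeric(1))
      mean(abs(r), na.rm = TRUE)
    }, numeric(1))
  }
  # E|r| under independence at n = 354 is about sqrt(2/(pi n)) ~ 0.042
  mean0 <- mean(adjCor(0, 1:20))
  expect_lt(mean0, 0.06)
  mean9 <- mean(adjCor(0.9, 21:25))
  expect_gt(mean9, 0.3)
})

test_that("realized MAF follows the uniform-mixture law in >= 95% of replicates", {
  breaks <- c(0, seq(0.08, 0.48, by = 0.05), 0.501)
  pr <- mafBinProbs(breaks, 354, 0.06, 0.5)
  fails <- 0L
  for (r in 1:20) {
    cfg <- simConfig(nAnimals = 354, nSnps = 1000, seed = 3000 + r)
    maf <- apply(genoMatrix(simulateGenotypes(cfg)), 2, snpMaf)
    obs <- as.vector(table(cut(maf, breaks, right = FALSE)))
    pv <- suppressWarnings(chisq.test(obs, p = pr, rescale.p = TRUE)$p.value)
    if (pv < 0.01) fails <- fails + 1L
  }
  expect_lte(fails, 1L)
})

test_that("phenotype generator hits the heritability target on average", {
  h2t <- 0.35
  reps <- 60
  realized <- vapply(seq_len(reps), function(s) {
    cfg <- simConfig(nAnimals = 354, nSnps = 2000, h2Target = h2t,
                     seed = 7000 + s)
    sim <- simulatePhenotypes(simulateGenotypes(cfg), cfg)
    sim$truth$realizedH2Early
  }, numeric(1))
  expect_lt(abs(mean(realized) - h2t), 0.03)
})

test_that("noise-free limit returns phenotype ~ mu + additive value", {
  cfg <- simConfig(nAnimals = 80, nSnps = 200, h2Target = 0.999, seed = 5)
  panel <- simulateGenotypes(cfg)
  sim <- simulatePhenotypes(panel, cfg)
  early <- sim$phenotypes[sim$phenotypes$stage == "early", ]
  resid <- early$value - cfg$traitMean - sim$truth$additiveEarly
  expect_lt(sd(resid), 0.05 * cfg$traitSd)
})

test_that("perfect genetic correlation makes the two stages' additive values collinear", {
  cfg <- simConfig(nAnimals = 100, nSnps = 300,
                   geneticCorrelationLater = 1, seed = 13)
  sim <- simulatePhenotypes(simulateGenotypes(cfg), cfg)
  expect_gt(cor(sim$truth$additiveEarly, sim$truth$additiveLater), 0.999)
})

test_that("corruptForQC injects exactly the requested defects", {
  panel <- tinyPanel(n = 120, m = 150, seed = 21)
  out <- corruptForQC(panel, nMissing = 8, missingRate = 0.15,
                      nLowMaf = 12, nHweViolating = 5, seed = 2)
  g <- genoMatrix(out$panel)
  man <- out$manifest
  expect_identical(as.vector(table(factor(man$type,
                                          c("missing", "maf", "hwe")))),
                   c(8L, 12L, 5L))
  expect_identical(anyDuplicated(man$markerIndex), 0L)
  for (j in man$markerIndex[man$type == "missing"])
    expect_lte(mean(!is.na(g[, j])), 0.90)
  for (j in man$markerIndex[man$type == "maf"])
    expect_lt(snpMaf(g[, j]), 0.01)
  for (j in man$markerIndex[man$type == "hwe"]) {
    x <- g[, j]
    p <- hweTest(sum(x == 0), sum(x == 1), sum(x == 2))$p.value
    expect_lt(p, 1e-6)
  }
  expect_error(corruptForQC(panel, nLowMaf = 200), "exceed")
})
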