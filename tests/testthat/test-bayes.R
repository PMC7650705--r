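oneMarkerFixture <- function() cachedFixture("oneMarker", {
  cfg <- simConfig(nAnimals = 120, nSnps = 1, nQtl = 1, seed = 7)
  panel <- simulateGenotypes(cfg)
  w <- genoMatrix(panel)[, 1] - 2 * mean(genoMatrix(panel)[, 1]) / 2
  set.seed(99)
  y <- 3 + 0.8 * w + rnorm(120, 0, 2)
  names(y) <- animalIds(panel)
  list(panel = panel, w = w, y = y)
})

test_that("hyperparameter constructor enforces chain and prior invariants", {
  expect_error(bayesHyperparams(nu = 2), "nu")
  expect_error(bayesHyperparams(pi = 1.2), "pi")
  expect_error(bayesHyperparams(chainLength = 100, burnIn = 100), "burnIn")
})

test_that("chains are bit-reproducible under a fixed seed", {
  herd <- smallHerd()
  hy <- bayesHyperparams(chainLength = 400, burnIn = 100, thin = 2, seed = 3)
  p1 <- fitBayes(herd$y, herd$panel, "B", hyper = hy)
  p2 <- fitBayes(herd$y, herd$panel, "B", hyper = hy)
  expect_identical(markerEffects(p1), markerEffects(p2))
  expect_identical(p1@fitted, p2@fitted)
  hy2 <- hy; hy2$seed <- 4
  p3 <- fitBayes(herd$y, herd$panel, "B", hyper = hy2)
  expect_false(identical(markerEffects(p1), markerEffects(p3)))
})

test_that("a constant phenotype leaves all posterior mean effects near zero", {
  panel <- tinyPanel(n = 60, m = 80, seed = 61)
  y <- rep(5, 60); names(y) <- animalIds(panel)
  hy <- bayesHyperparams(chainLength = 1000, burnIn = 200, thin = 2,
                         scale = 0.01, seed = 5)
  post <- fitBayes(y, panel, "A", hyper = hy)
  expect_lt(max(abs(markerEffects(post))), 0.05)
  expect_lt(post@sigmaE2, 0.5)
})

test_that("each sampler with fixed variances matches the conjugate closed form", {
  fx <- oneMarkerFixture()
  sg <- 0.5; se2 <- 4
  closed <- sum(fx$w * (fx$y - mean(fx$y))) / (sum(fx$w^2) + se2 / sg)
  for (mdl in c("A", "B", "C", "Lasso")) {
    est <- vapply(1:5, function(s) {
      hy <- bayesHyperparams(chainLength = 4000, burnIn = 1000, thin = 2,
                             pi = if (mdl %in% c("B", "C")) 0 else NA_real_,
                             seed = 100 + s)
      post <- fitBayes(fx$y, fx$panel, model = mdl, hyper = hy,
                       fixed = list(markerVar = sg, sigmaE2 = se2))
      markerEffects(post)
    }, numeric(1))
    mcse <- sd(est) / sqrt(length(est))
    expect_lt(abs(mean(est) - closed), 3 * mcse + 1e-4)
  }
})

test_that("Bayes C with pi pinned at 0 and common fixed variance reproduces ridge GEBVs", {
  panel <- tinyPanel(n = 80, m = 40, seed = 63)
  Z <- genoMatrix(panel); p <- colMeans(Z) / 2
  W <- sweep(Z, 2, 2 * p)
  set.seed(64)
  y <- 75 + as.vector(W %*% rnorm(40, 0, 0.4)) + rnorm(80, 0, 3)
  names(y) <- animalIds(panel)
  sg <- 0.2; se2 <- 9
  V <- sg * tcrossprod(W); diag(V) <- diag(V) + se2
  Vi <- solve(V); mu <- sum(Vi %*% y) / sum(Vi)
  ridge <- as.vector(W %*% solve(crossprod(W) + diag(se2 / sg, 40),
                                 crossprod(W, y - mu)))
  gebvs <- vapply(1:5, function(s) {
    hy <- bayesHyperparams(chainLength = 3000, burnIn = 500, thin = 2,
                           pi = 0, seed = 200 + s)
    post <- fitBayes(y, panel, "C", hyper = hy,
                     fixed = list(markerVar = sg, sigmaE2 = se2))
    gebvFromEffects(panel, post)$gebv
  }, numeric(80))
  mcse <- apply(gebvs, 1, sd) / sqrt(5)
  expect_true(all(abs(rowMeans(gebvs) - ridge) < 3 * mcse + 0.02))
})

test_that("Bayes B concentrates inclusion probability on true QTL markers", {
  diffs <- vapply(1:10, function(s) {
    cfg <- simConfig(nAnimals = 250, nSnps = 600, nQtl = 15,
                     qtlVarFrac = 0.8, h2Target = 0.5, ldDecay = 0,
                     seed = 300 + s)
    panel <- simulateGenotypes(cfg)
    tr <- simulatedTrait(panel, cfg)
    hy <- bayesHyperparams(chainLength = 1200, burnIn = 300, thin = 2,
                           seed = 300 + s)
    post <- fitBayes(tr$y, panel, "B", hyper = hy)
    ip <- inclusionProb(post)
    qtl <- tr$truth$qtlIndices
    mean(ip[qtl]) - mean(ip[-qtl])
  }, numeric(1))
  expect_lt(wilcox.test(diffs, alternative = "greater")$p.value, 0.01)
})

test_that("gebvFromEffects is consistent with the sampler's fitted values", {
  herd <- smallHerd()
  hy <- bayesHyperparams(chainLength = 600, burnIn = 100, thin = 2, seed = 8)
  post <- fitBayes(herd$y, herd$panel, "A", hyper = hy)
  gt <- gebvFromEffects(herd$panel, post)
  expect_lt(max(abs(unname(post@fitted) - gt$gebv)), 1e-8)
  # all-zero effects give all-zero GEBVs
  post0 <- post
  post0@effects <- rep(0, nMarkers(herd$panel))
  expect_true(all(gebvFromEffects(herd$panel, post0)$gebv == 0))
  # marker mismatch errors
  sub <- new("GenotypePanel",
             geno = genoMatrix(herd$panel)[, 1:10],
             map = markerMap(herd$panel)[1:10, ])
  expect_error(gebvFromEffects(sub, post), "marker sets")
})

test_that("doubling the chain moves GEBVs by less than the half-chain MC error", {
  herd <- smallHerd()
  hyS <- bayesHyperparams(chainLength = 2000, burnIn = 500, thin = 2, seed = 9)
  hyL <- bayesHyperparams(chainLength = 4000, burnIn = 500, thin = 2, seed = 9)
  pS <- fitBayes(herd$y, herd$panel, "C", hyper = hyS)
  pL <- fitBayes(herd$y, herd$panel, "C", hyper = hyL)
  half <- pS@chain$halfFitted
  mcse <- sqrt(mean((half["first", ] - half["second", ])^2)) / 2
  drift <- sqrt(mean((unname(pS@fitted) - unname(pL@fitted))^2))
  expect_lt(drift, 2 * mcse)
})
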