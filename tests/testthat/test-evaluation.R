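test_that("makeFolds partitions animals into balanced, reproducible folds", {
  ids <- sprintf("an_%03d", 1:354)
  f <- makeFolds(ids, k = 5, repeats = 2, seed = 1)
  sizes <- sort(as.vector(table(f$fold[f$rep == 1])))
  expect_equal(sizes, c(70, 71, 71, 71, 71))
  expect_identical(f, makeFolds(ids, k = 5, repeats = 2, seed = 1))
  expect_error(makeFolds(ids[1:3], k = 5), "exceed")
  expect_error(makeFolds(ids, k = 1), "at least 2")
})

test_that("every repeat's validation folds cover all animals exactly once", {
  ids <- paste0("x", 1:50)
  for (s in 1:100) {
    f <- makeFolds(ids, k = 5, repeats = 1, seed = s)
    expect_setequal(f$animal, ids)
    expect_equal(anyDuplicated(f$animal), 0)
  }
})

test_that("predictive ability is plain Pearson correlation", {
  y <- c(3.2, 1.1, 4.8, 2.5, 0.4)
  expect_equal(predictiveAbility(y, y), 1)
  expect_equal(predictiveAbility(-y, y), -1)
  expect_equal(predictiveAbility(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  expect_error(predictiveAbility(c(1, 2), c(3, 4)), "3 paired")
  expect_error(predictiveAbility(rep(1, 5), y), "zero variance")
})

test_that("accuracy scales ability by the square root of heritability", {
  expect_equal(round(predictiveAccuracy(0.164, 0.35), 3), 0.277)
  expect_equal(round(predictiveAccuracy(0.295, 0.57), 3), 0.391)
  expect_equal(predictiveAccuracy(0, 0.4), 0)
  expect_error(predictiveAccuracy(0.2, 0), "h2")
})

test_that("runCV shares folds across methods and satisfies the aggregation identity", {
  herd <- smallHerd()
  hy <- bayesHyperparams(chainLength = 500, burnIn = 100, thin = 2, seed = 2)
  cv <- runCV(herd$y, herd$panel, methods = c("GBLUP", "BayesC"),
              k = 4, repeats = 1, seed = 31, grm = herd$grm,
              varcomps = herd$vc, hyper = hy)
  cells <- cvCells(cv)
  expect_equal(nrow(cells), 8)  # 4 folds x 2 methods
  # identical partitions across methods: same validation sizes per fold
  byFold <- split(cells$nValidation, cells$fold)
  expect_true(all(vapply(byFold, function(v) length(unique(v)) == 1,
                         logical(1))))
  sm <- cvSummary(cv)
  expect_equal(sm$meanAccuracy, sm$meanAbility / sqrt(h2(herd$vc)),
               tolerance = 1e-12)
})

test_that("a heritable trait yields positive CV ability; a null trait does not", {
  herd <- smallHerd()
  cv <- runCV(herd$y, herd$panel, "GBLUP", k = 5, repeats = 2, seed = 17,
              grm = herd$grm, varcomps = herd$vc)
  expect_gt(mean(cvCells(cv)$ability), 0.1)
  set.seed(18)
  yNull <- setNames(rnorm(length(herd$y), 80, 10), names(herd$y))
  cvN <- runCV(yNull, herd$panel, "GBLUP", k = 5, repeats = 2, seed = 17,
               grm = herd$grm, varcomps = varComps(1, 99))
  expect_lt(abs(mean(cvCells(cvN)$ability)), 0.15)
})

test_that("animals missing the trait are dropped from the partition", {
  herd <- smallHerd()
  y <- herd$y
  y[1:10] <- NA
  expect_message(
    cv <- runCV(y, herd$panel, "GBLUP", k = 5, repeats = 1, seed = 3,
                grm = NULL, varcomps = herd$vc),
    "dropping 10")
  expect_equal(length(unique(cv@folds$animal)), length(y) - 10)
})

test_that("ability-on-heritability regression matches lm and guards its inputs", {
  ab <- c(0.05, 0.12, 0.2, 0.3)
  hh <- c(0.1, 0.2, 0.4, 0.6)
  sl <- abilityH2Regression(ab, hh)
  expect_equal(unname(sl["slope"]), unname(coef(lm(ab ~ hh))[2]))
  expect_equal(unname(abilityH2Regression(rep(0.2, 4), hh)["slope"]), 0)
  expect_error(abilityH2Regression(ab[1:2], hh[1:2]), "3 traits")
  expect_error(abilityH2Regression(ab, rep(0.3, 4)), "zero variance")
})

test_that("later-age correlation handles identity, orthogonal and missing cases", {
  x <- c(1.2, -0.5, 2.2, 0.1, -1.9)
  r <- laterAgeCorrelation(x, x)
  expect_equal(r$r, 1)
  expect_lt(r$p.value, 1e-4)
  r0 <- laterAgeCorrelation(c(1, -1, 1, -1), c(1, 1, -1, -1))
  expect_equal(r0$r, 0)
  withNA <- laterAgeCorrelation(c(x, 5), c(x, NA))
  expect_equal(withNA$r, 1)
  expect_error(laterAgeCorrelation(c(1, 2), c(1, 2)), "3 complete")
})

test_that("whole-herd early GEBVs track later-age phenotypes in the calibrated regime", {
  rs <- vapply(1:10, function(s) {
    cfg <- simConfig(nAnimals = 354, nSnps = 2000, seed = 400 + s)
    panel <- simulateGenotypes(cfg)
    tr <- simulatedTrait(panel, cfg)
    grm <- blendGRM(vanRadenGRM(panel), 0.05)
    vc <- remlFit(tr$y, grm)
    gb <- fitGBLUP(tr$y, grm, vc)
    laterAgeCorrelation(gb$gebv, unname(tr$yLater[gb$id]))$r
  }, numeric(1))
  expect_true(all(rs > 0.25 & rs < 0.55))
})
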