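test_that("snpMaf counts non-missing calls and folds at 0.5", {
  expect_equal(snpMaf(rep(1, 20)), 0.5)                      # all heterozygous
  expect_equal(snpMaf(c(rep(0, 99), 1)), 0.005)              # 1 copy in 200
  expect_equal(snpMaf(c(rep(0, 30), rep(1, 40), rep(2, 30))), 0.5)
  expect_equal(snpMaf(c(2, 2, NA, NA)), 0)                   # missing excluded
  expect_error(snpMaf(c(NA, NA)), "all-missing")
})

test_that("hweTest matches hand-computed and boundary cases", {
  r <- hweTest(25, 50, 25)
  expect_equal(r$statistic, 0)
  expect_equal(r$p.value, 1)
  r <- hweTest(10, 10, 10)   # expected counts 7.5 / 15 / 7.5
  expect_equal(r$statistic, 10 / 3, tolerance = 1e-12)
  expect_equal(r$p.value, pchisq(10 / 3, 1, lower.tail = FALSE))
  expect_lt(hweTest(50, 0, 50)$p.value, 1e-6)
  expect_equal(hweTest(40, 0, 0)$p.value, 1)  # monomorphic convention
})

test_that("hweTest agrees with the closed-form chi-square on all small count triples", {
  for (n in 1:30) {
    for (nAA in 0:n) for (nAa in 0:(n - nAA)) {
      naa <- n - nAA - nAa
      got <- hweTest(nAA, nAa, naa)$statistic
      expect_equal(got, hweChisqOracle(nAA, nAa, naa), tolerance = 1e-9)
    }
  }
})

test_that("exact HWE test orders tail probabilities sensibly", {
  # exact HWE proportions are the most probable configuration
  expect_equal(hweTest(25, 50, 25, method = "exact")$p.value, 1,
               tolerance = 1e-9)
  # complete heterozygote absence at p = 0.5 is extreme under both tests
  expect_lt(hweTest(50, 0, 50, method = "exact")$p.value, 1e-6)
})

test_that("clean panels pass QC untouched and filtering is idempotent", {
  panel <- tinyPanel(n = 150, m = 200, seed = 31)
  res <- filterVariants(panel)
  expect_equal(res$report$removedCallRate, 0)
  expect_equal(res$report$removedHwe, 0)
  expect_equal(res$report$removedMaf, 0)
  expect_equal(res$report$removedSamples, 0)
  expect_identical(genoMatrix(res$panel), genoMatrix(panel))
})

test_that("QC removal counts equal the injection manifest and bookkeeping balances", {
  panel <- tinyPanel(n = 150, m = 300, seed = 33)
  cor1 <- corruptForQC(panel, nMissing = 10, missingRate = 0.15,
                       nLowMaf = 50, nHweViolating = 5, seed = 4)
  res <- filterVariants(cor1$panel)
  rep1 <- res$report
  expect_equal(rep1$removedCallRate, 10)
  expect_equal(rep1$removedHwe, 5)
  expect_equal(rep1$removedMaf, 50)
  expect_equal(rep1$removedSamples, 0)
  # conservation per axis
  expect_equal(rep1$markersRetained + rep1$removedCallRate +
                 rep1$removedHwe + rep1$removedMaf, rep1$markersIn)
  expect_equal(rep1$samplesRetained + rep1$removedSamples, rep1$samplesIn)
  # idempotence
  res2 <- filterVariants(res$panel)
  expect_equal(res2$report$removedCallRate + res2$report$removedHwe +
                 res2$report$removedMaf + res2$report$removedSamples, 0)
})

test_that("minMaf = 0 removes nothing under the strict-inequality convention", {
  panel <- tinyPanel(n = 80, m = 60, seed = 35)
  g <- genoMatrix(panel)
  g[, 1] <- 0  # monomorphic, MAF 0
  mono <- GenotypePanel(g, markerMap(panel))
  res <- filterVariants(mono, qcThresholds(minMaf = 0))
  expect_equal(res$report$removedMaf, 0)  # 0 < 0 is false
  res2 <- filterVariants(mono)            # default minMaf = 0.01 fires
  expect_equal(res2$report$removedMaf, 1)
})

test_that("all-removed panels raise an explicit error", {
  g <- matrix(0L, 20, 5, dimnames = list(paste0("a", 1:20), NULL))
  panel <- GenotypePanel(g)
  expect_error(filterVariants(panel), "all markers removed")
})

test_that("snpDensity uses half-open 1 Mb windows and conserves counts", {
  map <- data.frame(chrom = c(1, 1, 1, 2), pos = c(1, 999999, 1000000, 5))
  d <- snpDensity(map)
  expect_equal(d$count[d$chrom == 1 & d$window == 0], 2)
  expect_equal(d$count[d$chrom == 1 & d$window == 1], 1)
  expect_equal(sum(d$count), nrow(map))
  # hand tally on a toy 10-marker map over 3 chromosomes
  map2 <- data.frame(chrom = rep(1:3, c(5, 3, 2)),
                     pos = c(1e5, 5e5, 1.2e6, 2.1e6, 2.9e6,
                             3e5, 1.7e6, 1.8e6,
                             9e5, 9.5e5))
  d2 <- snpDensity(map2)
  expect_equal(d2$count[d2$chrom == 1], c(2, 1, 2))
  expect_equal(d2$count[d2$chrom == 2], c(1, 2))
  expect_equal(d2$count[d2$chrom == 3], 2)
  expect_error(snpDensity(data.frame(chrom = 1, pos = c(5, 2))), "sorted")
})
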