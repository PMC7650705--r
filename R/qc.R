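#' @include AllClasses.R
NULL

#' Quality-control thresholds
#'
#' Defaults follow the chip-QC protocol used for the yak panel: SNPs with
#' call rate <= 0.90, Hardy-Weinberg p-value < 1e-6 or minor allele
#' frequency < 0.01 are removed; animals are retained when their genotype
#' call rate is > 0.90. Inequalities are applied exactly as stated
#' (non-strict for call rate, strict for HWE and MAF).
#'
#' @param minCallRateSnp SNP call-rate threshold (removed when `<=`).
#' @param minCallRateSample sample call-rate threshold (retained when `>`).
#' @param hweAlpha Hardy-Weinberg p-value threshold (removed when `<`).
#' @param minMaf minor-allele-frequency threshold (removed when `<`).
#' @return a list of class `QCThresholds`.
#' @export
qcThresholds <- function(minCallRateSnp = 0.90, minCallRateSample = 0.90,
                         hweAlpha = 1e-6, minMaf = 0.01) {
  vals <- c(minCallRateSnp, minCallRateSample, hweAlpha)
  if (any(vals <= 0 | vals > 1) || minMaf < 0 || minMaf > 1)
    stop("qcThresholds: thresholds must lie in (0, 1] (minMaf in [0, 1])",
         call. = FALSE)
  structure(list(minCallRateSnp = minCallRateSnp,
                 minCallRateSample = minCallRateSample,
                 hweAlpha = hweAlpha, minMaf = minMaf),
            class = "QCThresholds")
}

#' Minor allele frequency of one marker
#'
#' Computed over non-missing calls as `min(p, 1 - p)` where `p` is the
#' frequency of the counted allele.
#'
#' @param x vector of \{0,1,2,NA\} codes for one marker.
#' @return MAF in `[0, 0.5]`.
#' @examples
#' snpMaf(c(rep(0, 99), 1))  # one heterozygote in 100 animals -> 0.005
#' @export
snpMaf <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x))
    stop("snpMaf: MAF undefined for an all-missing marker", call. = FALSE)
  p <- sum(x) / (2 * length(x))
  min(p, 1 - p)
}

#' Hardy-Weinberg equilibrium test for one marker
#'
#' One-degree-of-freedom Pearson chi-square goodness of fit of the observed
#' genotype counts against Hardy-Weinberg expectations at the sample allele
#' frequency (the conventional chip-QC test); an exact test (full
#' enumeration of heterozygote counts at the observed allele counts) is
#' available behind `method = "exact"`. Monomorphic markers return p = 1 by
#' convention.
#'
#' @param nAA,nAa,naa genotype counts (codes 0, 1, 2).
#' @param method `"chisq"` (default) or `"exact"`.
#' @return list with `statistic` (chi-square; `NA` for the exact test) and
#'   `p.value`.
#' @examples
#' hweTest(25, 50, 25)  # exact HWE proportions: statistic 0, p = 1
#' @export
hweTest <- function(nAA, nAa, naa, method = c("chisq", "exact")) {
  method <- match.arg(method)
  n <- nAA + nAa + naa
  if (n < 1) stop("hweTest: needs at least one genotyped animal", call. = FALSE)
  p <- (2 * nAA + nAa) / (2 * n)
  if (p == 0 || p == 1)
    return(list(statistic = 0, p.value = 1))
  if (method == "chisq") {
    q <- 1 - p
    expd <- n * c(p^2, 2 * p * q, q^2)
    stat <- sum((c(nAA, nAa, naa) - expd)^2 / expd)
    list(statistic = stat, p.value = pchisq(stat, df = 1, lower.tail = FALSE))
  } else {
    # exact test: sum of conditional probabilities of heterozygote counts
    # no more probable than the observed one, given the allele counts
    nA <- 2 * nAA + nAa
    na <- 2 * n - nA
    hets <- seq(nA %% 2, min(nA, na), by = 2)
    # P(nAa = h | nA, n) proportional to 2^h / (nAA! nAa! naa!);
    # constants cancel in the normalisation below
    logp <- vapply(hets, function(h) {
      a <- (nA - h) / 2; b <- (na - h) / 2
      h * log(2) - lgamma(a + 1) - lgamma(h + 1) - lgamma(b + 1)
    }, numeric(1))
    logp <- logp - max(logp)
    pr <- exp(logp) / sum(exp(logp))
    pObs <- pr[match(nAa, hets)]
    list(statistic = NA_real_, p.value = min(1, sum(pr[pr <= pObs + 1e-12])))
  }
}

#' Apply the variant- and sample-level quality-control filters
#'
#' Filters are applied in a fixed, logged order: (1) SNP call rate
#' (`<= minCallRateSnp` removed), (2) Hardy-Weinberg (`p < hweAlpha`
#' removed), (3) MAF (`< minMaf` removed), then (4) sample call rate
#' (retained when `> minCallRateSample`, computed on the retained markers).
#' MAF and HWE use non-missing calls only; missing genotypes are not
#' imputed at this stage.
#'
#' @param panel a [GenotypePanel-class].
#' @param thresholds a [qcThresholds()] object.
#' @param hweMethod passed to [hweTest()].
#' @return list with `panel` (filtered) and `report` (list of class
#'   `QCReport`: removal counts per filter in application order, retained
#'   counts, and the removed marker/sample ids).
#' @export
filterVariants <- function(panel, thresholds = qcThresholds(),
                           hweMethod = "chisq") {
  stopifnot(is(panel, "GenotypePanel"))
  g <- genoMatrix(panel)
  if (!nrow(g) || !ncol(g))
    stop("filterVariants: empty genotype panel", call. = FALSE)
  mIn <- ncol(g); nIn <- nrow(g)

  callRate <- colMeans(!is.na(g))
  failCall <- callRate <= thresholds$minCallRateSnp

  keep <- !failCall
  hweP <- rep(1, mIn)
  for (j in which(keep)) {
    x <- g[, j]; x <- x[!is.na(x)]
    hweP[j] <- hweTest(sum(x == 0), sum(x == 1), sum(x == 2),
                       method = hweMethod)$p.value
  }
  failHwe <- keep & (hweP < thresholds$hweAlpha)
  keep <- keep & !failHwe

  maf <- rep(NA_real_, mIn)
  maf[keep] <- apply(g[, keep, drop = FALSE], 2, snpMaf)
  failMaf <- keep & (maf < thresholds$minMaf)
  keep <- keep & !failMaf

  if (!any(keep))
    stop("filterVariants: all markers removed by QC; panel is empty",
         call. = FALSE)

  g2 <- g[, keep, drop = FALSE]
  sampleCall <- rowMeans(!is.na(g2))
  keepSample <- sampleCall > thresholds$minCallRateSample
  if (!any(keepSample))
    stop("filterVariants: all samples removed by QC", call. = FALSE)

  out <- new("GenotypePanel", geno = g2[keepSample, , drop = FALSE],
             map = markerMap(panel)[keep, , drop = FALSE])
  report <- structure(list(
    filterOrder = c("snp_call_rate", "hwe", "maf", "sample_call_rate"),
    markersIn = mIn,
    removedCallRate = sum(failCall),
    removedHwe = sum(failHwe),
    removedMaf = sum(failMaf),
    markersRetained = sum(keep),
    samplesIn = nIn,
    removedSamples = sum(!keepSample),
    samplesRetained = sum(keepSample),
    removedMarkerIds = markerMap(panel)$id[failCall | failHwe | failMaf],
    removedSampleIds = rownames(g2)[!keepSample],
    thresholds = thresholds), class = "QCReport")
  list(panel = out, report = report)
}

#' @export
print.QCReport <- function(x, ...) {
  cat("QC report (filters applied in order:",
      paste(x$filterOrder, collapse = " -> "), ")\n")
  cat(sprintf("  markers: %d in, removed %d (call rate) + %d (HWE) + %d (MAF), %d retained\n",
              x$markersIn, x$removedCallRate, x$removedHwe, x$removedMaf,
              x$markersRetained))
  cat(sprintf("  samples: %d in, removed %d, %d retained\n",
              x$samplesIn, x$removedSamples, x$samplesRetained))
  invisible(x)
}

#' Per-chromosome SNP density in fixed windows
#'
#' Counts markers per half-open window `[k*w, (k+1)*w)` on each chromosome
#' (the 1-Mb-window marker-density summary).
#'
#' @param map marker map (`chrom`, `pos`), positions sorted within
#'   chromosome.
#' @param windowBp window width in bp (default 1e6).
#' @return `data.frame` with `chrom`, `window` (0-based index), `startBp`,
#'   `count`; counts sum to the number of markers.
#' @export
snpDensity <- function(map, windowBp = 1e6) {
  stopifnot(is.data.frame(map), all(c("chrom", "pos") %in% names(map)))
  bad <- vapply(split(map$pos, map$chrom), function(p) any(diff(p) < 0),
                logical(1))
  if (any(bad))
    stop("snpDensity: positions must be sorted within chromosome",
         call. = FALSE)
  out <- do.call(rbind, lapply(split(map, map$chrom), function(d) {
    w <- floor(d$pos / windowBp)
    tab <- table(w)
    data.frame(chrom = d$chrom[1], window = as.integer(names(tab)),
               startBp = as.integer(names(tab)) * windowBp,
               count = as.integer(tab), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
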