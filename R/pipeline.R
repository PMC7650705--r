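#' @include AllClasses.R
NULL

#' Configuration for the end-to-end pipeline
#'
#' Chains the stages simulate (optional) -> QC -> GRM -> REML -> repeated
#' k-fold cross-validation -> report tables. Each named trait is simulated
#' on the same genotype panel with its own heritability target (seed
#' offset per trait), mimicking a multi-trait recording scheme over one
#' herd.
#'
#' @param outDir output directory (created if needed).
#' @param sim a [simConfig()] describing the herd (used when no genotype
#'   files are given).
#' @param pedPath,mapPath,phenoPath optional input files; when set, the
#'   panel and phenotypes are read instead of simulated and `traits` is
#'   ignored.
#' @param traits named numeric vector of per-trait heritability targets
#'   for simulated herds.
#' @param thresholds [qcThresholds()].
#' @param blend GRM identity blending weight.
#' @param methods prediction methods for the CV stage.
#' @param k,repeats,seed CV controls.
#' @param hyper [bayesHyperparams()] for Bayesian methods.
#' @return list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(outDir, sim = simConfig(),
                           pedPath = NULL, mapPath = NULL, phenoPath = NULL,
                           traits = c(BW6 = 0.35, WH6 = 0.57, BW12 = 0.24,
                                      BL12 = 0.07),
                           thresholds = qcThresholds(), blend = 0.05,
                           methods = "GBLUP", k = 5L, repeats = 10L,
                           seed = 1L, hyper = bayesHyperparams()) {
  structure(list(outDir = outDir, sim = sim, pedPath = pedPath,
                 mapPath = mapPath, phenoPath = phenoPath, traits = traits,
                 thresholds = thresholds, blend = blend, methods = methods,
                 k = as.integer(k), repeats = as.integer(repeats),
                 seed = as.integer(seed), hyper = hyper),
            class = "PipelineConfig")
}

stageTry <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full genomic-prediction pipeline
#'
#' Executes simulate (or read) -> [filterVariants()] -> [vanRadenGRM()] +
#' [blendGRM()] -> [remlFit()] -> [runCV()] per trait, then writes: the QC
#' report, the GRM, a variance-component table (trait, sigma_a2, sigma_e2,
#' h2, se), an ability/accuracy table (trait x method), the OLS regression
#' of mean ability on heritability, a later-age correlation table (for
#' simulated herds, early-trait GEBVs against the later-stage phenotype),
#' and a manifest of every artifact with the seeds and parameters used.
#' Reruns with identical configuration are byte-identical.
#'
#' @param config a [pipelineConfig()].
#' @return the manifest `data.frame`, invisibly.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outDir, f)
  artifacts <- list()
  note <- function(name, path, detail = "")
    artifacts[[length(artifacts) + 1L]] <<-
      data.frame(artifact = name, path = path, detail = detail,
                 stringsAsFactors = FALSE)

  fromFiles <- !is.null(config$pedPath)
  if (fromFiles) {
    panel <- stageTry("read", readPlinkText(config$pedPath, config$mapPath))
    phenoAll <- stageTry("read", readPhenotypes(config$phenoPath))
    traitDefs <- unique(phenoAll[phenoAll$stage == "early", "trait"])
  } else {
    panel <- stageTry("simulate", simulateGenotypes(config$sim))
    traitDefs <- names(config$traits)
    phenoAll <- NULL
    truthList <- list()
    for (i in seq_along(config$traits)) {
      cfgT <- config$sim
      cfgT$h2Target <- unname(config$traits[i])
      cfgT$seed <- config$sim$seed + 1000L * i
      simP <- stageTry("simulate", simulatePhenotypes(panel, cfgT))
      ph <- simP$phenotypes
      ph$trait <- names(config$traits)[i]
      phenoAll <- rbind(phenoAll, ph)
      truthList[[names(config$traits)[i]]] <- simP$truth
    }
    writePlinkText(panel, out("panel"))
    note("genotypes", out("panel.ped"), sprintf("seed=%d", config$sim$seed))
    writePhenotypes(phenoAll, out("phenotypes.csv"))
    note("phenotypes", out("phenotypes.csv"))
  }

  qcRes <- stageTry("qc", filterVariants(panel, config$thresholds))
  rep0 <- qcRes$report
  qcDf <- data.frame(filter = c("snp_call_rate", "hwe", "maf",
                                "sample_call_rate"),
                     removed = c(rep0$removedCallRate, rep0$removedHwe,
                                 rep0$removedMaf, rep0$removedSamples))
  write.csv(qcDf, out("qc_report.csv"), row.names = FALSE)
  note("qc_report", out("qc_report.csv"),
       sprintf("markers %d -> %d", rep0$markersIn, rep0$markersRetained))
  panel <- qcRes$panel

  grm <- stageTry("grm", blendGRM(vanRadenGRM(panel), config$blend))
  writeGRM(grm, out("grm.csv"))
  note("grm", out("grm.csv"), sprintf("blend=%g", config$blend))

  vcRows <- list(); cvRows <- list(); laterRows <- list(); cellRows <- list()
  for (tr in traitDefs) {
    ph <- phenoAll[phenoAll$trait == tr & phenoAll$stage == "early", ]
    yv <- setNames(ph$value, ph$animal_id)
    yv <- yv[intersect(names(yv), animalIds(panel))]
    vc <- stageTry("reml", remlFit(yv, grm))
    vcRows[[tr]] <- data.frame(trait = tr, sigma_a2 = sigmaA2(vc),
                               sigma_e2 = sigmaE2(vc), h2 = h2(vc),
                               se_h2 = seH2(vc), stringsAsFactors = FALSE)
    cv <- stageTry("cv", runCV(yv, panel, methods = config$methods,
                               k = config$k, repeats = config$repeats,
                               seed = config$seed, grm = grm, varcomps = vc,
                               hyper = config$hyper))
    sm <- cvSummary(cv)
    sm <- data.frame(trait = tr, sm, stringsAsFactors = FALSE)
    cvRows[[tr]] <- sm
    cellRows[[tr]] <- data.frame(trait = tr, cvCells(cv),
                                 stringsAsFactors = FALSE)

    phL <- phenoAll[phenoAll$trait == tr & phenoAll$stage == "later", ]
    if (nrow(phL)) {
      gb <- fitGBLUP(yv, grm, vc)
      yl <- setNames(phL$value, phL$animal_id)[gb$id]
      lc <- laterAgeCorrelation(gb$gebv, unname(yl))
      laterRows[[tr]] <- data.frame(trait = tr, method = "GBLUP",
                                    r = lc$r, p.value = lc$p.value,
                                    stringsAsFactors = FALSE)
    }
  }
  vcTab <- do.call(rbind, vcRows)
  cvTab <- do.call(rbind, cvRows)
  write.csv(vcTab, out("variance_components.csv"), row.names = FALSE)
  note("variance_components", out("variance_components.csv"))
  write.csv(cvTab, out("cv_results.csv"), row.names = FALSE)
  note("cv_results", out("cv_results.csv"),
       sprintf("k=%d repeats=%d seed=%d", config$k, config$repeats,
               config$seed))
  write.csv(do.call(rbind, cellRows), out("cv_cells.csv"), row.names = FALSE)
  note("cv_cells", out("cv_cells.csv"), "one row per repeat x fold x method")

  if (nrow(vcTab) >= 3) {
    regRows <- do.call(rbind, lapply(unique(cvTab$method), function(meth) {
      d <- cvTab[cvTab$method == meth, ]
      hh <- vcTab$h2[match(d$trait, vcTab$trait)]
      cf <- abilityH2Regression(d$meanAbility, hh)
      data.frame(method = meth, intercept = cf["intercept"],
                 slope = cf["slope"], stringsAsFactors = FALSE)
    }))
    write.csv(regRows, out("ability_h2_regression.csv"), row.names = FALSE)
    note("ability_h2_regression", out("ability_h2_regression.csv"))
  }
  if (length(laterRows)) {
    write.csv(do.call(rbind, laterRows), out("later_age_correlation.csv"),
              row.names = FALSE)
    note("later_age_correlation", out("later_age_correlation.csv"))
  }

  note("manifest", out("manifest.csv"))
  manifest <- do.call(rbind, artifacts)
  write.csv(manifest, out("manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
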