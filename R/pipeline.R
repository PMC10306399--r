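.runConfigDefaults <- list(
  # input / output paths
  counts = NULL, design = NULL, ldh = NULL, qcMetrics = NULL,
  mixtures = NULL, pathways = NULL, outDir = "tpodmix_out",
  # QC stage
  ldhThreshold = 10, minReads = 1e5, minFraction = 0.40, fenceK = 3,
  clusterCut = 0.1, minReplicates = 2,
  # normalize stage
  pseudocount = 1, baseVehicle = 0.1,
  # trend prefilter
  nPerm = 500, pMax = 0.01, fc = 1.5,
  # BMC stage
  B = 100, bmrFactor = 1, ciLevel = 0.95, maxRatio = 40, minFitP = 0.1,
  # tPOD stage
  nSim = 10000, geneRank = 25, minPathwayGenes = 3, minPathwayFraction = 0.05,
  maxRank = 100,
  # reproducibility
  seed = 1L)

#' Pipeline run configuration
#'
#' All stage parameters default to the analysis' standard values (LDH
#' threshold 10-fold; 100,000-read and 0.40-alignment minimums; Tukey
#' fence at 3 x IQR; clustering cut 0.1; 500 trend permutations at
#' p <= .01 and 1.5-fold change; 100 bootstraps; benchmark response 1 SD;
#' 95% CI; BMCU/BMCL < 40; fit p > .1; 10,000 simulated experiments;
#' pathway gates of 3 genes / 5%; 100-gene accumulation). Unknown keys are
#' rejected before any stage runs; overrides are echoed to the run log.
#'
#' @param ... overrides of the defaults (see
#'   `tpodmix:::.runConfigDefaults`), including the input paths `counts`,
#'   `design`, `ldh`, `qcMetrics`, and optional `mixtures`, `pathways`.
#' @return list of class `"RunConfig"`.
#' @export
runConfig <- function(...) {
  over <- list(...)
  unknown <- setdiff(names(over), names(.runConfigDefaults))
  if (length(unknown))
    stopf("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(.runConfigDefaults, over, keep.null = TRUE)
  structure(cfg, overrides = names(over), class = "RunConfig")
}

.digests <- function(paths) {
  paths <- paths[!vapply(paths, is.null, TRUE)]
  as.list(tools::md5sum(unlist(paths)))
}

.logmsg <- function(log, fmt, ...) {
  line <- sprintf(paste0("[%s] ", fmt), format(Sys.time(), "%H:%M:%S"), ...)
  message(line)
  c(log, line)
}

## exposure groups retained for BMC analysis of one chemical/timepoint:
## base-vehicle controls plus exposures passing QC and replicate gates
.analysisColumns <- function(norm, design, exposures, chemical, tp) {
  ok <- exposures$retained & exposures$chemical == chemical &
    exposures$timepoint == tp
  concs <- exposures$concentration_uM[ok]
  keep <- design$sample[design$timepoint == tp &
                          ((design$chemical == "DMSO" &
                              design$concentration_uM == 0) |
                             (design$chemical == chemical &
                                design$concentration_uM %in% concs))]
  keep <- intersect(colnames(norm), keep)
  list(samples = keep,
       conc = design$concentration_uM[match(keep, design$sample)],
       topConc = if (length(concs)) max(concs) else NA_real_)
}

#' Run the full tPOD pipeline
#'
#' Executes qc -> normalize -> prefilter -> bmc -> tpod -> predict on the
#' input files named in the configuration, writing each stage's outputs
#' and a JSON run manifest (input digests, seeds, per-stage survivor
#' counts, output digests) to the output directory. A rerun with
#' unchanged inputs and seeds resumes after the expensive BMC stage by
#' reloading its table when its recorded input digests still match.
#'
#' @param config a [runConfig()].
#' @return invisibly, the manifest (also written to
#'   `<outDir>/manifest.json`).
#' @export
runPipeline <- function(config) {
  stopifnot(is(config, "RunConfig"))
  for (p in c("counts", "design", "ldh", "qcMetrics"))
    if (is.null(config[[p]]) || !file.exists(config[[p]]))
      stopf("input '%s' is missing or unreadable", p)
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  log <- character()
  for (key in setdiff(attr(config, "overrides"),
                      c("counts", "design", "ldh", "qcMetrics", "mixtures",
                        "pathways", "outDir")))
    log <- .logmsg(log, "config override: %s = %s", key,
                   paste(format(config[[key]]), collapse = ","))
  inputs <- .digests(config[c("counts", "design", "ldh", "qcMetrics",
                              "mixtures", "pathways")])
  manifest <- list(inputs = inputs, seed = config$seed, stages = list())
  out <- function(name) file.path(config$outDir, name)

  ## ---- load -----------------------------------------------------------
  counts <- readCounts(config$counts)
  design <- readDesign(config$design)
  ldh <- readLdh(config$ldh)
  metrics <- readQcMetrics(config$qcMetrics)
  study <- podExperiment(counts, design, ldh, metrics)
  pathways <- if (!is.null(config$pathways)) readGmt(config$pathways)
  mixtures <- if (!is.null(config$mixtures)) readMixtures(config$mixtures)
  chems <- setdiff(unique(design$chemical), "DMSO")
  tps <- unique(design$timepoint)

  ## ---- qc -------------------------------------------------------------
  report <- runQc(study, ldhThreshold = config$ldhThreshold,
                  minReads = config$minReads,
                  minFraction = config$minFraction, fenceK = config$fenceK,
                  clusterCut = config$clusterCut,
                  minN = config$minReplicates)
  writeExclusionReport(report, out("exclusions.csv"))
  utils::write.csv(exposureStatus(report), out("exposures.csv"),
                   row.names = FALSE, quote = FALSE)
  nRet <- length(retainedSamples(report))
  log <- .logmsg(log, "qc: %d of %d samples retained", nRet, nrow(design))
  manifest$stages$qc <- list(samples_retained = nRet,
                             exposures_dropped =
                               sum(!exposureStatus(report)$retained))

  ## ---- normalize ------------------------------------------------------
  normed <- normalizeStudy(study, report, pseudocount = config$pseudocount,
                           baseVehicle = config$baseVehicle)
  writeNormalized(normed$matrix, out("normalized.tsv"))
  log <- .logmsg(log, "normalize: %d probes x %d samples",
                 nrow(normed$matrix), ncol(normed$matrix))
  manifest$stages$normalize <- list(samples = ncol(normed$matrix))

  ## ---- prefilter + bmc (resumable) -----------------------------------
  exposures <- exposureStatus(report)
  bmcPath <- out("bmc_table.tsv")
  trendPath <- out("trend.tsv")
  prevManifest <- if (file.exists(out("manifest.json")))
    tryCatch(jsonlite::read_json(out("manifest.json"),
                                 simplifyVector = TRUE),
             error = function(e) NULL)
  canResume <- !is.null(prevManifest) &&
    identical(prevManifest$inputs, inputs) &&
    identical(as.integer(prevManifest$seed), as.integer(config$seed)) &&
    file.exists(bmcPath) && file.exists(trendPath) &&
    isTRUE(prevManifest$stages$bmc$complete)
  if (canResume) {
    log <- .logmsg(log, "bmc: resuming from %s (inputs unchanged)", bmcPath)
    trend <- read.delim(trendPath, stringsAsFactors = FALSE)
    allFits <- read.delim(bmcPath, stringsAsFactors = FALSE)
    allFits$reason[is.na(allFits$reason)] <- ""
  } else {
    if (1 / (config$nPerm + 1) > config$pMax)
      log <- .logmsg(log,
                     "warning: permutation floor 1/%d exceeds pMax=%g; no gene can pass",
                     config$nPerm + 1, config$pMax)
    trendRows <- list()
    fitRows <- list()
    for (tp in tps) for (ch in chems) {
      cols <- .analysisColumns(normed$matrix, normed$design, exposures,
                               ch, tp)
      if (!is.finite(cols$topConc) ||
          length(unique(cols$conc)) < 3) {
        log <- .logmsg(log, "prefilter: %s/%s skipped (too few exposures)",
                       ch, tp)
        next
      }
      sub <- normed$matrix[, cols$samples, drop = FALSE]
      pre <- prefilterGenes(sub, cols$conc, pMax = config$pMax,
                            fc = config$fc, nPerm = config$nPerm,
                            seed = subSeed(config$seed, "prefilter", ch, tp))
      pre <- cbind(chemical = ch, timepoint = tp, pre)
      trendRows[[paste(ch, tp)]] <- pre
      passing <- pre$gene[pre$pass]
      log <- .logmsg(log, "prefilter: %s/%s %d of %d genes pass", ch, tp,
                     length(passing), nrow(pre))
      if (!length(passing)) next
      cfg <- fitConfig(B = config$B, bmrFactor = config$bmrFactor,
                       ciLevel = config$ciLevel, maxRatio = config$maxRatio,
                       minFitP = config$minFitP)
      dist <- bmcDistribution(sub, cols$conc, genes = passing,
                              config = cfg,
                              seed = subSeed(config$seed, "bmc", ch, tp),
                              chemical = ch, timepoint = tp)
      ft <- fitTable(dist)
      ft <- cbind(chemical = ch, timepoint = tp, topConc = cols$topConc, ft)
      fitRows[[paste(ch, tp)]] <- ft
      log <- .logmsg(log, "bmc: %s/%s %d surviving BMCs", ch, tp,
                     sum(ft$reason == ""))
    }
    trend <- if (length(trendRows))
      do.call(rbind, c(trendRows, list(make.row.names = FALSE)))
    allFits <- if (length(fitRows))
      do.call(rbind, c(fitRows, list(make.row.names = FALSE)))
    if (is.null(trend))
      stopf("prefilter stage failed: no chemical/timepoint had enough exposures")
    write.table(trend, trendPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
    if (is.null(allFits))
      allFits <- data.frame(chemical = character(), timepoint = character(),
                            topConc = numeric(), gene = character(),
                            draw = integer(), model = character(),
                            bmc = numeric(), bmcl = numeric(),
                            bmcu = numeric(), gofP = numeric(),
                            reason = character())
    write.table(allFits, bmcPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
    ## reload what was written so that fresh and resumed runs feed the
    ## downstream stages byte-identical values
    allFits <- read.delim(bmcPath, stringsAsFactors = FALSE)
    allFits$reason[is.na(allFits$reason)] <- ""
  }
  manifest$stages$prefilter <- list(genes_passing = sum(trend$pass))
  manifest$stages$bmc <- list(complete = TRUE,
                              surviving_bmcs = sum(allFits$reason == ""))

  ## ---- tpod -----------------------------------------------------------
  tpodRows <- list()
  accRows <- list()
  results <- list() # [[tp]][[chem]] -> list(gene25=, pathway=, acc=)
  for (tp in tps) for (ch in chems) {
    sub <- allFits[allFits$chemical == ch & allFits$timepoint == tp, ,
                   drop = FALSE]
    if (!nrow(sub) || !sum(sub$reason == "")) next
    kept <- sub[sub$reason == "", ]
    dist <- new("BmcDistribution", chemical = ch, timepoint = tp,
                B = as.integer(config$B),
                bmcs = lapply(split(kept$bmc, kept$gene), as.numeric),
                fits = sub)
    sims <- simulateTpodExperiments(dist, nSim = config$nSim,
                                    seed = subSeed(config$seed, "tpod",
                                                   ch, tp))
    topC <- sub$topConc[1]
    g25 <- gene25Tpod(sims, topConc = topC, rank = config$geneRank,
                      ciLevel = config$ciLevel)
    res <- list(gene25 = g25)
    if (!is.null(pathways))
      res$pathway <- pathwayLowestMedianTpod(
        sims, pathways, minGenes = config$minPathwayGenes,
        minFraction = config$minPathwayFraction, ciLevel = config$ciLevel)
    res$acc <- accumulationCurve(sims, maxRank = config$maxRank,
                                 ciLevel = config$ciLevel)
    results[[tp]][[ch]] <- res
    for (kind in intersect(c("gene25", "pathway"), names(res))) {
      r <- res[[kind]]
      tpodRows[[paste(ch, tp, kind)]] <- data.frame(
        chemical = ch, timepoint = tp, kind = r@kind, median = r@median,
        ci_lower = r@ciLower, ci_upper = r@ciUpper, n_sim = r@nSim,
        fallback = r@fallback, stringsAsFactors = FALSE)
    }
    accRows[[paste(ch, tp)]] <- cbind(chemical = ch, timepoint = tp,
                                      res$acc)
  }
  if (!length(tpodRows)) stopf("tpod stage failed: no BMC distributions")
  tpodTab <- do.call(rbind, c(tpodRows, list(make.row.names = FALSE)))
  write.table(tpodTab, out("tpod.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  accTab <- do.call(rbind, c(accRows, list(make.row.names = FALSE)))
  write.table(accTab, out("accumulation.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  log <- .logmsg(log, "tpod: %d results", nrow(tpodTab))
  manifest$stages$tpod <- list(results = nrow(tpodTab))

  ## ---- predict --------------------------------------------------------
  if (!is.null(mixtures)) {
    predRows <- list()
    paccRows <- list()
    for (tp in names(results)) for (mx in mixtures) {
      have <- names(results[[tp]])
      if (!all(mx@components %in% have)) next
      comp <- results[[tp]][mx@components]
      draws <- lapply(comp, function(r) tpodDraws(r$gene25))
      pred <- propagatePredictionCi(mx, draws, ciLevel = config$ciLevel)
      censored <- any(vapply(comp, function(r) r$gene25@fallback, TRUE))
      row <- data.frame(mixture = mx@mixtureId, timepoint = tp,
                        kind = "gene25", stringsAsFactors = FALSE)
      if (mx@mixtureId %in% have) {
        emp <- results[[tp]][[mx@mixtureId]]$gene25
        row <- cbind(row, comparePrediction(emp, pred))
      } else {
        row$predicted_median <- pred$median
        row$predicted_ci_lower <- pred$ci_lower
        row$predicted_ci_upper <- pred$ci_upper
      }
      row$censored_component <- censored
      predRows[[paste(mx@mixtureId, tp)]] <- row
      curves <- lapply(comp, `[[`, "acc")
      pac <- predictedAccumulationCurve(mx, curves)
      if (mx@mixtureId %in% have) {
        empAcc <- results[[tp]][[mx@mixtureId]]$acc
        pac$empirical_bmc <- empAcc$median[match(pac$rank, empAcc$rank)]
      }
      paccRows[[paste(mx@mixtureId, tp)]] <-
        cbind(mixture = mx@mixtureId, timepoint = tp, pac)
    }
    if (length(predRows)) {
      predTab <- do.call(rbind, c(predRows, list(make.row.names = FALSE)))
      write.table(predTab, out("predictions.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      paccTab <- do.call(rbind, c(paccRows, list(make.row.names = FALSE)))
      write.table(paccTab, out("predicted_accumulation.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      log <- .logmsg(log, "predict: %d mixture predictions", nrow(predTab))
      manifest$stages$predict <- list(predictions = nrow(predTab))
    }
  }

  ## ---- manifest -------------------------------------------------------
  outFiles <- list.files(config$outDir, pattern = "\\.(tsv|csv)$",
                         full.names = TRUE)
  manifest$outputs <- .digests(as.list(outFiles))
  manifest$log <- log
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
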