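#' LDH fold changes over matched vehicle controls
#'
#' Blank luminescence is averaged and subtracted from every well before
#' ratios are formed; each sample's fold change is its blank-corrected RLU
#' divided by the mean blank-corrected RLU of its matched control group.
#'
#' @param lum data.frame with columns `sample`, `rlu` (raw relative
#'   luminescence units), covering samples, controls and blanks.
#' @param blankIds sample ids of the blank wells (>= 1).
#' @param controls named list: sample id -> character vector of matched
#'   control sample ids (see [matchedControls()]).
#' @return data.frame: `sample`, `rlu_corrected`, `control_mean`,
#'   `fold_change`.
#' @export
ldhFoldChanges <- function(lum, blankIds, controls) {
  stopifnot(all(c("sample", "rlu") %in% colnames(lum)))
  if (!length(blankIds) || !all(blankIds %in% lum$sample))
    stopf("at least one blank well with luminescence is required")
  blankMean <- mean(lum$rlu[lum$sample %in% blankIds])
  corrected <- setNames(lum$rlu - blankMean, lum$sample)
  ids <- names(controls)
  missing <- setdiff(ids, lum$sample)
  if (length(missing))
    stopf("no luminescence for sample(s): %s",
          paste(missing, collapse = ", "))
  res <- lapply(ids, function(s) {
    ctrl <- controls[[s]]
    if (!length(ctrl) || !all(ctrl %in% lum$sample))
      stopf("missing matched control group for exposure sample '%s'", s)
    cm <- mean(corrected[ctrl])
    if (!is.finite(cm) || cm <= 0)
      stopf("control group of sample '%s' has nonpositive corrected mean %s",
            s, format(cm))
    data.frame(sample = s, rlu_corrected = unname(corrected[s]),
               control_mean = cm, fold_change = unname(corrected[s]) / cm,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Matched vehicle-control sample ids for each exposed sample
#'
#' Controls are the vehicle (chemical `"DMSO"`, concentration 0) samples
#' sharing the exposed sample's timepoint and vehicle percentage.
#'
#' @param design design table (see [designTable()]).
#' @return named list, exposed sample id -> control sample ids.
#' @export
matchedControls <- function(design) {
  exposed <- design[design$concentration_uM > 0, , drop = FALSE]
  out <- lapply(seq_len(nrow(exposed)), function(i) {
    row <- exposed[i, ]
    design$sample[design$concentration_uM == 0 &
                    design$timepoint == row$timepoint &
                    design$vehicle_pct == row$vehicle_pct]
  })
  setNames(out, exposed$sample)
}

#' Cytotoxic concentration flagging with cascade
#'
#' A concentration whose mean LDH fold change reaches the threshold is
#' cytotoxic, and so is every higher tested concentration regardless of its
#' own LDH value: past the first cytotoxic level the signal typically
#' *drops* as dead spheroids stop releasing LDH, so the cascade is applied
#' by concentration order.
#'
#' @param concentrations ascending tested concentrations (uM).
#' @param meanFoldChanges per-concentration mean LDH fold change (replicate
#'   mean), parallel to `concentrations`.
#' @param threshold fold-change cutoff (default 10).
#' @return numeric vector of excluded concentrations (possibly empty).
#' @export
flagCytotoxicConcentrations <- function(concentrations, meanFoldChanges,
                                        threshold = 10) {
  stopifnot(length(concentrations) == length(meanFoldChanges))
  if (!length(concentrations)) return(numeric(0))
  if (is.unsorted(concentrations, strictly = TRUE))
    stopf("concentrations must be sorted ascending")
  hit <- which(meanFoldChanges >= threshold)
  if (!length(hit)) return(numeric(0))
  concentrations[seq(min(hit), length(concentrations))]
}

#' Cytotoxicity exclusions for a whole study
#'
#' Applies [ldhFoldChanges()] and [flagCytotoxicConcentrations()] per
#' chemical and timepoint and returns the excluded samples.
#'
#' @param study a [PodExperiment-class].
#' @param threshold LDH fold-change cutoff (default 10).
#' @return list with `flagged` (data.frame: chemical, timepoint,
#'   concentration_uM) and `samples` (excluded sample ids).
#' @export
cytotoxicityExclusions <- function(study, threshold = 10) {
  d <- designTable(study)
  ldh <- ldhTable(study)
  lum <- data.frame(sample = ldh$sample, rlu = ldh$rlu)
  fc <- ldhFoldChanges(lum, ldh$sample[ldh$is_blank], matchedControls(d))
  d2 <- merge(d, fc[, c("sample", "fold_change")], by = "sample")
  flagged <- list()
  for (tp in unique(d2$timepoint)) {
    for (ch in setdiff(unique(d2$chemical), "DMSO")) {
      sub <- d2[d2$timepoint == tp & d2$chemical == ch, , drop = FALSE]
      if (!nrow(sub)) next
      agg <- aggregate(fold_change ~ concentration_uM, sub, mean)
      agg <- agg[order(agg$concentration_uM), ]
      bad <- flagCytotoxicConcentrations(agg$concentration_uM,
                                         agg$fold_change, threshold)
      if (length(bad))
        flagged[[length(flagged) + 1L]] <-
          data.frame(chemical = ch, timepoint = tp, concentration_uM = bad,
                     stringsAsFactors = FALSE)
    }
  }
  flagged <- if (length(flagged)) do.call(rbind, flagged) else
    data.frame(chemical = character(), timepoint = character(),
               concentration_uM = numeric())
  key <- paste(d$chemical, d$timepoint, d$concentration_uM)
  badKey <- paste(flagged$chemical, flagged$timepoint,
                  flagged$concentration_uM)
  list(flagged = flagged, samples = d$sample[key %in% badKey])
}

#' Study-wide sample quality control
#'
#' Applies, per timepoint, the exclusion gates used before any modeling:
#' \itemize{
#'   \item `low_reads`: mapped reads below `minReads` (default 100,000,
#'     i.e. 10% of the 1M-read target depth);
#'   \item `low_alignment`: fraction of mapped reads below `minFraction`
#'     (default 0.40);
#'   \item `cluster_singleton`: complete-linkage hierarchical clustering on
#'     the distance 1 - Spearman correlation across probes (probes with
#'     nonzero variance), dendrogram cut at height `clusterCut`; samples
#'     forming singleton clusters are excluded;
#'   \item `fence_outlier_<metric>`: Tukey outer fence at
#'     `fenceK` x IQR beyond the quartiles, applied independently to the
#'     number of probes with >= 5 reads, the number of probes capturing 80%
#'     of the signal, and the Gini coefficient.
#' }
#' Reasons accumulate; a sample may fail several gates. Samples listed in
#' `cytotoxic` are excluded with that reason first and do not enter the
#' clustering or fence statistics.
#'
#' @param metrics QC-metric table (see [qcMetrics()]).
#' @param counts count (or normalized) matrix, probes x samples.
#' @param design design table with at least `sample` and `timepoint`.
#' @param minReads minimum mapped reads.
#' @param minFraction minimum fraction of mapped reads.
#' @param fenceK fence multiplier (outer fence = 3).
#' @param clusterCut dendrogram cut height.
#' @param cytotoxic sample ids already excluded as cytotoxic.
#' @return an [ExclusionReport-class] (exposure table empty until
#'   [enforceMinReplicates()]).
#' @export
sampleQualityFilter <- function(metrics, counts, design,
                                minReads = 1e5, minFraction = 0.40,
                                fenceK = 3, clusterCut = 0.1,
                                cytotoxic = character()) {
  if (!all(design$sample %in% metrics$sample))
    stopf("QC metrics missing for sample(s): %s",
          paste(setdiff(design$sample, metrics$sample), collapse = ", "))
  if (!all(design$sample %in% colnames(counts)))
    stopf("counts missing for sample(s): %s",
          paste(setdiff(design$sample, colnames(counts)), collapse = ", "))
  ids <- design$sample
  reasons <- setNames(vector("list", length(ids)), ids)
  for (s in intersect(cytotoxic, ids)) reasons[[s]] <- "cytotoxic"
  m <- metrics[match(ids, metrics$sample), ]
  live <- setdiff(ids, cytotoxic)

  for (s in live[m$mapped_reads[match(live, ids)] < minReads])
    reasons[[s]] <- c(reasons[[s]], "low_reads")
  for (s in live[m$fraction_mapped[match(live, ids)] < minFraction])
    reasons[[s]] <- c(reasons[[s]], "low_alignment")

  fenceMetrics <- c(fence_outlier_nprobes5 = "n_probes_min5",
                    fence_outlier_nprobes80 = "n_probes_80pct",
                    fence_outlier_gini = "gini")
  for (tp in unique(design$timepoint)) {
    tpIds <- intersect(design$sample[design$timepoint == tp], live)
    if (length(tpIds) >= 3) { # clustering gate
      x <- counts[, tpIds, drop = FALSE]
      x <- x[apply(x, 1, function(r) stats::var(r) > 0), , drop = FALSE]
      if (nrow(x) >= 2) {
        dd <- as.dist(1 - cor(x, method = "spearman"))
        cl <- cutree(hclust(dd, method = "complete"), h = clusterCut)
        singletons <- names(cl)[cl %in% as.integer(names(which(table(cl) == 1)))]
        for (s in singletons)
          reasons[[s]] <- c(reasons[[s]], "cluster_singleton")
      }
    }
    if (length(tpIds) >= 4) { # fence gates
      mi <- match(tpIds, ids)
      for (code in names(fenceMetrics)) {
        v <- m[[fenceMetrics[[code]]]][mi]
        fence <- tukeyFence(v, fenceK)
        for (s in tpIds[v < fence["lower"] | v > fence["upper"]])
          reasons[[s]] <- c(reasons[[s]], code)
      }
    }
  }
  nr <- vapply(reasons, length, 1L)
  samples <- data.frame(
    sample = ids,
    status = ifelse(nr > 0, "excluded", "retained"),
    reasons = vapply(reasons, paste, "", collapse = ";"),
    stringsAsFactors = FALSE)
  new("ExclusionReport", samples = samples,
      exposures = data.frame(),
      params = list(minReads = minReads, minFraction = minFraction,
                    fenceK = fenceK, clusterCut = clusterCut))
}

#' Enforce a minimum replicate count per exposure
#'
#' Exposures (chemical x timepoint x concentration) retaining fewer than
#' `minN` samples after the upstream gates are dropped from BMC analysis;
#' their surviving samples are marked `insufficient_replicates`.
#'
#' @param report an [ExclusionReport-class] from [sampleQualityFilter()].
#' @param design design table sharing the report's sample ids.
#' @param minN minimum retained replicates (default 2).
#' @return the updated [ExclusionReport-class] with the exposure table
#'   filled in.
#' @export
enforceMinReplicates <- function(report, design, minN = 2) {
  s <- report@samples
  if (!all(design$sample %in% s$sample))
    stopf("report and design sample ids differ")
  retained <- s$sample[s$status == "retained"]
  exp <- unique(design[design$concentration_uM > 0,
                       c("chemical", "timepoint", "concentration_uM")])
  exp <- exp[order(exp$chemical, exp$timepoint, exp$concentration_uM), ]
  rownames(exp) <- NULL
  exp$n_retained <- vapply(seq_len(nrow(exp)), function(i) {
    sum(design$chemical == exp$chemical[i] &
          design$timepoint == exp$timepoint[i] &
          design$concentration_uM == exp$concentration_uM[i] &
          design$sample %in% retained)
  }, 1L)
  exp$retained <- exp$n_retained >= minN
  for (i in which(!exp$retained)) {
    hit <- design$sample[design$chemical == exp$chemical[i] &
                           design$timepoint == exp$timepoint[i] &
                           design$concentration_uM == exp$concentration_uM[i]]
    hit <- intersect(hit, retained)
    sel <- s$sample %in% hit
    s$status[sel] <- "excluded"
    s$reasons[sel] <- ifelse(nzchar(s$reasons[sel]),
                             paste0(s$reasons[sel], ";insufficient_replicates"),
                             "insufficient_replicates")
  }
  new("ExclusionReport", samples = s, exposures = exp,
      params = c(report@params, list(minN = minN)))
}

#' Full quality-control stage
#'
#' Cytotoxicity exclusions, then the study-wide sample gates, then the
#' minimum-replicate rule.
#'
#' @param study a [PodExperiment-class].
#' @inheritParams sampleQualityFilter
#' @param ldhThreshold LDH fold-change cutoff.
#' @param minN minimum retained replicates per exposure.
#' @return an [ExclusionReport-class].
#' @export
runQc <- function(study, ldhThreshold = 10, minReads = 1e5,
                  minFraction = 0.40, fenceK = 3, clusterCut = 0.1,
                  minN = 2) {
  cyto <- cytotoxicityExclusions(study, ldhThreshold)
  rep <- sampleQualityFilter(qcMetrics(study), counts(study),
                             designTable(study), minReads = minReads,
                             minFraction = minFraction, fenceK = fenceK,
                             clusterCut = clusterCut,
                             cytotoxic = cyto$samples)
  enforceMinReplicates(rep, designTable(study), minN)
}
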