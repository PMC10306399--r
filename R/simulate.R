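## Response-curve families on the log2 scale.
## A responsive gene's expected log2 expression at effective concentration c
## is baseline + maxEffect * shape(c), with shape(0) = 0 and shape -> 1 as
## c -> Inf:
##   hill:        shape(c) = c^h / (ec50^h + c^h)
##   exponential: shape(c) = 1 - exp(-(c / ec50)^h)
.curveShape <- function(family, conc, ec50, shape) {
  switch(family,
         hill = ifelse(conc <= 0, 0,
                       conc^shape / (ec50^shape + conc^shape)),
         exponential = 1 - exp(-(pmax(conc, 0) / ec50)^shape),
         flat = rep(0, length(conc)),
         stopf("unknown curve family '%s'", family))
}

## Analytic benchmark concentration of a ground-truth gene: the c solving
## |f(c) - f(0)| = sd, i.e. shape(c) = sd / |maxEffect|.
.curveTrueBmc <- function(family, ec50, shape, maxEffect, sd) {
  r <- sd / abs(maxEffect)
  if (!is.finite(r) || r <= 0 || r >= 1) return(NA_real_)
  switch(family,
         hill = ec50 * (r / (1 - r))^(1 / shape),
         exponential = ec50 * (-log(1 - r))^(1 / shape),
         flat = NA_real_)
}

.buildDesignTable <- function(design) {
  rows <- list()
  for (tp in design@timepoints) {
    for (v in names(design@controlCounts)) {
      nC <- design@controlCounts[[v]]
      if (nC < 1) next
      ids <- sprintf("%s_DMSO_%s_r%02d", tp, v, seq_len(nC))
      rows[[length(rows) + 1L]] <- data.frame(
        sample = ids, plate = ((seq_len(nC) - 1L) %% design@plates) + 1L,
        timepoint = tp, chemical = "DMSO", concentration_uM = 0,
        vehicle_pct = as.numeric(v), replicate = seq_len(nC),
        stringsAsFactors = FALSE)
    }
    for (ch in design@chemicals) {
      for (cc in design@concentrations[[ch]]) {
        nR <- design@replicates
        ids <- sprintf("%s_%s_c%g_r%d", tp, ch, cc, seq_len(nR))
        rows[[length(rows) + 1L]] <- data.frame(
          sample = ids, plate = ((seq_len(nR) - 1L) %% design@plates) + 1L,
          timepoint = tp, chemical = ch, concentration_uM = cc,
          vehicle_pct = vehicleFor(design, cc), replicate = seq_len(nR),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

## QC metrics derivable from the count matrix; mapped reads extrapolate the
## matrix column sums to the full targeted panel so that default simulations
## land near the assay's nominal 1M-read depth.
.computeQcMetrics <- function(counts, fractionMapped, panelSize = 3000) {
  n80 <- apply(counts, 2, function(x) {
    if (sum(x) == 0) return(0L)
    xs <- sort(x, decreasing = TRUE)
    sum(cumsum(xs) < 0.8 * sum(xs)) + 1L
  })
  data.frame(
    sample = colnames(counts),
    mapped_reads = round(colSums(counts) * panelSize / nrow(counts)),
    fraction_mapped = fractionMapped,
    n_probes_min5 = colSums(counts >= 5),
    n_probes_80pct = as.integer(n80),
    gini = apply(counts, 2, giniCoefficient),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Simulate a concentration-response transcriptomic study
#'
#' Generates a probe-by-sample count matrix with the statistical structure
#' the downstream analysis assumes: responsive genes follow a known
#' concentration-response curve on the log2 scale with normal within-group
#' variation; counts are negative binomial around the expected expression
#' with gene-specific dispersion and per-sample library-size factors; flat
#' genes have concentration-independent expectation. The analytic benchmark
#' concentration of every responsive gene (the concentration at which the
#' curve deviates from control by one within-group SD) is exported as
#' ground truth for recovery testing.
#'
#' Per-chemical potency multipliers shift every responsive gene's curve
#' along the concentration axis (EC50 / potency); the stored ground-truth
#' BMC refers to potency 1 and is divided by the multiplier via
#' [trueBmc()]. A potency chosen as the fraction-weighted sum of component
#' potencies makes a simulated "mixture" exposure exactly
#' concentration-additive with respect to its components.
#'
#' @param design a [SimDesign-class].
#' @param nGenes number of probes (>= 50).
#' @param fracResponsive fraction of probes given a response curve.
#' @param seed RNG seed (defaults to the design's).
#' @param potency named per-chemical potency multipliers (default 1).
#' @param vehicleShift named additive log2 shift per vehicle percentage
#'   (e.g. `c("0.17" = 0.2, "0.3" = 0.5)`); unspecified levels shift 0.
#'   The shift is applied to a random half of the probes — a shift common
#'   to every probe would be absorbed by the library-size factors;
#'   affected probes are flagged in the ground-truth table.
#' @param dispersionRange negative-binomial dispersion range (log-uniform).
#' @param libFactorRange per-sample library-size factor range (log-uniform).
#' @param baselineRange baseline log2 expression range.
#' @param effectRange absolute max effect range (log2 units).
#' @param sdRange within-group SD range (log2 units).
#' @param ec50Range EC50 range (uM, log-uniform).
#' @return a [PodExperiment-class] with assay `"counts"`, the design as
#'   colData, and LDH / QC-metric / ground-truth tables attached.
#' @export
simulateStudy <- function(design, nGenes = 1000, fracResponsive = 0.1,
                          seed = design@seed,
                          potency = NULL,
                          vehicleShift = NULL,
                          dispersionRange = c(0.002, 0.02),
                          libFactorRange = c(0.5, 2),
                          baselineRange = c(6, 11),
                          effectRange = c(1, 3),
                          sdRange = c(0.2, 0.6),
                          ec50Range = c(1, 50)) {
  validObject(design)
  if (nGenes < 50) stopf("invalid design: nGenes must be >= 50")
  if (fracResponsive < 0 || fracResponsive > 1)
    stopf("fracResponsive must be in [0, 1]")
  pot <- setNames(rep(1, length(design@chemicals)), design@chemicals)
  if (!is.null(potency)) pot[names(potency)] <- potency
  shift <- setNames(rep(0, length(design@vehicleLevels)),
                    as.character(design@vehicleLevels))
  if (!is.null(vehicleShift)) shift[names(vehicleShift)] <- vehicleShift

  dtab <- .buildDesignTable(design)
  nS <- nrow(dtab)
  withSeed(seed, {
    ## --- gene ground truth ---------------------------------------------
    probes <- sprintf("PROBE_%04d", seq_len(nGenes))
    nResp <- round(fracResponsive * nGenes)
    responsive <- rep(FALSE, nGenes)
    if (nResp > 0) responsive[sample.int(nGenes, nResp)] <- TRUE
    family <- ifelse(responsive,
                     sample(c("hill", "exponential"), nGenes, replace = TRUE),
                     "flat")
    baseline <- runif(nGenes, baselineRange[1], baselineRange[2])
    effect <- ifelse(responsive,
                     runif(nGenes, effectRange[1], effectRange[2]) *
                       sample(c(-1, 1), nGenes, replace = TRUE), 0)
    ec50 <- exp(runif(nGenes, log(ec50Range[1]), log(ec50Range[2])))
    hshape <- runif(nGenes, 1, 3)
    disp <- exp(runif(nGenes, log(dispersionRange[1]),
                      log(dispersionRange[2])))
    ## The benchmark response is defined against the *observed* log2
    ## within-group SD, which includes the count-sampling layer on top of
    ## the latent normal variation. The drawn SD is therefore the total
    ## target: the latent component is reduced by the delta-method count
    ## noise var (1/mu + phi)/ln(2)^2 at baseline so that observed group
    ## SDs converge to the stored value, keeping the analytic ground
    ## truth on the scale the modeling stage actually sees.
    gsd <- runif(nGenes, sdRange[1], sdRange[2])
    noiseSd <- sqrt(1 / 2^baseline + disp) / log(2)
    latentSd <- sqrt(pmax(gsd^2 - noiseSd^2, 0.03^2))
    gsd <- sqrt(latentSd^2 + noiseSd^2) # total; differs only when floored
    trueBmc <- vapply(seq_len(nGenes), function(g)
      .curveTrueBmc(family[g], ec50[g], hshape[g], effect[g], gsd[g]),
      numeric(1))
    gt <- data.frame(probe = probes, responsive = responsive,
                     family = family, baseline_log2 = baseline,
                     max_effect_log2 = effect, ec50_uM = ec50,
                     shape = hshape, sd_log2 = gsd, dispersion = disp,
                     true_bmc_uM = trueBmc, stringsAsFactors = FALSE)

    ## --- latent expression and counts ----------------------------------
    libf <- exp(runif(nS, log(libFactorRange[1]), log(libFactorRange[2])))
    cEff <- dtab$concentration_uM * pot[dtab$chemical]
    cEff[dtab$chemical == "DMSO"] <- 0
    vshift <- shift[as.character(dtab$vehicle_pct)]
    ## The vehicle (solvent) effect touches a subset of probes, as a real
    ## solvent response would; a shift common to all probes would simply
    ## be absorbed by the library-size factors and would leave the
    ## vehicle-rescaling step nothing to correct.
    vehicleAffected <- runif(nGenes) < 0.5
    counts <- matrix(0L, nGenes, nS, dimnames = list(probes, dtab$sample))
    for (g in seq_len(nGenes)) {
      mu2 <- baseline[g] + effect[g] *
        .curveShape(family[g], cEff, ec50[g], hshape[g]) +
        if (vehicleAffected[g]) vshift else 0
      latent <- mu2 + rnorm(nS, 0, latentSd[g])
      counts[g, ] <- rnbinom(nS, mu = libf * 2^latent, size = 1 / disp[g])
    }
    storage.mode(counts) <- "integer"
    gt$vehicle_affected <- vehicleAffected

    ## --- ancillary tables ----------------------------------------------
    frac <- runif(nS, 0.45, 0.78)
    qc <- .computeQcMetrics(counts, frac)
    blankRlu <- rnorm(3, 50, 5)
    ldh <- rbind(
      data.frame(sample = sprintf("BLANK_%d", 1:3), rlu = blankRlu,
                 is_blank = TRUE, stringsAsFactors = FALSE),
      data.frame(sample = dtab$sample, rlu = rnorm(nS, 1050, 30),
                 is_blank = FALSE, stringsAsFactors = FALSE))

    se <- SummarizedExperiment(
      assays = list(counts = counts),
      colData = DataFrame(dtab, row.names = dtab$sample))
    out <- new("PodExperiment", se, ldh = ldh, qcMetrics = qc,
               groundTruth = gt)
    metadata(out)$potency <- pot
    metadata(out)$seed <- as.integer(seed)
    metadata(out)$design <- design
    validObject(out)
    out
  })
}

#' Ground-truth BMC of simulated genes for one chemical
#'
#' Divides the stored reference BMC by the chemical's potency multiplier.
#'
#' @param study a simulated [PodExperiment-class].
#' @param chemical exposure id.
#' @return named numeric vector of true BMCs (uM; NA for flat genes).
#' @export
trueBmc <- function(study, chemical) {
  gt <- groundTruth(study)
  if (!nrow(gt)) stopf("study carries no ground truth")
  pot <- metadata(study)$potency
  if (!chemical %in% names(pot)) stopf("unknown chemical '%s'", chemical)
  setNames(gt$true_bmc_uM / pot[[chemical]], gt$probe)
}

#' Impose a cytotoxic collapse on a simulated study
#'
#' At and above the onset concentration of one chemical, expression counts
#' are globally suppressed (cell death); the LDH signal at the onset
#' concentration is set to the requested fold change over matched vehicle
#' controls, while higher concentrations show a *decreased* LDH signal, as
#' degraded spheroids release no further LDH. The cascade exclusion of the
#' higher concentrations is therefore driven by the QC rule, not by their
#' own LDH values. QC metrics are recomputed from the suppressed counts.
#'
#' @param study a simulated [PodExperiment-class].
#' @param chemical exposure id (must exist in the study design).
#' @param onsetConcentration one of the chemical's tested concentrations.
#' @param ldhFold LDH fold change to plant at the onset concentration.
#' @param suppression multiplicative count suppression at/above onset.
#' @return the modified [PodExperiment-class].
#' @export
simulateCytotoxicCollapse <- function(study, chemical, onsetConcentration,
                                      ldhFold, suppression = 0.05) {
  d <- designTable(study)
  if (!chemical %in% d$chemical) stopf("unknown chemical '%s'", chemical)
  concs <- sort(unique(d$concentration_uM[d$chemical == chemical]))
  if (!onsetConcentration %in% concs)
    stopf("onset concentration %g is not tested for '%s'",
          onsetConcentration, chemical)
  ldh <- ldhTable(study)
  blankMean <- mean(ldh$rlu[ldh$is_blank])
  hit <- d$chemical == chemical & d$concentration_uM >= onsetConcentration

  cts <- counts(study)
  cts[, d$sample[hit]] <- round(cts[, d$sample[hit], drop = FALSE] *
                                  suppression)
  for (s in d$sample[hit]) {
    row <- d[d$sample == s, ]
    ctrl <- d$sample[d$chemical == "DMSO" & d$timepoint == row$timepoint &
                       d$vehicle_pct == row$vehicle_pct]
    ctrlMean <- mean(ldh$rlu[match(ctrl, ldh$sample)]) - blankMean
    fold <- if (row$concentration_uM == onsetConcentration) ldhFold else 0.3
    ldh$rlu[ldh$sample == s] <- blankMean + fold * ctrlMean
  }
  qc <- study@qcMetrics
  newQc <- .computeQcMetrics(cts, qc$fraction_mapped[match(colnames(cts),
                                                           qc$sample)])
  out <- study
  out@ldh <- ldh
  out@qcMetrics <- newQc
  assay(out, "counts") <- cts
  validObject(out)
  out
}

#' Simulate a pathway database
#'
#' Draws gene sets (without replacement within a set; sets may overlap)
#' over the supplied gene universe, as a stand-in pathway annotation for
#' the lowest-pathway-median tPOD.
#'
#' @param geneIds gene universe.
#' @param nPathways number of sets.
#' @param sizeRange inclusive set-size range, within `[1, length(geneIds)]`.
#' @param seed RNG seed.
#' @return named list of character vectors (class `"PathwayDb"`), writable
#'   with [writeGmt()].
#' @export
simulatePathways <- function(geneIds, nPathways, sizeRange = c(5, 40),
                             seed = 1L) {
  if (sizeRange[1] < 1) stopf("size range lower bound must be >= 1")
  if (sizeRange[2] > length(geneIds))
    stopf("size range upper bound exceeds the gene universe")
  withSeed(seed, {
    sizeChoices <- seq(sizeRange[1], sizeRange[2])
    sizes <- sizeChoices[sample.int(length(sizeChoices), nPathways,
                                    replace = TRUE)]
    db <- lapply(sizes, function(k) sample(geneIds, k))
    names(db) <- sprintf("PATHWAY_%03d", seq_len(nPathways))
    structure(db, class = c("PathwayDb", "list"))
  })
}
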