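#' @describeIn PodExperiment-class the raw count matrix.
#' @param object,x a `PodExperiment`.
#' @export
setMethod("counts", "PodExperiment", function(object) assay(object, "counts"))

#' @describeIn PodExperiment-class per-sample LDH luminescence table
#'   (blanks included as `is_blank = TRUE` rows).
#' @export
setMethod("ldhTable", "PodExperiment", function(x) x@ldh)

#' @describeIn PodExperiment-class per-sample QC metrics.
#' @export
setMethod("qcMetrics", "PodExperiment", function(x) x@qcMetrics)

#' @describeIn PodExperiment-class per-probe simulation ground truth
#'   (empty for real studies).
#' @export
setMethod("groundTruth", "PodExperiment", function(x) x@groundTruth)

#' @describeIn PodExperiment-class the design table as a plain data.frame.
#' @export
setMethod("designTable", "PodExperiment",
          function(x) as.data.frame(colData(x)))

setMethod("show", "PodExperiment", function(object) {
  d <- designTable(object)
  cat("PodExperiment:", nrow(object), "probes x", ncol(object), "samples\n")
  cat("  chemicals:", paste(setdiff(unique(d$chemical), "DMSO"),
                            collapse = ", "), "\n")
  cat("  timepoints:", paste(unique(d$timepoint), collapse = ", "), "\n")
  cat("  controls:", sum(d$concentration_uM == 0), "samples;",
      "ground truth:", nrow(object@groundTruth), "probes\n")
})

#' @describeIn BmcDistribution-class gene id -> surviving bootstrap BMCs.
#' @param object,x a `BmcDistribution`.
#' @export
setMethod("bmcList", "BmcDistribution", function(x) x@bmcs)

#' @describeIn BmcDistribution-class per-gene number of surviving BMCs.
#' @export
setMethod("survivalCounts", "BmcDistribution",
          function(x) vapply(x@bmcs, length, 1L))

#' @describeIn BmcDistribution-class per-bootstrap fit detail table.
#' @export
setMethod("fitTable", "BmcDistribution", function(x) x@fits)

setMethod("show", "BmcDistribution", function(object) {
  n <- survivalCounts(object)
  cat("BmcDistribution:", object@chemical, "/", object@timepoint, "\n")
  cat("  ", length(n), "genes;", sum(n), "surviving BMCs of",
      length(n) * object@B, "draws (B =", object@B, ")\n")
})

#' @describeIn ExclusionReport-class ids of retained samples.
#' @param object,x an `ExclusionReport`.
#' @export
setMethod("retainedSamples", "ExclusionReport", function(x)
  x@samples$sample[x@samples$status == "retained"])

#' @describeIn ExclusionReport-class per-sample status/reason table.
#' @export
setMethod("sampleStatus", "ExclusionReport", function(x) x@samples)

#' @describeIn ExclusionReport-class per-exposure retained replicate counts.
#' @export
setMethod("exposureStatus", "ExclusionReport", function(x) x@exposures)

setMethod("show", "ExclusionReport", function(object) {
  s <- object@samples
  cat("ExclusionReport:", sum(s$status == "retained"), "of", nrow(s),
      "samples retained\n")
  bad <- s[s$status == "excluded", , drop = FALSE]
  if (nrow(bad)) {
    codes <- unlist(strsplit(bad$reasons, ";", fixed = TRUE))
    tab <- sort(table(codes), decreasing = TRUE)
    cat("  reasons:", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n")
  }
  if (nrow(object@exposures))
    cat("  exposures dropped:", sum(!object@exposures$retained), "of",
        nrow(object@exposures), "\n")
})

#' @describeIn MixtureDefinition-class molar fractions p_i (sum to 1).
#' @param object,x a `MixtureDefinition`.
#' @export
setMethod("molarFractions", "MixtureDefinition", function(x)
  setNames(x@molarities / sum(x@molarities), x@components))

#' @describeIn MixtureDefinition-class TRUE iff all component molarities
#'   are equal.
#' @export
setMethod("isEquimolar", "MixtureDefinition", function(x)
  diff(range(x@molarities)) <= 1e-12 * max(x@molarities))

setMethod("show", "MixtureDefinition", function(object) {
  cat("Mixture", object@mixtureId, "-", length(object@components),
      "components", if (isEquimolar(object)) "(equimolar)" else "", "\n")
  cat(" ", paste(object@components, collapse = " + "), "\n")
  cat("  total molarity:", sum(object@molarities), "uM\n")
})

#' @describeIn TpodResult-class per-simulation tPOD draws.
#' @param object,x a `TpodResult`.
#' @export
setMethod("tpodDraws", "TpodResult", function(x) x@draws)

setMethod("show", "TpodResult", function(object) {
  cat(sprintf("tPOD (%s) %s / %s: %.4g uM [%.4g, %.4g] over %d simulations%s\n",
              object@kind, object@chemical, object@timepoint, object@median,
              object@ciLower, object@ciUpper, object@nSim,
              if (isTRUE(object@fallback)) " (top-concentration fallback)"
              else ""))
})
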