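#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   colData "assay<-"
#' @importFrom S4Vectors DataFrame metadata "metadata<-"
NULL

## Required columns of a sample design table. Concentration 0 rows are the
## vehicle (DMSO) controls; concentrations are micromolar totals.
.designCols <- c("sample", "plate", "timepoint", "chemical",
                 "concentration_uM", "vehicle_pct", "replicate")

#' SimDesign: layout of a simulated concentration-response study
#'
#' Describes chemicals (or mixtures, treated as opaque exposure ids), their
#' tested concentrations in micromolar total, replication, plates,
#' timepoints, the vehicle-percentage rule and matched-control counts.
#'
#' The vehicle rule maps an exposure concentration to the DMSO percentage
#' used to dissolve it: concentrations below `vehicleBreaks[1]` use
#' `vehicleLevels[1]`, and so on (defaults: <50 uM at 0.1%, 50-<100 uM at
#' 0.17%, >=100 uM at 0.30%).
#'
#' @slot chemicals character vector of exposure ids.
#' @slot concentrations named list (per chemical) of strictly positive,
#'   ascending concentrations (uM).
#' @slot replicates replicates per exposure concentration.
#' @slot timepoints timepoint labels (free strings, never parsed).
#' @slot plates number of plates replicates are spread across.
#' @slot vehicleBreaks ascending concentration cutpoints for the vehicle rule.
#' @slot vehicleLevels vehicle percentages, length `length(vehicleBreaks)+1`.
#' @slot controlCounts named numeric: vehicle percentage (as character) ->
#'   number of matched control samples per timepoint.
#' @slot seed default simulation seed.
#' @export
setClass("SimDesign", representation(
  chemicals = "character",
  concentrations = "list",
  replicates = "integer",
  timepoints = "character",
  plates = "integer",
  vehicleBreaks = "numeric",
  vehicleLevels = "numeric",
  controlCounts = "numeric",
  seed = "integer"
))

setValidity("SimDesign", function(object) {
  msg <- character()
  if (!length(object@chemicals)) msg <- c(msg, "no chemicals")
  if (!identical(sort(names(object@concentrations)), sort(object@chemicals)))
    msg <- c(msg, "concentrations must be a named list covering every chemical")
  for (ch in names(object@concentrations)) {
    cc <- object@concentrations[[ch]]
    if (!length(cc) || any(!is.finite(cc)) || any(cc <= 0))
      msg <- c(msg, sprintf("chemical '%s': concentrations must be strictly positive", ch))
    else if (is.unsorted(cc, strictly = TRUE))
      msg <- c(msg, sprintf("chemical '%s': concentrations must be strictly ascending", ch))
  }
  if (object@replicates < 1L) msg <- c(msg, "replicates must be >= 1")
  if (length(object@vehicleLevels) != length(object@vehicleBreaks) + 1L)
    msg <- c(msg, "vehicleLevels must have length length(vehicleBreaks) + 1")
  used <- unique(unlist(lapply(object@concentrations, function(cc)
    vehicleFor(object, cc))))
  have <- object@controlCounts[as.character(used)]
  if (any(is.na(have)) || any(have < 2))
    msg <- c(msg, "every vehicle percentage in use needs >= 2 matched control samples")
  if (length(msg)) msg else TRUE
})

#' Construct a SimDesign
#'
#' Defaults mirror the study layout this generator emulates: the standard
#' single-chemical series 0.2, 2, 10, 20, 50, 100 uM, 4 replicates per
#' exposure spread over 4 plates, and per-timepoint vehicle control counts
#' of 24 (0.1%), 8 (0.17%) and 8 (0.30%).
#'
#' @param chemicals character vector of exposure ids.
#' @param concentrations numeric vector (shared by all chemicals) or named
#'   list per chemical, uM.
#' @param replicates replicates per exposure concentration.
#' @param timepoints timepoint labels.
#' @param plates number of plates.
#' @param vehicleBreaks,vehicleLevels vehicle-percentage rule (see class doc).
#' @param controlCounts named numeric, controls per vehicle level per timepoint.
#' @param seed default simulation seed.
#' @return a [SimDesign-class] object.
#' @export
simDesign <- function(chemicals,
                      concentrations = c(0.2, 2, 10, 20, 50, 100),
                      replicates = 4L,
                      timepoints = "24h",
                      plates = 4L,
                      vehicleBreaks = c(50, 100),
                      vehicleLevels = c(0.1, 0.17, 0.3),
                      controlCounts = c("0.1" = 24, "0.17" = 8, "0.3" = 8),
                      seed = 1L) {
  if (!is.list(concentrations))
    concentrations <- setNames(rep(list(as.numeric(concentrations)),
                                   length(chemicals)), chemicals)
  new("SimDesign", chemicals = as.character(chemicals),
      concentrations = concentrations, replicates = as.integer(replicates),
      timepoints = as.character(timepoints), plates = as.integer(plates),
      vehicleBreaks = vehicleBreaks, vehicleLevels = vehicleLevels,
      controlCounts = controlCounts, seed = as.integer(seed))
}

#' Vehicle percentage for given concentrations under a design's vehicle rule
#' @param design a [SimDesign-class].
#' @param conc numeric concentrations (uM).
#' @return numeric vehicle percentages.
#' @export
vehicleFor <- function(design, conc) {
  design@vehicleLevels[findInterval(conc, design@vehicleBreaks) + 1L]
}

#' PodExperiment: counts, design and ancillary tables of one study
#'
#' A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' holding the probe-by-sample count matrix (assay `"counts"`) and the
#' sample design table as `colData`, extended with the per-sample LDH
#' luminescence table, the per-sample QC-metric table and (for simulated
#' studies) the per-probe ground truth.
#'
#' @slot ldh data.frame with columns `sample`, `rlu`, `is_blank`.
#' @slot qcMetrics data.frame with columns `sample`, `mapped_reads`,
#'   `fraction_mapped`, `n_probes_min5`, `n_probes_80pct`, `gini`.
#' @slot groundTruth data.frame (possibly empty) of per-probe simulation
#'   truth; see [groundTruth()].
#' @export
setClass("PodExperiment", contains = "SummarizedExperiment",
         representation(ldh = "data.frame",
                        qcMetrics = "data.frame",
                        groundTruth = "data.frame"))

setValidity("PodExperiment", function(object) {
  msg <- character()
  if (!"counts" %in% names(assays(object)))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cts <- assay(object, "counts")
    if (any(cts < 0)) msg <- c(msg, "counts must be nonnegative")
    if (any(cts != round(cts))) msg <- c(msg, "counts must be integral")
  }
  missing <- setdiff(.designCols, colnames(colData(object)))
  if (length(missing))
    msg <- c(msg, paste0("design columns missing: ",
                         paste(missing, collapse = ", ")))
  else {
    ids <- colData(object)$sample
    if (anyDuplicated(ids)) msg <- c(msg, "duplicate sample ids")
    if (nrow(object@ldh) &&
        !all(ids %in% object@ldh$sample[!object@ldh$is_blank]))
      msg <- c(msg, "every sample must appear in the LDH table")
    if (nrow(object@qcMetrics) && !all(ids %in% object@qcMetrics$sample))
      msg <- c(msg, "every sample must appear in the QC-metrics table")
  }
  if (length(msg)) msg else TRUE
})

#' ExclusionReport: per-sample QC verdicts and per-exposure replicate counts
#'
#' @slot samples data.frame: `sample`, `status` ("retained"/"excluded"),
#'   `reasons` (semicolon-joined machine-readable codes).
#' @slot exposures data.frame: `chemical`, `timepoint`, `concentration_uM`,
#'   `n_retained`, `retained` (logical; FALSE when the exposure is dropped
#'   from BMC analysis).
#' @slot params list of the thresholds used.
#' @export
setClass("ExclusionReport", representation(
  samples = "data.frame", exposures = "data.frame", params = "list"))

#' BmcDistribution: surviving bootstrap BMCs per gene
#'
#' @slot chemical exposure id.
#' @slot timepoint timepoint label.
#' @slot B number of bootstrap draws attempted per gene.
#' @slot bmcs named list, gene id -> numeric vector of surviving BMCs
#'   (length <= B).
#' @slot fits data.frame of per-bootstrap fit details (model, BMC, BMCL,
#'   BMCU, fit p, filter reason).
#' @export
setClass("BmcDistribution", representation(
  chemical = "character", timepoint = "character", B = "integer",
  bmcs = "list", fits = "data.frame"))

setValidity("BmcDistribution", function(object) {
  n <- vapply(object@bmcs, length, 1L)
  if (any(n > object@B)) "a gene has more surviving BMCs than draws" else TRUE
})

#' TpodResult: a transcriptomic point of departure with its uncertainty
#'
#' @slot chemical exposure id.
#' @slot timepoint timepoint label.
#' @slot kind `"gene25"` or `"pathway_lowest_median"`.
#' @slot median median tPOD (uM) over simulated experiments.
#' @slot ciLower,ciUpper percentile confidence bounds (uM).
#' @slot nSim number of simulated experiments.
#' @slot fallback TRUE when the reported tPOD is effectively the top tested
#'   concentration because most simulations had too few genes.
#' @slot draws the per-simulation tPOD values the summary was taken over.
#' @export
setClass("TpodResult", representation(
  chemical = "character", timepoint = "character", kind = "character",
  median = "numeric", ciLower = "numeric", ciUpper = "numeric",
  nSim = "integer", fallback = "logical", draws = "numeric"))

setValidity("TpodResult", function(object) {
  if (is.na(object@median)) return(TRUE) # undefined result, flagged upstream
  if (object@ciLower <= object@median && object@median <= object@ciUpper)
    TRUE else "requires ciLower <= median <= ciUpper"
})

#' MixtureDefinition: components and molar composition of one mixture
#'
#' Components are stored with their per-component molarity at a reference
#' exposure level; molar fractions p_i = molarity_i / total are derived.
#' All mixture potencies in this package are on the total-molarity basis.
#'
#' @slot mixtureId mixture id.
#' @slot components chemical ids.
#' @slot molarities per-component molarities (uM), parallel to `components`.
#' @export
setClass("MixtureDefinition", representation(
  mixtureId = "character", components = "character", molarities = "numeric"))

setValidity("MixtureDefinition", function(object) {
  msg <- character()
  if (length(object@components) != length(object@molarities))
    msg <- c(msg, "components and molarities must be parallel")
  if (anyDuplicated(object@components)) msg <- c(msg, "duplicate components")
  if (any(!is.finite(object@molarities)) || any(object@molarities <= 0))
    msg <- c(msg, "molarities must be strictly positive")
  if (length(msg)) msg else TRUE
})

#' Construct a MixtureDefinition
#' @param mixtureId mixture id.
#' @param components chemical ids.
#' @param molarities per-component molarities (uM); a single value is
#'   recycled (equimolar mixture).
#' @return a [MixtureDefinition-class].
#' @export
mixtureDefinition <- function(mixtureId, components, molarities = 1) {
  if (length(molarities) == 1L)
    molarities <- rep(molarities, length(components))
  new("MixtureDefinition", mixtureId = as.character(mixtureId),
      components = as.character(components),
      molarities = as.numeric(molarities))
}
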