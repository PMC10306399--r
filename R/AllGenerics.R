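#' @importFrom BiocGenerics counts
NULL

#' @rdname PodExperiment-class
#' @export
setGeneric("ldhTable", function(x) standardGeneric("ldhTable"))

#' @rdname PodExperiment-class
#' @export
setGeneric("qcMetrics", function(x) standardGeneric("qcMetrics"))

#' @rdname PodExperiment-class
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname PodExperiment-class
#' @export
setGeneric("designTable", function(x) standardGeneric("designTable"))

#' @rdname BmcDistribution-class
#' @export
setGeneric("bmcList", function(x) standardGeneric("bmcList"))

#' @rdname BmcDistribution-class
#' @export
setGeneric("survivalCounts", function(x) standardGeneric("survivalCounts"))

#' @rdname BmcDistribution-class
#' @export
setGeneric("fitTable", function(x) standardGeneric("fitTable"))

#' @rdname ExclusionReport-class
#' @export
setGeneric("retainedSamples", function(x) standardGeneric("retainedSamples"))

#' @rdname ExclusionReport-class
#' @export
setGeneric("sampleStatus", function(x) standardGeneric("sampleStatus"))

#' @rdname ExclusionReport-class
#' @export
setGeneric("exposureStatus", function(x) standardGeneric("exposureStatus"))

#' @rdname MixtureDefinition-class
#' @export
setGeneric("molarFractions", function(x) standardGeneric("molarFractions"))

#' @rdname MixtureDefinition-class
#' @export
setGeneric("isEquimolar", function(x) standardGeneric("isEquimolar"))

#' @rdname TpodResult-class
#' @export
setGeneric("tpodDraws", function(x) standardGeneric("tpodDraws"))
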