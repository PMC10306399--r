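#' Median-of-ratios library-size factors
#'
#' For each sample, the size factor is the median over probes of the ratio
#' of the probe's count to its geometric mean across samples, taken over
#' probes with a strictly positive geometric mean (i.e. no zero count in
#' any sample).
#'
#' @param counts probe x sample count matrix.
#' @return named positive numeric vector of per-sample size factors.
#' @export
libSizeFactors <- function(counts) {
  if (any(colSums(counts) == 0))
    stopf("sample(s) with all-zero counts: %s",
          paste(colnames(counts)[colSums(counts) == 0], collapse = ", "))
  logGeo <- rowMeans(log(counts))
  ok <- is.finite(logGeo)
  if (!any(ok))
    stopf("no probe has a positive geometric mean across samples")
  geo <- exp(logGeo[ok])
  f <- apply(counts[ok, , drop = FALSE], 2, function(x) median(x / geo))
  if (any(!is.finite(f)) || any(f <= 0))
    stopf("nonpositive size factor for sample(s): %s",
          paste(colnames(counts)[!is.finite(f) | f <= 0], collapse = ", "))
  f
}

#' Log2 library-size normalization
#'
#' `value(g, s) = log2(count(g, s) / factor_s + pseudocount)`.
#'
#' @param counts probe x sample count matrix.
#' @param factors per-sample size factors (from [libSizeFactors()]).
#' @param pseudocount added before the log (default 1, so zero counts map
#'   to 0).
#' @return matrix of log2 normalized values, with the factors attached as
#'   attribute `"sizeFactors"`.
#' @export
log2Normalize <- function(counts, factors = libSizeFactors(counts),
                          pseudocount = 1) {
  if (any(!is.finite(factors)) || any(factors <= 0))
    stopf("size factors must be strictly positive")
  if (length(factors) != ncol(counts))
    stopf("one size factor per sample is required")
  out <- log2(sweep(counts, 2, factors, "/") + pseudocount)
  attr(out, "sizeFactors") <- factors
  out
}

#' Rescale to the base vehicle's matched controls
#'
#' Exposures dissolved at higher vehicle (DMSO) percentages are normalized
#' to their vehicle-matched controls and rescaled to the base (0.1%)
#' control group: per probe and timepoint, samples with vehicle != base are
#' shifted by (mean of base-vehicle controls - mean of their matched
#' controls). Base-vehicle samples are never shifted. After rescaling the
#' non-base control samples are removed (set `dropControls = FALSE` to keep
#' them, e.g. to verify the shift is idempotent).
#'
#' @param norm log2 normalized matrix (probes x samples).
#' @param design design table covering the matrix columns.
#' @param baseVehicle base vehicle percentage (default 0.1).
#' @param dropControls drop non-base control samples afterwards.
#' @return the rescaled matrix (columns possibly removed).
#' @export
rescaleVehicleMatched <- function(norm, design, baseVehicle = 0.1,
                                  dropControls = TRUE) {
  design <- design[match(colnames(norm), design$sample), , drop = FALSE]
  if (any(is.na(design$sample)))
    stopf("design is missing sample(s) present in the matrix")
  out <- norm
  for (tp in unique(design$timepoint)) {
    inTp <- design$timepoint == tp
    baseCtrl <- design$sample[inTp & design$concentration_uM == 0 &
                                design$vehicle_pct == baseVehicle]
    vehicles <- setdiff(unique(design$vehicle_pct[inTp]), baseVehicle)
    if (length(vehicles) && !length(baseCtrl))
      stopf("timepoint '%s': no retained base-vehicle (%g%%) controls", tp,
            baseVehicle)
    baseMean <- rowMeans(out[, baseCtrl, drop = FALSE])
    for (v in vehicles) {
      ctrl <- design$sample[inTp & design$concentration_uM == 0 &
                              design$vehicle_pct == v]
      if (!length(ctrl))
        stopf("timepoint '%s': no retained matched controls for vehicle %g%%",
              tp, v)
      shift <- baseMean - rowMeans(out[, ctrl, drop = FALSE])
      cols <- design$sample[inTp & design$vehicle_pct == v]
      out[, cols] <- out[, cols, drop = FALSE] + shift
    }
  }
  if (dropControls) {
    drop <- design$sample[design$concentration_uM == 0 &
                            design$vehicle_pct != baseVehicle]
    out <- out[, setdiff(colnames(out), drop), drop = FALSE]
  }
  out
}

#' Full normalization stage
#'
#' Median-of-ratios size factors, log2 transform, vehicle-matched
#' rescaling, restricted to retained samples.
#'
#' @param study a [PodExperiment-class].
#' @param report an [ExclusionReport-class]; only retained samples enter.
#' @param pseudocount see [log2Normalize()].
#' @param baseVehicle see [rescaleVehicleMatched()].
#' @return list with `matrix` (normalized, rescaled, non-base controls
#'   removed), `design` (matching rows) and `sizeFactors`.
#' @export
normalizeStudy <- function(study, report = NULL, pseudocount = 1,
                           baseVehicle = 0.1) {
  d <- designTable(study)
  keep <- if (is.null(report)) d$sample else
    intersect(d$sample, retainedSamples(report))
  cts <- counts(study)[, keep, drop = FALSE]
  f <- libSizeFactors(cts)
  norm <- log2Normalize(cts, f, pseudocount)
  res <- rescaleVehicleMatched(norm, d[match(keep, d$sample), ],
                               baseVehicle = baseVehicle)
  list(matrix = res,
       design = d[match(colnames(res), d$sample), ],
       sizeFactors = f)
}
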