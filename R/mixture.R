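#' Relative potency factor
#'
#' `RPF_i = ECx_std / ECx_i`: the ratio of the standard chemical's
#' effective concentration to the component's. RPF above 1 means the
#' component is more potent than the standard.
#'
#' @param ecxStd effective concentration of the standard (uM).
#' @param ecxI effective concentration(s) of the component(s) (uM).
#' @return numeric RPF(s).
#' @export
relativePotency <- function(ecxStd, ecxI) {
  if (!is.finite(ecxStd) || ecxStd <= 0 ||
      any(!is.finite(ecxI)) || any(ecxI <= 0))
    stopf("effective concentrations must be positive and finite")
  ecxStd / ecxI
}

#' Relative potency table for a chemical set
#'
#' @param ecx named vector of per-chemical effective concentrations (uM,
#'   total-molarity basis).
#' @param standard the standard chemical id (RPF 1 by definition).
#' @return data.frame: `chemical`, `ecx_uM`, `rpf`, with the standard's id
#'   attached as attribute `"standard"`.
#' @export
rpfTable <- function(ecx, standard = names(ecx)[1]) {
  if (!standard %in% names(ecx))
    stopf("standard '%s' has no effective concentration", standard)
  out <- data.frame(chemical = names(ecx), ecx_uM = as.numeric(ecx),
                    rpf = relativePotency(ecx[[standard]], as.numeric(ecx)),
                    stringsAsFactors = FALSE)
  attr(out, "standard") <- standard
  out
}

#' Concentration-addition mixture potency
#'
#' The standard concentration-addition prediction
#' `ECx_mix = (sum_i p_i / ECx_i)^(-1)`, with `p_i` the molar fraction of
#' component i. Inputs and result are on the total-molarity basis.
#'
#' @param mix a [MixtureDefinition-class].
#' @param ecx named vector of per-component effective concentrations (uM,
#'   total-molarity basis); must cover every component.
#' @return predicted mixture ECx (uM, total molarity).
#' @export
predictMixtureEcx <- function(mix, ecx) {
  p <- molarFractions(mix)
  missing <- setdiff(names(p), names(ecx))
  if (length(missing))
    stopf("missing potency for component(s): %s",
          paste(missing, collapse = ", "))
  e <- ecx[names(p)]
  if (any(!is.finite(e)) || any(e <= 0))
    stopf("component potencies must be positive and finite")
  1 / sum(p / e)
}

#' Equimolar concentration-addition shortcut via relative potency factors
#'
#' For an equimolar mixture of N components,
#' `ECx_mix = N * ECx_std / sum_i RPF_i`, algebraically identical to
#' [predictMixtureEcx()] with `p_i = 1/N` and `ECx_i = ECx_std / RPF_i`.
#'
#' @param mix an equimolar [MixtureDefinition-class].
#' @param rpf an [rpfTable()] covering every component.
#' @return predicted mixture ECx (uM, total molarity).
#' @export
predictMixtureEcxEquimolar <- function(mix, rpf) {
  if (!isEquimolar(mix))
    stopf("mixture '%s' is not equimolar; use predictMixtureEcx()",
          mix@mixtureId)
  std <- attr(rpf, "standard")
  missing <- setdiff(mix@components, rpf$chemical)
  if (length(missing))
    stopf("missing RPF for component(s): %s", paste(missing, collapse = ", "))
  ecxStd <- rpf$ecx_uM[rpf$chemical == std]
  rpfI <- rpf$rpf[match(mix@components, rpf$chemical)]
  length(mix@components) * ecxStd / sum(rpfI)
}

#' Propagate component tPOD uncertainty into the mixture prediction
#'
#' Applies [predictMixtureEcx()] to each index-paired set of component
#' simulation draws (components are simulated independently; draws are
#' paired by index) and summarizes the resulting distribution by its
#' median and percentile interval.
#'
#' @param mix a [MixtureDefinition-class].
#' @param draws named list, component -> numeric vector of per-simulation
#'   tPOD draws (see [tpodDraws()]); equal lengths required.
#' @param ciLevel confidence level.
#' @return list: `median`, `ci_lower`, `ci_upper`, `draws`.
#' @export
propagatePredictionCi <- function(mix, draws, ciLevel = 0.95) {
  p <- molarFractions(mix)
  missing <- setdiff(names(p), names(draws))
  if (length(missing))
    stopf("no simulation draws for component(s): %s",
          paste(missing, collapse = ", "))
  draws <- draws[names(p)]
  len <- vapply(draws, length, 1L)
  if (length(unique(len)) != 1L)
    stopf("component draw vectors must be aligned in length")
  mat <- do.call(cbind, draws) # nSim x components, paired by index
  pred <- 1 / rowSums(sweep(1 / mat, 2, p[colnames(mat)], "*"))
  ci <- percentileCi(pred, ciLevel)
  list(median = median(pred), ci_lower = ci[1], ci_upper = ci[2],
       draws = pred)
}

#' Compare an empirical tPOD with its concentration-addition prediction
#'
#' Reports the fold difference of the medians (always >= 1, with a label
#' for which is lower), whether the two confidence intervals overlap, and
#' the conservative fold difference computed from the CI bounds: the upper
#' bound of the lower-valued interval against the lower bound of the
#' higher-valued interval, floored at 1 when the intervals overlap.
#'
#' @param empirical a [TpodResult-class] (or list with `median`,
#'   `ci_lower`, `ci_upper`).
#' @param predicted list with `median`, `ci_lower`, `ci_upper` (from
#'   [propagatePredictionCi()]).
#' @return one-row data.frame: medians and CIs, `fold_difference`,
#'   `direction` ("empirical_lower"/"predicted_lower"/"equal"),
#'   `ci_overlap`, `conservative_fold_difference`.
#' @export
comparePrediction <- function(empirical, predicted) {
  emp <- if (is(empirical, "TpodResult"))
    list(median = empirical@median, ci_lower = empirical@ciLower,
         ci_upper = empirical@ciUpper) else empirical
  fold <- max(emp$median, predicted$median) / min(emp$median,
                                                  predicted$median)
  overlap <- max(emp$ci_lower, predicted$ci_lower) <=
    min(emp$ci_upper, predicted$ci_upper)
  consFold <- if (overlap) 1 else {
    lowInt <- if (emp$median <= predicted$median) emp else predicted
    highInt <- if (emp$median <= predicted$median) predicted else emp
    max(1, highInt$ci_lower / lowInt$ci_upper)
  }
  data.frame(empirical_median = emp$median, empirical_ci_lower = emp$ci_lower,
             empirical_ci_upper = emp$ci_upper,
             predicted_median = predicted$median,
             predicted_ci_lower = predicted$ci_lower,
             predicted_ci_upper = predicted$ci_upper,
             fold_difference = fold,
             direction = if (emp$median == predicted$median) "equal"
             else if (emp$median < predicted$median) "empirical_lower"
             else "predicted_lower",
             ci_overlap = overlap,
             conservative_fold_difference = consFold,
             stringsAsFactors = FALSE)
}

#' Rank-matched concentration-addition accumulation curve
#'
#' At each gene-BMC rank present in every component's accumulation curve,
#' the mixture's predicted BMC is the concentration-addition combination
#' of the components' rank-matched BMCs; ranks where any component curve
#' has ended are absent.
#'
#' @param mix a [MixtureDefinition-class].
#' @param curves named list, component -> accumulation curve data.frame
#'   from [accumulationCurve()].
#' @return data.frame: `rank`, `predicted_bmc`.
#' @export
predictedAccumulationCurve <- function(mix, curves) {
  p <- molarFractions(mix)
  missing <- setdiff(names(p), names(curves))
  if (length(missing))
    stopf("no accumulation curve for component(s): %s",
          paste(missing, collapse = ", "))
  ranks <- Reduce(intersect, lapply(curves[names(p)], `[[`, "rank"))
  rows <- lapply(sort(ranks), function(k) {
    ecx <- vapply(names(p), function(ch)
      curves[[ch]]$median[curves[[ch]]$rank == k], numeric(1))
    data.frame(rank = k, predicted_bmc = predictMixtureEcx(mix, ecx))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
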