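#' Simulate experiments from a bootstrap BMC distribution
#'
#' Each simulated experiment includes every gene independently with
#' probability (surviving draws) / B — its relative frequency in the
#' bootstrap — and, when included, assigns it one of its surviving BMCs
#' drawn uniformly.
#'
#' @param dist a [BmcDistribution-class] with at least one surviving BMC.
#' @param nSim number of simulated experiments (default 10,000).
#' @param seed RNG seed.
#' @return object of class `"TpodSimulations"`: a list with `genes`,
#'   `incl` (nSim x genes logical inclusion matrix), `vals` (drawn BMC per
#'   simulation and gene) and `nSim`.
#' @export
simulateTpodExperiments <- function(dist, nSim = 10000, seed = NULL) {
  bmcs <- bmcList(dist)
  if (!length(bmcs) || !sum(vapply(bmcs, length, 1L)))
    stopf("empty BMC distribution: no gene has a surviving BMC")
  genes <- names(bmcs)
  G <- length(genes)
  withSeed(seed, {
    incl <- matrix(FALSE, nSim, G, dimnames = list(NULL, genes))
    vals <- matrix(NA_real_, nSim, G, dimnames = list(NULL, genes))
    for (j in seq_len(G)) {
      v <- bmcs[[j]]
      incl[, j] <- runif(nSim) < length(v) / dist@B
      vals[, j] <- if (length(v) == 1L) v else
        v[sample.int(length(v), nSim, replace = TRUE)]
    }
    structure(list(genes = genes, incl = incl, vals = vals,
                   nSim = as.integer(nSim), chemical = dist@chemical,
                   timepoint = dist@timepoint, B = dist@B),
              class = "TpodSimulations")
  })
}

## k-th smallest BMC per simulation; NA where a simulation has < k genes
.rankMatrix <- function(sims, maxRank) {
  out <- matrix(NA_real_, sims$nSim, maxRank)
  for (i in seq_len(sims$nSim)) {
    v <- sort(sims$vals[i, sims$incl[i, ]])
    k <- min(length(v), maxRank)
    if (k > 0) out[i, seq_len(k)] <- v[seq_len(k)]
  }
  out
}

#' 25th-gene-BMC transcriptomic point of departure
#'
#' Per simulated experiment the value is the `rank`-th smallest gene BMC;
#' an experiment with fewer genes than the rank substitutes the top tested
#' concentration (the documented handling for weakly responding chemicals
#' whose gene count never reaches the rank). The tPOD is the median over
#' simulations with 2.5/97.5 percentile confidence bounds; the fallback
#' flag is set when the majority of simulations required the substitution.
#'
#' @param sims a `"TpodSimulations"` object.
#' @param topConc top tested concentration (uM), used as the fallback.
#' @param rank gene rank (default 25).
#' @param ciLevel confidence level (default 0.95).
#' @return a [TpodResult-class].
#' @export
gene25Tpod <- function(sims, topConc, rank = 25, ciLevel = 0.95) {
  nGenes <- rowSums(sims$incl)
  draws <- numeric(sims$nSim)
  short <- nGenes < rank
  rk <- .rankMatrix(sims, rank)
  draws[!short] <- rk[!short, rank]
  draws[short] <- topConc
  ci <- percentileCi(draws, ciLevel)
  new("TpodResult", chemical = sims$chemical, timepoint = sims$timepoint,
      kind = "gene25", median = median(draws), ciLower = ci[1],
      ciUpper = ci[2], nSim = sims$nSim,
      fallback = mean(short) > 0.5, draws = draws)
}

#' Lowest-pathway-median-BMC transcriptomic point of departure
#'
#' Per simulated experiment, a pathway qualifies when at least `minGenes`
#' of its genes carry BMCs in that experiment and those genes make up at
#' least `minFraction` of the pathway's size; the experiment's value is
#' the minimum over qualifying pathways of the median BMC of the pathway's
#' present genes. Experiments with no qualifying pathway contribute
#' nothing; if no experiment has one, the result is flagged undefined
#' (NA median).
#'
#' @param sims a `"TpodSimulations"` object.
#' @param pathways named list, pathway id -> gene ids (see [readGmt()]).
#' @param minGenes minimum present genes per pathway (default 3).
#' @param minFraction minimum present fraction of the pathway (default
#'   0.05).
#' @param ciLevel confidence level.
#' @return a [TpodResult-class].
#' @export
pathwayLowestMedianTpod <- function(sims, pathways, minGenes = 3,
                                    minFraction = 0.05, ciLevel = 0.95) {
  if (!length(pathways)) stopf("pathway database is empty")
  draws <- rep(NA_real_, sims$nSim)
  for (pw in names(pathways)) {
    idx <- which(sims$genes %in% pathways[[pw]])
    if (!length(idx)) next
    size <- length(pathways[[pw]])
    present <- sims$incl[, idx, drop = FALSE]
    nPresent <- rowSums(present)
    ok <- nPresent >= minGenes & nPresent >= minFraction * size
    if (!any(ok)) next
    vv <- sims$vals[, idx, drop = FALSE]
    vv[!present] <- NA_real_
    med <- apply(vv[ok, , drop = FALSE], 1, median, na.rm = TRUE)
    draws[ok] <- pmin(draws[ok], med, na.rm = TRUE)
  }
  defined <- !is.na(draws)
  if (!any(defined)) {
    return(new("TpodResult", chemical = sims$chemical,
               timepoint = sims$timepoint, kind = "pathway_lowest_median",
               median = NA_real_, ciLower = NA_real_, ciUpper = NA_real_,
               nSim = sims$nSim, fallback = FALSE, draws = draws))
  }
  ci <- percentileCi(draws[defined], ciLevel)
  new("TpodResult", chemical = sims$chemical, timepoint = sims$timepoint,
      kind = "pathway_lowest_median", median = median(draws[defined]),
      ciLower = ci[1], ciUpper = ci[2], nSim = sims$nSim,
      fallback = FALSE, draws = draws)
}

#' Gene-BMC accumulation curve
#'
#' For each rank up to `maxRank`, the median (with percentile CI) over
#' simulated experiments of the rank-th smallest gene BMC. Experiments
#' with fewer genes than a rank contribute nothing at that rank, and
#' ranks no experiment reaches are absent, so the curve ends at the total
#' number of genes fitting BMCs when fewer than `maxRank`.
#'
#' @param sims a `"TpodSimulations"` object.
#' @param maxRank largest rank reported (default 100).
#' @param ciLevel confidence level.
#' @return data.frame: `rank`, `median`, `ci_lower`, `ci_upper`, `n_sims`.
#' @export
accumulationCurve <- function(sims, maxRank = 100, ciLevel = 0.95) {
  rk <- .rankMatrix(sims, maxRank)
  rows <- lapply(seq_len(maxRank), function(k) {
    v <- rk[, k]
    v <- v[!is.na(v)]
    if (!length(v)) return(NULL)
    ci <- percentileCi(v, ciLevel)
    data.frame(rank = k, median = median(v), ci_lower = ci[1],
               ci_upper = ci[2], n_sims = length(v))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
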