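#' BMC-stage configuration
#'
#' Bundles the benchmark-concentration modeling parameters with their
#' standard defaults: the five-model suite, a benchmark response of 1
#' residual SD under constant variance, 95% profile-likelihood confidence
#' bounds, 100 bootstrap draws, and the BMC filters (BMC no higher than
#' the top tested concentration, BMCU/BMCL ratio below 40, goodness-of-fit
#' p above 0.1).
#'
#' @param models model suite.
#' @param bmrFactor benchmark response in residual SDs.
#' @param ciLevel profile confidence level.
#' @param B bootstrap draws per gene.
#' @param maxRatio BMCU/BMCL filter bound (fits at or above are dropped).
#' @param minFitP goodness-of-fit filter (fits at or below are dropped).
#' @param alphaNested nested chi-square level for linear vs poly2.
#' @return list of class `"FitConfig"`.
#' @export
fitConfig <- function(models = .bmcModels, bmrFactor = 1, ciLevel = 0.95,
                      B = 100, maxRatio = 40, minFitP = 0.1,
                      alphaNested = 0.05) {
  stopifnot(B >= 1, ciLevel > 0, ciLevel < 1, maxRatio > 1)
  structure(list(models = models, bmrFactor = bmrFactor, ciLevel = ciLevel,
                 B = as.integer(B), maxRatio = maxRatio, minFitP = minFitP,
                 alphaNested = alphaNested),
            class = "FitConfig")
}

#' Parametric bootstrap of a gene's concentration-response
#'
#' Each draw replaces every concentration group's values by draws from a
#' normal distribution whose mean and SD are the group's sample estimates
#' (a zero-SD group yields constant draws).
#'
#' @param conc per-sample concentrations (0 = control); every group needs
#'   at least 2 samples.
#' @param values per-sample log2 values.
#' @param B number of bootstrap draws.
#' @param seed RNG seed.
#' @return numeric matrix, `length(values)` x `B`; rows align with `conc`.
#' @export
bootstrapGeneResponses <- function(conc, values, B = 100, seed = NULL) {
  stopifnot(length(conc) == length(values))
  nPer <- table(conc)
  if (any(nPer < 2))
    stopf("group(s) with fewer than 2 samples: %s",
          paste(names(nPer)[nPer < 2], collapse = ", "))
  gm <- vapply(split(values, conc), mean, numeric(1))
  gs <- vapply(split(values, conc), sd, numeric(1))
  mu <- gm[as.character(conc)]
  sg <- gs[as.character(conc)]
  n <- length(values)
  withSeed(seed,
    matrix(rnorm(n * B, mean = rep(mu, B), sd = rep(sg, B)), n, B))
}

## Fit the suite on one response vector, select, and profile the BMC.
.fitOneDraw <- function(conc, values, config) {
  fits <- fitAllModels(conc, values, config$models)
  best <- selectBestModel(fits, config$alphaNested)
  if (is.null(best))
    return(data.frame(model = NA_character_, bmc = NA_real_,
                      bmcl = NA_real_, bmcu = NA_real_, gofP = NA_real_))
  pb <- profileBmc(best, config$bmrFactor, config$ciLevel)
  data.frame(model = best$model, bmc = pb$bmc, bmcl = pb$bmcl,
             bmcu = pb$bmcu, gofP = best$gofP)
}

## Filter verdict for one fit row; "" means kept.
.bmcFilterReason <- function(row, topConc, maxRatio, minFitP) {
  if (is.na(row$model)) return("no_fit")
  if (is.na(row$bmc)) return("no_bmc")
  if (row$bmc > topConc) return("bmc_above_top")
  ratio <- row$bmcu / row$bmcl
  if (!is.finite(ratio) || ratio >= maxRatio) return("ci_ratio")
  if (is.na(row$gofP) || row$gofP <= minFitP) return("poor_fit")
  ""
}

#' Apply the BMC filters to a fit table
#'
#' Keeps fits whose BMC is at or below the top tested concentration
#' (strictly higher excluded), whose BMCU/BMCL ratio is below the bound
#' (ratio at the bound excluded) and whose goodness-of-fit p exceeds the
#' cutoff (p at the cutoff excluded); others receive a reason code.
#'
#' @param fits data.frame with columns `gene`, `draw`, `model`, `bmc`,
#'   `bmcl`, `bmcu`, `gofP`.
#' @param topConc highest tested concentration (uM).
#' @param config a [fitConfig()].
#' @param chemical,timepoint labels for the result.
#' @return a [BmcDistribution-class].
#' @export
filterBmcs <- function(fits, topConc, config = fitConfig(),
                       chemical = "chemical", timepoint = "tp") {
  fits$reason <- vapply(seq_len(nrow(fits)), function(i)
    .bmcFilterReason(fits[i, ], topConc, config$maxRatio, config$minFitP),
    "")
  kept <- fits[fits$reason == "", , drop = FALSE]
  bmcs <- split(kept$bmc, factor(kept$gene, levels = unique(fits$gene)))
  bmcs <- bmcs[vapply(bmcs, length, 1L) > 0]
  new("BmcDistribution", chemical = chemical, timepoint = timepoint,
      B = config$B, bmcs = lapply(bmcs, as.numeric), fits = fits)
}

#' Bootstrap BMC distribution for a set of genes
#'
#' For each gene: draw `config$B` parametric bootstrap response sets, fit
#' the model suite on each, select the best model, derive BMC/BMCL/BMCU by
#' profile likelihood, and keep the draws passing the BMC filters.
#'
#' @param norm normalized log2 matrix (genes x samples) for one chemical
#'   and timepoint, controls (concentration 0) included.
#' @param conc per-sample concentrations aligned with the columns.
#' @param genes gene ids to model (default: all rows).
#' @param config a [fitConfig()].
#' @param seed master seed; per-gene seeds are derived with [subSeed()].
#' @param chemical,timepoint labels for the result.
#' @return a [BmcDistribution-class].
#' @export
bmcDistribution <- function(norm, conc, genes = rownames(norm),
                            config = fitConfig(), seed = 1L,
                            chemical = "chemical", timepoint = "tp") {
  topConc <- max(conc)
  rows <- lapply(genes, function(g) {
    draws <- bootstrapGeneResponses(conc, norm[g, ], B = config$B,
                                    seed = subSeed(seed, "bmc", g))
    res <- lapply(seq_len(config$B), function(b)
      .fitOneDraw(conc, draws[, b], config))
    cbind(gene = g, draw = seq_len(config$B), do.call(rbind, res))
  })
  fits <- do.call(rbind, rows)
  filterBmcs(fits, topConc, config, chemical, timepoint)
}
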