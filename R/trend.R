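## Williams-type isotonic contrast for one direction.
## Groups must be ordered by concentration with the control first. The
## treatment means are amalgamated by weighted PAVA (nondecreasing), and
## the statistic is the amalgamated top-dose estimate minus the control
## mean, scaled by the pooled within-group SD.
.williamsStat <- function(values, group, nPerGroup, pooledSd) {
  m <- vapply(split(values, group), mean, numeric(1))
  k <- length(m)
  iso <- pava(m[-1], w = nPerGroup[-1])
  se <- pooledSd * sqrt(1 / nPerGroup[k] + 1 / nPerGroup[1])
  if (se == 0) return(0)
  (iso[k - 1] - m[1]) / se
}

#' Williams-type trend test with permutation p-value
#'
#' Tests for a monotone concentration-response against the control using
#' an isotonic-regression (pool-adjacent-violators) contrast: the
#' amalgamated top-dose mean minus the control mean, scaled by the pooled
#' within-group SD. Both response directions are evaluated (the test is run
#' on the values and on their negation) and the larger-magnitude direction
#' is reported, with ties broken toward "up". Significance comes from
#' permuting sample-to-group labels:
#' `p = (1 + #permuted >= observed) / (nPerm + 1)`.
#'
#' @param conc per-sample concentrations (uM); 0 denotes the control group.
#'   At least 3 groups including the control are required.
#' @param values per-sample log2 expression values.
#' @param nPerm number of permutations (default 500).
#' @param seed RNG seed for the permutations.
#' @return data.frame with `direction`, `statistic`, `p.value`.
#' @export
williamsTrend <- function(conc, values, nPerm = 500, seed = NULL) {
  stopifnot(length(conc) == length(values))
  if (!any(conc == 0)) stopf("a control group (concentration 0) is required")
  lev <- sort(unique(conc))
  if (length(lev) < 3) stopf("at least 3 concentration groups are required")
  if (length(values) < 6) stopf("at least 6 samples are required")
  group <- match(conc, lev)
  nPerGroup <- as.numeric(table(group))
  grpVar <- vapply(split(values, group), stats::var, numeric(1))
  grpVar[nPerGroup == 1] <- 0 # singleton groups carry no df
  pooledSd <- sqrt(sum((nPerGroup - 1) * grpVar) / sum(nPerGroup - 1))

  if (!is.finite(pooledSd) || pooledSd == 0) {
    allEqual <- diff(range(values)) == 0
    return(data.frame(direction = "up",
                      statistic = if (allEqual) 0 else Inf,
                      p.value = if (allEqual) 1 else NA_real_))
  }
  statBoth <- function(v) {
    up <- .williamsStat(v, group, nPerGroup, pooledSd)
    dn <- .williamsStat(-v, group, nPerGroup, pooledSd)
    if (abs(up) >= abs(dn)) c(up, 1) else c(dn, -1)
  }
  obs <- statBoth(values)
  perm <- withSeed(seed, vapply(seq_len(nPerm), function(i)
    statBoth(sample(values))[1], numeric(1)))
  p <- (1 + sum(perm >= obs[1])) / (nPerm + 1)
  data.frame(direction = if (obs[2] > 0) "up" else "down",
             statistic = obs[1], p.value = p, row.names = NULL)
}

#' Linear fold-change gate
#'
#' Passes when the largest absolute difference between any treatment group
#' mean and the control mean reaches `log2(thresholdLinear)` on the log2
#' scale (boundary inclusive).
#'
#' @param conc per-sample concentrations (0 = control).
#' @param values per-sample log2 values.
#' @param thresholdLinear linear fold-change threshold (default 1.5).
#' @return list with `pass` (logical) and `maxAbsLog2FC`.
#' @export
foldChangeGate <- function(conc, values, thresholdLinear = 1.5) {
  if (!any(conc == 0)) stopf("a control group (concentration 0) is required")
  m <- vapply(split(values, conc), mean, numeric(1))
  ctrl <- m[["0"]]
  mfc <- max(abs(m[names(m) != "0"] - ctrl))
  # small epsilon keeps the inclusive boundary robust to float rounding
  list(pass = mfc >= log2(thresholdLinear) - 1e-12, maxAbsLog2FC = mfc)
}

#' Trend prefilter over a gene matrix
#'
#' Runs the Williams-type permutation trend test and the linear
#' fold-change gate on every gene; genes pass with permutation
#' `p <= pMax` AND fold change at or above the gate.
#'
#' @param norm normalized log2 matrix (genes x samples) for one chemical
#'   and timepoint, controls included.
#' @param conc per-sample concentrations aligned to the columns.
#' @param pMax permutation p-value cutoff (default 0.01).
#' @param fc linear fold-change threshold (default 1.5).
#' @param nPerm permutations per gene (default 500).
#' @param seed RNG seed (one stream across genes; deterministic).
#' @return data.frame: `gene`, `direction`, `statistic`, `p.value`,
#'   `maxAbsLog2FC`, `pass`.
#' @export
prefilterGenes <- function(norm, conc, pMax = 0.01, fc = 1.5,
                           nPerm = 500, seed = NULL) {
  if (!nrow(norm))
    return(data.frame(gene = character(), direction = character(),
                      statistic = numeric(), p.value = numeric(),
                      maxAbsLog2FC = numeric(), pass = logical()))
  withSeed(seed, {
    rows <- lapply(seq_len(nrow(norm)), function(g) {
      tr <- williamsTrend(conc, norm[g, ], nPerm = nPerm, seed = NULL)
      gate <- foldChangeGate(conc, norm[g, ], fc)
      data.frame(gene = rownames(norm)[g], tr,
                 maxAbsLog2FC = gate$maxAbsLog2FC,
                 pass = !is.na(tr$p.value) & tr$p.value <= pMax & gate$pass,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
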