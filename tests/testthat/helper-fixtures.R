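## Shared builders for small in-code fixtures. Unit tests use reduced
## control counts for speed; study-condition defaults are exercised in the
## acceptance tests.

tinyDesign <- function(chemicals = "chemA", seed = 1L, ...) {
  simDesign(chemicals, seed = seed,
            controlCounts = c("0.1" = 8, "0.17" = 4, "0.3" = 4), ...)
}

## per-sample concentration vector with a control group
concVector <- function(levels = c(0.2, 2, 10, 20, 50, 100), n = 4,
                       nCtrl = 8) {
  rep(c(0, levels), c(nCtrl, rep(n, length(levels))))
}

## one gene's response values following a saturating log2 curve
curveValues <- function(conc, baseline = 8, effect = 2, ec50 = 10,
                        sd = 0.3, seed = NULL) {
  mu <- baseline + effect * (1 - exp(-conc / ec50))
  if (!is.null(seed)) set.seed(seed)
  mu + rnorm(length(conc), 0, sd)
}

## a BmcDistribution built directly from a gene -> BMCs list
makeDist <- function(bmcs, B = 10L, chemical = "chem", timepoint = "24h") {
  new("BmcDistribution", chemical = chemical, timepoint = timepoint,
      B = as.integer(B), bmcs = lapply(bmcs, as.numeric),
      fits = data.frame())
}

## a small homogeneous study for the sample QC gates: shared per-gene
## expression levels give realistic between-sample rank correlation
## (iid columns would make every sample a cluster singleton)
.qcFixture <- function(n = 12, nGenes = 40, seed = 1) {
  set.seed(seed)
  mu <- exp(runif(nGenes, log(50), log(2000)))
  counts <- matrix(rnbinom(nGenes * n, mu = mu, size = 20), nGenes, n,
                   dimnames = list(sprintf("g%02d", 1:nGenes),
                                   sprintf("s%02d", 1:n)))
  design <- data.frame(sample = colnames(counts), plate = 1,
                       timepoint = "24h",
                       chemical = rep(c("DMSO", "chemA"), c(4, n - 4)),
                       concentration_uM = rep(c(0, 1, 2, 5, 10),
                                              c(4, 2, 2, 2, 2))[1:n],
                       vehicle_pct = 0.1,
                       replicate = 1:n)
  metrics <- tpodmix:::.computeQcMetrics(counts, rep(0.6, n))
  list(counts = counts, design = design, metrics = metrics)
}

## all permutations of a small vector (for exhaustive permutation oracles)
allPermutations <- function(x) {
  n <- length(x)
  if (n == 1L) return(matrix(x, 1))
  out <- NULL
  for (i in seq_len(n)) {
    rest <- allPermutations(x[-i])
    out <- rbind(out, cbind(x[i], rest))
  }
  out
}
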