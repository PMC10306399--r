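test_that("size factors match a hand-computed median of ratios", {
  counts <- matrix(c(2, 4, 6, 4, 8, 3), 3,
                   dimnames = list(c("g1", "g2", "g3"), c("a", "b")))
  # geometric means: sqrt(8), sqrt(32), sqrt(18); ratios per sample have
  # medians 1/sqrt(2) and sqrt(2)
  f <- libSizeFactors(counts)
  expect_equal(unname(f), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
})

test_that("size factors are scale-equivariant and symmetric", {
  set.seed(1)
  a <- rnbinom(31, mu = 100, size = 10) + 1L
  counts <- cbind(a = a, b = a)
  f <- libSizeFactors(counts)
  expect_equal(f[["a"]], f[["b"]])
  counts2 <- cbind(a = a, b = 2L * a)
  f2 <- libSizeFactors(counts2)
  expect_equal(f2[["b"]] / f2[["a"]], 2)
  # permutation invariance over samples
  m <- cbind(a = a, b = rev(a) + 3L, c = a + 7L)
  expect_equal(libSizeFactors(m)[c("c", "a")],
               libSizeFactors(m[, c("c", "b", "a")])[c("c", "a")])
  expect_error(libSizeFactors(cbind(a = a, z = 0L * a)), "all-zero")
})

test_that("size factors agree with the DESeq2 median-of-ratios reference", {
  skip_if_not_installed("DESeq2")
  set.seed(7)
  counts <- matrix(rnbinom(31 * 6, mu = 150, size = 8) + 1L, 31, 6,
                   dimnames = list(sprintf("g%02d", 1:31),
                                   sprintf("s%d", 1:6)))
  ours <- libSizeFactors(counts)
  ref <- DESeq2::estimateSizeFactorsForMatrix(counts)
  # with an odd probe count the plain median of ratios coincides with
  # exp(median(log ratios))
  expect_equal(unname(ours), unname(ref), tolerance = 1e-10)
})

test_that("log2 normalization follows value = log2(count/factor + pc)", {
  counts <- matrix(c(0L, 7L), 1, dimnames = list("g", c("a", "b")))
  v <- log2Normalize(counts, factors = c(a = 1, b = 1))
  expect_equal(unname(v["g", ]), c(0, 3))
  # doubling a sample's counts and its factor leaves values unchanged
  counts2 <- matrix(c(10L, 20L), 1, dimnames = list("g", c("a", "b")))
  v2 <- log2Normalize(counts2, factors = c(a = 1, b = 2))
  expect_equal(v2["g", "a"], v2["g", "b"])
  expect_error(log2Normalize(counts, factors = c(a = 1, b = -1)),
               "positive")
})

test_that("vehicle rescaling removes a planted offset and spares the base", {
  d <- tinyDesign(replicates = 6L)
  st <- simulateStudy(d, nGenes = 80, fracResponsive = 0, seed = 21,
                      vehicleShift = c("0.17" = 0.4, "0.3" = 0.7))
  dsg <- designTable(st)
  f <- libSizeFactors(counts(st))
  norm <- log2Normalize(counts(st), f)
  res <- rescaleVehicleMatched(norm, dsg, dropControls = FALSE)
  # base-vehicle columns are untouched
  baseCols <- dsg$sample[dsg$vehicle_pct == 0.1]
  expect_identical(res[, baseCols], norm[, baseCols])
  # planted shifts vanish: vehicle-affected flat genes' 100 uM group mean
  # matches the base controls after rescaling
  aff <- groundTruth(st)$vehicle_affected
  ctrl <- dsg$sample[dsg$concentration_uM == 0 & dsg$vehicle_pct == 0.1]
  high <- dsg$sample[dsg$concentration_uM == 100]
  gap <- mean(rowMeans(res[aff, high]) - rowMeans(res[aff, ctrl]))
  gapBefore <- mean(rowMeans(norm[aff, high]) - rowMeans(norm[aff, ctrl]))
  # part of the global component of the shift is absorbed by the size
  # factors; the residual per-probe offset is what rescaling must remove
  expect_gt(gapBefore, 0.25)
  expect_lt(abs(gap), 0.1)
  # shifting is idempotent; dropping afterwards equals the one-shot path
  res2 <- rescaleVehicleMatched(res, dsg, dropControls = FALSE)
  expect_equal(res2, res, tolerance = 1e-12)
  drop1 <- rescaleVehicleMatched(norm, dsg)
  drop2 <- res[, colnames(drop1)]
  expect_equal(drop1, drop2, tolerance = 1e-12)
  # non-base controls are removed from the one-shot result
  expect_false(any(dsg$sample[dsg$concentration_uM == 0 &
                                dsg$vehicle_pct != 0.1] %in%
                     colnames(drop1)))
})

test_that("rescaling with equal control means only removes controls", {
  norm <- matrix(rep(c(5, 5, 5, 5, 7, 7), each = 2), nrow = 2,
                 dimnames = list(c("g1", "g2"),
                                 c("c1", "c2", "c3", "c4", "e1", "e2")))
  norm["g1", ] <- c(5, 5, 5, 5, 7, 7)
  norm["g2", ] <- c(4, 4, 4, 4, 6, 6)
  dsg <- data.frame(sample = colnames(norm), plate = 1, timepoint = "24h",
                    chemical = c("DMSO", "DMSO", "DMSO", "DMSO", "x", "x"),
                    concentration_uM = c(0, 0, 0, 0, 100, 100),
                    vehicle_pct = c(0.1, 0.1, 0.3, 0.3, 0.3, 0.3),
                    replicate = 1:6)
  out <- rescaleVehicleMatched(norm, dsg)
  expect_identical(colnames(out), c("c1", "c2", "e1", "e2"))
  expect_equal(out[, c("e1", "e2")], norm[, c("e1", "e2")])
  # a missing matched control group is an error naming the vehicle
  dsg2 <- dsg[dsg$vehicle_pct == 0.1 | dsg$concentration_uM > 0, ]
  expect_error(rescaleVehicleMatched(norm[, dsg2$sample], dsg2), "0.3")
})
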