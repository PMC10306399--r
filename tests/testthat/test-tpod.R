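test_that("degenerate single-BMC genes give identical simulations", {
  dist <- makeDist(setNames(as.list(1:30), sprintf("g%02d", 1:30)), B = 1)
  sims <- simulateTpodExperiments(dist, nSim = 200, seed = 1)
  expect_true(all(sims$incl))
  g25 <- gene25Tpod(sims, topConc = 100)
  expect_equal(g25@median, 25) # the 25th smallest of 1..30
  expect_equal(g25@ciLower, 25)
  expect_equal(g25@ciUpper, 25)
  expect_false(g25@fallback)
})

test_that("gene inclusion follows the survival relative frequency", {
  bmcs <- c(setNames(as.list(seq(1, 30)), sprintf("g%02d", 1:30)),
            list(half = rep(5, 5)))
  dist <- makeDist(bmcs, B = 10) # "half" survives 5 of 10 draws
  sims <- simulateTpodExperiments(dist, nSim = 10000, seed = 2)
  phat <- mean(sims$incl[, "half"])
  expect_lt(abs(phat - 0.5), 3 * sqrt(0.25 / 10000))
  sims2 <- simulateTpodExperiments(dist, nSim = 10000, seed = 2)
  expect_identical(sims$vals, sims2$vals)
  expect_error(simulateTpodExperiments(makeDist(list()), 10),
               "empty")
})

test_that("adding a low gene can only lower the 25th gene BMC", {
  base <- setNames(as.list(2:31), sprintf("g%02d", 1:30))
  d1 <- makeDist(base, B = 1)
  d2 <- makeDist(c(base, list(low = 0.5)), B = 1)
  s1 <- simulateTpodExperiments(d1, nSim = 50, seed = 3)
  s2 <- simulateTpodExperiments(d2, nSim = 50, seed = 3)
  expect_lte(gene25Tpod(s2, 100)@median, gene25Tpod(s1, 100)@median)
})

test_that("fewer genes than the rank falls back to the top concentration", {
  dist <- makeDist(setNames(as.list(1:10), sprintf("g%02d", 1:10)), B = 1)
  sims <- simulateTpodExperiments(dist, nSim = 100, seed = 4)
  g25 <- gene25Tpod(sims, topConc = 100)
  expect_equal(g25@median, 100)
  expect_true(g25@fallback)
})

test_that("pathway gates require 3 genes covering 5% of the set", {
  universe <- sprintf("G%03d", 1:200)
  dist <- makeDist(setNames(list(1, 2, 3), universe[1:3]), B = 1)
  sims <- simulateTpodExperiments(dist, nSim = 50, seed = 5)
  # 10-gene pathway with 3 present genes (30%) qualifies; median is 2
  small <- list(pwA = universe[1:10])
  r <- pathwayLowestMedianTpod(sims, small)
  expect_equal(r@median, 2)
  expect_equal(r@ciLower, 2)
  # 100-gene pathway with the same 3 genes (3% < 5%) does not qualify
  big <- list(pwB = universe[1:100])
  r2 <- pathwayLowestMedianTpod(sims, big)
  expect_true(is.na(r2@median))
  # the lowest qualifying pathway median wins
  dist3 <- makeDist(setNames(as.list(c(1, 2, 3, 4, 5, 6)), universe[1:6]),
                    B = 1)
  sims3 <- simulateTpodExperiments(dist3, nSim = 20, seed = 6)
  two <- list(lowPw = universe[1:3], highPw = universe[4:6])
  r3 <- pathwayLowestMedianTpod(sims3, two)
  expect_equal(r3@median, 2) # min(median(1,2,3)=2, median(4,5,6)=5)
})

test_that("accumulation curves are sorted and consistent with gene25", {
  set.seed(7)
  bmcs <- lapply(1:40, function(i) sort(runif(8, 1, 100)))
  names(bmcs) <- sprintf("g%02d", 1:40)
  dist <- makeDist(bmcs, B = 8) # survival 8/8: every gene always present
  sims <- simulateTpodExperiments(dist, nSim = 500, seed = 8)
  acc <- accumulationCurve(sims, maxRank = 40)
  expect_true(all(diff(acc$median) >= 0))
  g25 <- gene25Tpod(sims, topConc = 100)
  expect_equal(acc$median[acc$rank == 25], g25@median)
  # a single-gene distribution yields exactly rank 1
  one <- simulateTpodExperiments(makeDist(list(g1 = 5), B = 1), 20, seed = 9)
  acc1 <- accumulationCurve(one, maxRank = 10)
  expect_equal(acc1$rank, 1L)
})

test_that("simulation summaries match exhaustive enumeration on tiny input", {
  # 3 genes with survival 2/4, 4/4, 1/4 and <=2 BMCs each; rank-2 tPOD
  bmcs <- list(gA = c(1, 3), gB = c(10, 20), gC = 50)
  surv <- c(2, 4, 1)
  B <- 4
  top <- 100
  # exact enumeration over inclusion patterns and uniform BMC draws
  exactMean <- 0
  exactFallback <- 0
  for (inc in 0:7) {
    present <- as.logical(bitwAnd(inc, c(1, 2, 4)))
    pInc <- prod(ifelse(present, surv / B, 1 - surv / B))
    draws <- expand.grid(lapply(seq_along(bmcs), function(i)
      if (present[i]) bmcs[[i]] else NA_real_))
    pDraw <- 1 / nrow(draws)
    for (r in seq_len(nrow(draws))) {
      v <- sort(na.omit(as.numeric(draws[r, ])))
      val <- if (length(v) >= 2) v[2] else top
      exactMean <- exactMean + pInc * pDraw * val
      if (length(v) < 2) exactFallback <- exactFallback + pInc * pDraw
    }
  }
  dist <- makeDist(list(gA = c(1, 3), gB = c(10, 20, 10, 20), gC = 50),
                   B = B)
  # gB needs survival 4: repeat its two BMCs; gA 2; gC 1 (as constructed)
  sims <- simulateTpodExperiments(dist, nSim = 20000, seed = 10)
  r2 <- gene25Tpod(sims, topConc = top, rank = 2)
  simMean <- mean(tpodDraws(r2))
  simFallback <- mean(rowSums(sims$incl) < 2)
  expect_lt(abs(simMean - exactMean), 1.5) # ~3 MC SDs of a mean near 40
  expect_lt(abs(simFallback - exactFallback),
            3 * sqrt(exactFallback * (1 - exactFallback) / 20000))
})
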