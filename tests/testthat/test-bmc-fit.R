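test_that("bootstrap draws reproduce group moments and determinism", {
  conc <- rep(c(0, 1, 10), each = 4)
  y <- c(rnorm(4, 5, 0), 6:9 / 2, rep(7, 4))
  d1 <- bootstrapGeneResponses(conc, y, B = 50, seed = 3)
  d2 <- bootstrapGeneResponses(conc, y, B = 50, seed = 3)
  expect_identical(d1, d2)
  # zero-SD groups yield constant draws at the group mean
  yc <- rep(c(2, 4, 6), each = 4)
  dc <- bootstrapGeneResponses(conc, yc, B = 5, seed = 1)
  expect_true(all(dc == yc))
  # bootstrap mean of group means stays within 3 standard errors
  gm <- tapply(y, conc, mean)["1"]
  se <- sd(y[conc == 1]) / 2
  bootMeans <- colMeans(d1[conc == 1, ])
  expect_lt(abs(mean(bootMeans) - gm), 3 * se / sqrt(50))
  expect_error(bootstrapGeneResponses(c(0, 0, 1), c(1, 2, 3), B = 2),
               "fewer than 2")
})

test_that("exact linear data is recovered with goodness-of-fit ~ 1", {
  conc <- rep(c(0, 1, 5, 20, 100), each = 4)
  y <- 4 + 0.03 * conc
  f <- fitDoseResponse("linear", conc, y)
  expect_equal(f$pars[["a"]], 4, tolerance = 1e-6)
  expect_equal(f$pars[["b"]], 0.03, tolerance = 1e-6)
  expect_gt(f$gofP, 0.99)
})

test_that("nested models never lose likelihood and the chi-square picks", {
  conc <- rep(c(0, 1, 5, 20, 50, 100), each = 4)
  set.seed(8)
  yCurved <- 5 + 0.04 * conc - 2e-4 * conc^2 + rnorm(24, 0, 0.1)
  lin <- fitDoseResponse("linear", conc, yCurved)
  p2 <- fitDoseResponse("poly2", conc, yCurved)
  expect_gte(p2$loglik, lin$loglik)
  # strongly curved truth: poly2 replaces linear
  expect_equal(selectBestModel(list(linear = lin, poly2 = p2))$model,
               "poly2")
  # truly linear data keeps the simpler model
  yLin <- 5 + 0.03 * conc + rnorm(24, 0, 0.3)
  sel <- selectBestModel(fitAllModels(conc, yLin, c("linear", "poly2")))
  expect_equal(sel$model, "linear")
})

test_that("exp5 parameters are recovered from dense low-noise data", {
  conc <- rep(c(0, 0.5, 2, 10, 40, 100), each = 4)
  truth <- c(a = 6, b = 0.08, e = 1.4, p = 1.3)
  mu <- truth[["a"]] * (truth[["e"]] - (truth[["e"]] - 1) *
                          exp(-(truth[["b"]] * conc)^truth[["p"]]))
  set.seed(9)
  f <- fitDoseResponse("exp5", conc, mu + rnorm(24, 0, 0.02))
  for (nm in names(truth))
    expect_lt(abs(f$pars[[nm]] - truth[[nm]]) / truth[[nm]], 0.05)
})

test_that("model selection ties break by parsimony then suite order", {
  mk <- function(model, aic, npar) list(model = model, aic = aic,
                                        npar = npar, loglik = 0,
                                        converged = TRUE)
  fits <- list(power = mk("power", 10, 3), exp3 = mk("exp3", 10, 3),
               exp5 = mk("exp5", 12, 4))
  expect_equal(selectBestModel(fits)$model, "power") # order breaks the tie
  fits2 <- list(power = mk("power", 10, 3), exp5 = mk("exp5", 10, 4))
  expect_equal(selectBestModel(fits2)$model, "power") # fewer parameters
  single <- list(exp3 = mk("exp3", 99, 3))
  expect_equal(selectBestModel(single)$model, "exp3")
  none <- list(linear = list(model = "linear", converged = FALSE))
  expect_null(selectBestModel(none))
})

test_that("linear-model BMC equals the closed form sigma/|b|", {
  set.seed(10)
  for (i in 1:5) {
    conc <- rep(c(0, 2, 10, 50, 100), each = 4)
    y <- 6 + runif(1, 0.005, 0.05) * conc * sample(c(-1, 1), 1) +
      rnorm(20, 0, runif(1, 0.1, 0.6))
    f <- fitDoseResponse("linear", conc, y)
    pb <- profileBmc(f)
    expect_equal(pb$bmc, f$sigma / abs(f$pars[["b"]]), tolerance = 1e-6)
    expect_true(pb$bmcl <= pb$bmc && pb$bmc <= pb$bmcu)
  }
})

test_that("BMC and its bounds are equivariant under concentration scaling
           and invariant under value shifts", {
  conc <- rep(c(0, 1, 5, 20, 100), each = 4)
  set.seed(11)
  y <- curveValues(conc, effect = 1.5, ec50 = 15, sd = 0.2)
  f1 <- fitDoseResponse("exp5", conc, y)
  f2 <- fitDoseResponse("exp5", conc * 7, y)
  p1 <- profileBmc(f1)
  p2 <- profileBmc(f2)
  expect_equal(p2$bmc, 7 * p1$bmc, tolerance = 1e-6)
  expect_equal(p2$bmcl, 7 * p1$bmcl, tolerance = 1e-3)
  expect_equal(p2$bmcu, 7 * p1$bmcu, tolerance = 1e-3)
  fLin1 <- fitDoseResponse("linear", conc, y)
  fLin2 <- fitDoseResponse("linear", conc, y + 100)
  expect_equal(profileBmc(fLin1)$bmc, profileBmc(fLin2)$bmc,
               tolerance = 1e-9)
})

test_that("profile bounds widen monotonically with the confidence level", {
  conc <- rep(c(0, 2, 10, 50, 100), each = 4)
  set.seed(12)
  y <- 6 + 0.02 * conc + rnorm(20, 0, 0.4)
  f <- fitDoseResponse("linear", conc, y)
  p90 <- profileBmc(f, ciLevel = 0.90)
  p99 <- profileBmc(f, ciLevel = 0.99)
  expect_lte(p99$bmcl, p90$bmcl)
  expect_gte(p99$bmcu, p90$bmcu)
})

test_that("a curve that never reaches the benchmark yields no BMC", {
  conc <- rep(c(0, 1, 5, 20, 100), each = 4)
  set.seed(13)
  y <- rnorm(20, 8, 0.5)
  y <- y - coef(lm(y ~ conc))[2] * conc # exactly zero fitted slope
  f <- fitDoseResponse("linear", conc, y)
  expect_lt(abs(f$pars[["b"]]), 1e-10)
  pb <- profileBmc(f)
  expect_true(is.na(pb$bmc)) # a flat line never deviates by 1 SD
})

test_that("BMC filters use the documented boundary semantics", {
  cfg <- fitConfig(B = 4)
  fits <- data.frame(
    gene = "g1", draw = 1:5,
    model = c("linear", "linear", "linear", "linear", NA),
    bmc = c(100, 101, 50, 50, NA),
    bmcl = c(10, 10, 1, 10, NA),
    bmcu = c(100, 100, 40, 100, NA),
    gofP = c(0.5, 0.5, 0.5, 0.1, NA))
  dist <- filterBmcs(fits, topConc = 100, cfg)
  reasons <- fitTable(dist)$reason
  expect_equal(reasons,
               c("", "bmc_above_top", "ci_ratio", "poor_fit", "no_fit"))
  expect_equal(unname(survivalCounts(dist)), 1L)
})

test_that("constant bootstrap draws do not fabricate a response", {
  conc <- rep(c(0, 1, 10, 100), each = 4)
  out <- tpodmix:::.fitOneDraw(conc, rep(5, 16), fitConfig())
  expect_true(is.na(out$bmc))
})
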