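test_that("relative potency factors follow ECx_std / ECx_i", {
  expect_equal(relativePotency(10, 10), 1)
  expect_equal(relativePotency(10, 5), 2)
  expect_equal(relativePotency(3, 7) * relativePotency(7, 3), 1)
  expect_error(relativePotency(-1, 5), "positive")
  expect_error(relativePotency(5, 0), "positive")
})

test_that("concentration addition reproduces worked arithmetic", {
  pair <- mixtureDefinition("m", c("x", "y"))
  expect_equal(predictMixtureEcx(pair, c(x = 10, y = 10)), 10)
  expect_equal(predictMixtureEcx(pair, c(x = 10, y = 40)), 16)
  one <- mixtureDefinition("solo", "x")
  expect_equal(predictMixtureEcx(one, c(x = 7.5)), 7.5)
  expect_error(predictMixtureEcx(pair, c(x = 10)), "y")
})

test_that("the equimolar RPF shortcut matches the general form exactly", {
  rpf <- rpfTable(c(std = 40, other = 10), standard = "std")
  expect_equal(rpf$rpf[rpf$chemical == "other"], 4)
  mix <- mixtureDefinition("m", c("std", "other"))
  expect_equal(predictMixtureEcxEquimolar(mix, rpf), 16)
  expect_equal(predictMixtureEcxEquimolar(mix, rpf),
               predictMixtureEcx(mix, c(std = 40, other = 10)))
  # two components of equal potency yield the standard's ECx
  rpf1 <- rpfTable(c(std = 25, twin = 25), standard = "std")
  expect_equal(predictMixtureEcxEquimolar(
    mixtureDefinition("m2", c("std", "twin")), rpf1), 25)
  # permuting the component order changes nothing
  mixRev <- mixtureDefinition("m", c("other", "std"))
  expect_equal(predictMixtureEcxEquimolar(mixRev, rpf), 16)
  uneq <- mixtureDefinition("u", c("std", "other"), c(1, 2))
  expect_error(predictMixtureEcxEquimolar(uneq, rpf), "not equimolar")
})

test_that("concentration-addition identities hold over random instances", {
  set.seed(20)
  for (i in 1:300) {
    n <- sample(2:12, 1)
    ids <- sprintf("c%02d", seq_len(n))
    ecx <- setNames(10^runif(n, -1, 2), ids)
    # general mixture: CA bounds containment
    mix <- mixtureDefinition("m", ids, molarities = runif(n, 0.5, 5))
    pred <- predictMixtureEcx(mix, ecx)
    expect_gte(pred, min(ecx) - 1e-12)
    expect_lte(pred, max(ecx) + 1e-12)
    # equimolar: shortcut == general, for any choice of standard
    eq <- mixtureDefinition("e", ids)
    predEq <- predictMixtureEcx(eq, ecx)
    for (std in sample(ids, 2)) {
      rpf <- rpfTable(ecx, standard = std)
      expect_equal(predictMixtureEcxEquimolar(eq, rpf), predEq,
                   tolerance = 1e-12)
    }
    # a chemical mixed with itself keeps its own potency at any split
    self <- mixtureDefinition("s", c("a1", "a2"), runif(2, 0.1, 5))
    expect_equal(predictMixtureEcx(self, c(a1 = ecx[[1]], a2 = ecx[[1]])),
                 ecx[[1]], tolerance = 1e-12)
  }
})

test_that("paired-draw CI propagation matches direct recomputation", {
  mix <- mixtureDefinition("m", c("x", "y"))
  set.seed(21)
  draws <- list(x = 10^runif(500, 0, 2), y = 10^runif(500, 0, 2))
  pc <- propagatePredictionCi(mix, draws)
  oracle <- 1 / (0.5 / draws$x + 0.5 / draws$y)
  expect_equal(pc$draws, oracle)
  expect_equal(pc$median, median(oracle))
  expect_equal(c(pc$ci_lower, pc$ci_upper),
               unname(quantile(oracle, c(0.025, 0.975))))
  expect_gte(pc$median, min(median(draws$x), median(draws$y)) * 0.5)
  # zero-width component CIs give a zero-width prediction
  flat <- list(x = rep(10, 50), y = rep(40, 50))
  pcFlat <- propagatePredictionCi(mix, flat)
  expect_equal(pcFlat$ci_lower, pcFlat$ci_upper)
  expect_equal(pcFlat$median, 16)
  expect_error(propagatePredictionCi(mix, list(x = 1:5)), "y")
  expect_error(propagatePredictionCi(mix, list(x = 1:5, y = 1:4)),
               "aligned")
})

test_that("prediction comparison reports folds and CI overlap", {
  same <- comparePrediction(list(median = 5, ci_lower = 4, ci_upper = 6),
                            list(median = 5, ci_lower = 2, ci_upper = 9))
  expect_equal(same$fold_difference, 1)
  expect_true(same$ci_overlap)
  expect_equal(same$conservative_fold_difference, 1)
  apart <- comparePrediction(list(median = 1.5, ci_lower = 1, ci_upper = 2),
                             list(median = 6, ci_lower = 4, ci_upper = 8))
  expect_false(apart$ci_overlap)
  expect_equal(apart$fold_difference, 4)
  expect_equal(apart$conservative_fold_difference, 2) # 4 / 2
  near <- comparePrediction(list(median = 3, ci_lower = 1, ci_upper = 5),
                            list(median = 6, ci_lower = 4, ci_upper = 8))
  expect_true(near$ci_overlap)
  expect_equal(near$conservative_fold_difference, 1)
})

test_that("rank-matched prediction combines accumulation curves", {
  mkCurve <- function(v) data.frame(rank = seq_along(v), median = v,
                                    ci_lower = v, ci_upper = v,
                                    n_sims = 10)
  mix <- mixtureDefinition("m", c("x", "y"))
  same <- predictedAccumulationCurve(mix, list(x = mkCurve(c(1, 2, 3)),
                                               y = mkCurve(c(1, 2, 3))))
  expect_equal(same$predicted_bmc, c(1, 2, 3))
  two <- predictedAccumulationCurve(mix, list(x = mkCurve(c(1, 2, 3)),
                                              y = mkCurve(c(2, 4, 6))))
  expect_equal(two$predicted_bmc, c(4 / 3, 8 / 3, 4))
  expect_true(all(diff(two$predicted_bmc) >= 0))
  # ranks end where the shortest component curve ends
  short <- predictedAccumulationCurve(mix, list(x = mkCurve(c(1, 2, 3)),
                                                y = mkCurve(c(2, 4))))
  expect_equal(short$rank, 1:2)
})
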