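test_that("LDH fold changes subtract the blank mean before the ratio", {
  lum <- data.frame(sample = c("B1", "C1", "C2", "S1", "S2"),
                    rlu = c(10, 60, 60, 110, 60))
  ctl <- list(S1 = c("C1", "C2"), S2 = c("C1", "C2"))
  fc <- ldhFoldChanges(lum, "B1", ctl)
  expect_equal(fc$fold_change[fc$sample == "S1"], 2.0) # (110-10)/50
  expect_equal(fc$fold_change[fc$sample == "S2"], 1.0) # equals control mean
  # corrected control mean of zero is an error, not an infinity
  lum0 <- data.frame(sample = c("B1", "C1", "S1"), rlu = c(10, 10, 110))
  expect_error(ldhFoldChanges(lum0, "B1", list(S1 = "C1")), "nonpositive")
  expect_error(ldhFoldChanges(lum, character(), ctl), "blank")
  expect_error(ldhFoldChanges(lum, "B1", list(S9 = "C1")), "S9")
})

test_that("cytotoxicity flags cascade to all higher concentrations", {
  cc <- c(1, 5, 20, 100)
  expect_equal(flagCytotoxicConcentrations(cc, c(1.2, 1.5, 11, 0.4)),
               c(20, 100))
  expect_equal(flagCytotoxicConcentrations(cc, c(1.2, 1.5, 9.9, 0.4)),
               numeric(0))
  expect_equal(flagCytotoxicConcentrations(cc, c(12, 1, 1, 1)), cc)
  expect_equal(flagCytotoxicConcentrations(cc, c(1, 1, 1, 10)), 100)
  expect_equal(flagCytotoxicConcentrations(numeric(0), numeric(0)),
               numeric(0))
  expect_error(flagCytotoxicConcentrations(c(5, 1), c(1, 1)), "ascending")
})

test_that("read-depth and alignment gates use the documented boundaries", {
  fx <- .qcFixture()
  m <- fx$metrics
  m$mapped_reads[1] <- 99999L            # just below 10% of 1M target
  m$mapped_reads[2] <- 100000L           # exactly at the cutoff: retained
  m$fraction_mapped[3] <- 0.399
  m$fraction_mapped[4] <- 0.40           # boundary: retained
  rep <- sampleQualityFilter(m, fx$counts, fx$design)
  s <- sampleStatus(rep)
  expect_match(s$reasons[s$sample == "s01"], "low_reads")
  expect_false(grepl("low_reads", s$reasons[s$sample == "s02"]))
  expect_match(s$reasons[s$sample == "s03"], "low_alignment")
  expect_false(grepl("low_alignment", s$reasons[s$sample == "s04"]))
})

test_that("Tukey fence gate matches a brute-force quartile oracle", {
  for (seed in 1:4) {
    fx <- .qcFixture(n = 16, seed = seed)
    m <- fx$metrics
    m$gini[1] <- 0.99 # plant an extreme signal-concentration value
    rep <- sampleQualityFilter(m, fx$counts, fx$design)
    s <- sampleStatus(rep)
    for (col in c("n_probes_min5", "n_probes_80pct", "gini")) {
      q <- quantile(m[[col]], c(0.25, 0.75), type = 7)
      lo <- q[1] - 3 * (q[2] - q[1])
      hi <- q[2] + 3 * (q[2] - q[1])
      code <- c(n_probes_min5 = "fence_outlier_nprobes5",
                n_probes_80pct = "fence_outlier_nprobes80",
                gini = "fence_outlier_gini")[[col]]
      flagged <- sort(s$sample[grepl(code, s$reasons)])
      oracle <- sort(m$sample[m[[col]] < lo | m[[col]] > hi])
      expect_identical(flagged, oracle)
    }
    expect_match(s$reasons[s$sample == "s01"], "fence_outlier_gini")
  }
})

test_that("identical expression columns yield no singletons or outliers", {
  fx <- .qcFixture()
  counts <- matrix(rep(fx$counts[, 1], ncol(fx$counts)), nrow(fx$counts),
                   dimnames = dimnames(fx$counts))
  metrics <- tpodmix:::.computeQcMetrics(counts, rep(0.6, ncol(counts)))
  rep <- sampleQualityFilter(metrics, counts, fx$design)
  expect_true(all(sampleStatus(rep)$status == "retained"))
})

test_that("a divergent sample is excluded as a cluster singleton", {
  fx <- .qcFixture(n = 10, seed = 3)
  fx$counts[, 1] <- rev(fx$counts[, 1]) + # destroy rank correlation
    sample(0:50, nrow(fx$counts), replace = TRUE)
  rep <- sampleQualityFilter(fx$metrics, fx$counts, fx$design)
  s <- sampleStatus(rep)
  expect_match(s$reasons[s$sample == "s01"], "cluster_singleton")
})

test_that("minimum replicate rule drops exposures and marks survivors", {
  fx <- .qcFixture()
  rep0 <- sampleQualityFilter(fx$metrics, fx$counts, fx$design,
                              cytotoxic = c("s05", "s07", "s08"))
  rep <- enforceMinReplicates(rep0, fx$design)
  ex <- exposureStatus(rep)
  # concentration 1 uM keeps one of two samples -> dropped, survivor marked
  expect_false(ex$retained[ex$concentration_uM == 1])
  expect_equal(ex$n_retained[ex$concentration_uM == 1], 1L)
  s <- sampleStatus(rep)
  expect_match(s$reasons[s$sample == "s06"], "insufficient_replicates")
  # concentration 2 uM lost both samples -> dropped with nobody to mark
  expect_false(ex$retained[ex$concentration_uM == 2])
  expect_equal(ex$n_retained[ex$concentration_uM == 2], 0L)
  # exactly 2 retained replicates is enough
  expect_true(all(ex$retained[ex$concentration_uM %in% c(5, 10)]))
})

test_that("the full QC stage is deterministic and idempotent", {
  d <- tinyDesign()
  st <- simulateStudy(d, nGenes = 60, fracResponsive = 0.1, seed = 12)
  r1 <- runQc(st)
  r2 <- runQc(st)
  expect_identical(sampleStatus(r1), sampleStatus(r2))
  expect_identical(exposureStatus(r1), exposureStatus(r2))
})
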