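test_that("LS statistic worked examples and edge handling", {
  expect_equal(lsStatistic(c(0.1, 0.01)), 3.453878, tolerance = 1e-6)
  expect_equal(lsStatistic(rep(1, 4)), 0)
  expect_equal(lsStatistic(0.05), 2.995732, tolerance = 1e-6)
  expect_warning(flo <- lsStatistic(c(0, 0.5)), "floored")
  expect_true(is.finite(flo))
  expect_error(lsStatistic(1.2), "\\[0, 1\\]")
})

test_that("KS statistic worked examples and brute-force equivalence", {
  expect_equal(ksStatistic(c(0.01, 0.2, 0.5)), 0.5)
  expect_equal(ksStatistic(1), 0)
  set.seed(5)
  for (rep in 1:5) {
    p <- runif(7)
    ps <- sort(p)
    oracle <- max(vapply(1:7, function(i) i / 7 - ps[i], numeric(1)))
    expect_equal(ksStatistic(p), oracle)
    expect_equal(ksStatistic(rev(p)), ksStatistic(p))  # order invariance
  }
})

test_that("adding a p = 1 member lowers LS and bounds KS correctly", {
  p <- c(0.01, 0.2, 0.4)
  expect_lt(lsStatistic(c(p, 1)), lsStatistic(p))
  expect_equal(lsStatistic(c(rep(1, 3), 1)), 0)
  # KS of the augmented set equals its own recomputation (no shortcuts)
  expect_equal(ksStatistic(c(p, 1)),
    max(seq_len(4) / 4 - sort(c(p, 1))))
})

test_that("random-set empirical p follows the add-one rule", {
  set.seed(9)
  allP <- runif(200)
  k <- 5
  topSet <- sort(allP)[seq_len(k)]
  obs <- lsStatistic(topSet)
  p <- randomSetPvalue(obs, lsStatistic, k, allP, nNull = 100, seed = 1)
  expect_equal(p, 1 / 101)
  expect_error(randomSetPvalue(1, lsStatistic, 300, allP), "population")
  expect_error(randomSetPvalue(1, lsStatistic, 5, allP, nNull = 50),
               ">= 100")
  # monotone non-increasing in the observed statistic, never zero
  pLow <- randomSetPvalue(obs / 10, lsStatistic, k, allP, nNull = 100,
    seed = 1)
  expect_gte(pLow, p)
  expect_gt(p, 0)
})

test_that("random decoy sets yield approximately uniform empirical p", {
  set.seed(15)
  allP <- runif(500)
  reps <- vapply(1:150, function(i) {
    members <- sample(allP, 10)
    randomSetPvalue(lsStatistic(members), lsStatistic, 10, allP,
      nNull = 200)
  }, numeric(1))
  ks <- suppressWarnings(ks.test(reps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("maxmean statistic worked examples", {
  mm <- maxmeanStat(c(2, -1, -3))
  expect_equal(mm$stat, 4 / 3, tolerance = 1e-6)
  expect_equal(mm$direction, "down")
  mm2 <- maxmeanStat(rep(2.5, 6))
  expect_equal(mm2$stat, 2.5)
  expect_equal(mm2$direction, "up")
})

test_that("maxmean permutation test flags a planted coordinate set", {
  p <- tnfPanels()
  eff <- data.frame(gene = p$gene[p$panel == "death"],
    condition = "FPOS_GML", log2fc = 1)
  sim <- simulateDataset(simulationConfig(nGenes = 800, nDecoySets = 2,
    effects = eff), seed = 23)
  spec <- ComparisonSpec("FPOS_GML", "CTRL")
  mm <- maxmeanTest(sim$se, spec, geneSets(sim$geneSets)$TNF_DEATH,
    nPerm = 200, seed = 1)
  expect_lt(mm$p, 0.05)
  expect_equal(mm$direction, "up")
  mmDecoy <- maxmeanTest(sim$se, spec,
    geneSets(sim$geneSets)$DECOY_001, nPerm = 200, seed = 1)
  expect_gt(mmDecoy$p, 0.05)
})

test_that("degenerate permutation spaces are refused with the count", {
  mat <- matrix(rnorm(40, 8), 10, 4,
    dimnames = list(paste0("G", 1:10), paste0("s", 1:4)))
  se <- makeTinyExperiment(mat, rep(c("CTRL", "FPOS_GML"), each = 2))
  expect_error(
    maxmeanTest(se, ComparisonSpec("FPOS_GML", "CTRL"), c("G1", "G2")),
    "6 distinct")
})

test_that("consensus rule counts strict exceedances of alpha", {
  expect_true(consensusCall(0.04, 0.2, 0.01)$consensus)
  expect_equal(consensusCall(0.04, 0.2, 0.01)$nSignificant, 2)
  expect_false(consensusCall(0.04, 0.2, 0.6)$consensus)
  # boundary: p exactly alpha does not count
  expect_equal(consensusCall(0.05, 0.05, 0.05)$nSignificant, 0)
  expect_false(consensusCall(0.05, 0.05, 0.05)$consensus)
})

test_that("gene-set analysis scores planted sets and skips tiny ones", {
  p <- tnfPanels()
  eff <- data.frame(gene = p$gene[p$panel == "death"],
    condition = "FPOS_GML", log2fc = 1)
  sim <- simulateDataset(simulationConfig(nGenes = 600, nDecoySets = 4,
    effects = eff), seed = 29)
  gsc <- GeneSetCollection(c(geneSets(sim$geneSets),
    list(TINY = c("G00001", "NOT_PRESENT_1", "NOT_PRESENT_2"))))
  res <- suppressMessages(geneSetAnalysis(sim$se,
    ComparisonSpec("FPOS_GML", "CTRL"), gsc,
    nNull = 500, nPerm = 150, seed = 3))
  expect_true("TINY" %in% attr(res, "skipped"))
  death <- res[res$set == "TNF_DEATH", ]
  expect_true(death$consensus)
  expect_equal(death$maxmeanDirection, "up")
  expect_true(all(res$lsP > 0 & res$lsP <= 1))
  expect_true(all(res$nSignificant ==
    (res$lsP < 0.05) + (res$ksP < 0.05) + (res$maxmeanP < 0.05)))
})

test_that("the 2-of-3 consensus is conservative under a global null", {
  sim <- simulateDataset(simulationConfig(nGenes = 500, nDecoySets = 40),
    seed = 37)
  res <- suppressMessages(geneSetAnalysis(sim$se,
    ComparisonSpec("FNEG_NAGM", "CTRL"), sim$geneSets,
    nNull = 300, nPerm = 100, seed = 5))
  decoys <- res[startsWith(res$set, "DECOY"), ]
  consRate <- mean(decoys$consensus)
  singleRates <- c(mean(decoys$lsP < 0.05), mean(decoys$ksP < 0.05),
                   mean(decoys$maxmeanP < 0.05))
  expect_lte(consRate, min(singleRates) + 1e-12)
})
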