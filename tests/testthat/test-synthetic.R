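test_that("gene variance sampler is reproducible and respects the prior", {
  v1 <- sampleGeneVariances(5, 3, 1, seed = 11)
  v2 <- sampleGeneVariances(5, 3, 1, seed = 11)
  expect_identical(v1, v2)
  expect_true(all(v1 > 0))
  expect_error(sampleGeneVariances(5, -1, 1), "positive")

  # degenerate-prior limit: huge shape with prior mean precision 1
  v <- sampleGeneVariances(2000, 1e6, 1e-6, seed = 1)
  expect_lt(var(v), 1e-4)
  expect_equal(mean(v), 1, tolerance = 0.01)
})

test_that("pooled 10-vs-10 variances follow the implied F distribution", {
  set.seed(202)
  nG <- 20000; a <- 3; b <- 1
  sigma2 <- sampleGeneVariances(nG, a, b)
  x <- matrix(rnorm(nG * 20), nG, 20) * sqrt(sigma2)
  mA <- rowMeans(x[, 1:10]); mB <- rowMeans(x[, 11:20])
  s2 <- (rowSums((x[, 1:10] - mA)^2) + rowSums((x[, 11:20] - mB)^2)) / 18
  ks <- suppressWarnings(ks.test(s2 * a * b, pf, df1 = 18, df2 = 2 * a))
  expect_gt(ks$p.value, 0.01)
})

test_that("default design yields 50 arrays, 10 per group, deterministically", {
  cfg <- simulationConfig(nGenes = 80)
  sim <- simulateDataset(cfg, seed = 9)
  expect_equal(ncol(sim$se), 50L)
  expect_true(all(table(sampleGroups(sim$se)) == 10L))
  # each MS case contributes one GML and one NAGM array
  ci <- caseIds(sim$se)
  ms <- grepl("^F", ci)
  expect_true(all(table(ci[ms]) == 2L))

  sim2 <- simulateDataset(cfg, seed = 9)
  expect_identical(SummarizedExperiment::assay(sim$se),
                   SummarizedExperiment::assay(sim2$se))
  expect_identical(geneSets(sim$geneSets), geneSets(sim2$geneSets))
})

test_that("empty effect table means empty truth and null group differences", {
  sim <- simulateDataset(simulationConfig(nGenes = 3000), seed = 2)
  expect_equal(nrow(sim$truth$effects), 0L)
  expect_false(any(sim$truth$sets$enriched))
  st <- rvmTTest(sim$se, ComparisonSpec("FNEG_NAGM", "CTRL"))
  # group means differ only by noise: the study-threshold DEG rate is
  # a small fraction, and typical log2 differences are small
  expect_lt(mean(st$significant), 0.02)
  expect_lt(median(abs(st$log2fc)), 0.3)
})

test_that("planted effects are realized at the configured size", {
  eff <- data.frame(gene = "G00042", condition = "FPOS_GML", log2fc = 1)
  cfg <- simulationConfig(nGenes = 500, effects = eff)
  sim <- simulateDataset(cfg, seed = 31)
  x <- SummarizedExperiment::assay(sim$se)
  grp <- as.character(sampleGroups(sim$se))
  xa <- x["G00042", grp == "FPOS_GML"]
  xb <- x["G00042", grp == "CTRL"]
  realized <- mean(xa) - mean(xb)
  s2 <- (sum((xa - mean(xa))^2) + sum((xb - mean(xb))^2)) / 18
  expect_lt(abs(realized - 1), 3 * sqrt(s2 * (1 / 10 + 1 / 10)))
  expect_identical(sim$truth$effects, eff)
})

test_that("effect tables referencing unknown genes or conditions error", {
  bad1 <- simulationConfig(nGenes = 100,
    effects = data.frame(gene = "NOPE", condition = "FPOS_GML",
                         log2fc = 1))
  expect_error(simulateDataset(bad1, seed = 1), "unknown gene")
  bad2 <- simulationConfig(nGenes = 100,
    effects = data.frame(gene = "G00010", condition = "CTRL",
                         log2fc = 1))
  expect_error(simulateDataset(bad2, seed = 1), "unknown condition")
})

test_that("planted truth appears in the set-level truth and nowhere else", {
  p <- tnfPanels()
  eff <- data.frame(gene = p$gene[p$panel == "death"],
    condition = "FPOS_GML", log2fc = 0.8)
  sim <- simulateDataset(simulationConfig(nGenes = 300, nDecoySets = 10,
    effects = eff), seed = 5)
  tr <- sim$truth$sets
  expect_true(all(tr$enriched[tr$set == "TNF_DEATH" &
                              tr$condition == "FPOS_GML"]))
  expect_false(any(tr$enriched[tr$set != "TNF_DEATH"]))
  expect_false(any(tr$enriched[tr$condition != "FPOS_GML"]))
})

test_that("with no planted effects the two-sample t-test is calibrated", {
  sim <- simulateDataset(simulationConfig(nGenes = 8000), seed = 77)
  x <- SummarizedExperiment::assay(sim$se)
  grp <- as.character(sampleGroups(sim$se))
  xa <- x[, grp == "FNEG_GML"]; xb <- x[, grp == "CTRL"]
  mA <- rowMeans(xa); mB <- rowMeans(xb)
  s2 <- (rowSums((xa - mA)^2) + rowSums((xb - mB)^2)) / 18
  tt <- (mA - mB) / sqrt(s2 * 0.2)
  p <- 2 * pt(-abs(tt), 18)
  for (alpha in c(0.05, 0.01)) {
    band <- 2.576 * sqrt(alpha * (1 - alpha) / 8000)
    expect_lt(abs(mean(p < alpha) - alpha), band)
  }
})

test_that("qPCR generator honours the log2 identity and recovers ratios", {
  t1 <- simulateQpcrTable(
    data.frame(target = "T", group = "FPOS_GML", ratio = 1),
    noiseSd = 0, sampleSd = 0.2, seed = 1)
  dct <- t1$ct_target - t1$ct_reference
  expect_equal(var(dct), 0)

  t2 <- simulateQpcrTable(
    data.frame(target = "T", group = "FPOS_GML", ratio = 2),
    noiseSd = 0, seed = 1)
  d2 <- t2$ct_target - t2$ct_reference
  expect_equal(mean(d2[t2$group == "FPOS_GML"]) -
               mean(d2[t2$group == "CTRL"]), -1)

  expect_error(simulateQpcrTable(
    data.frame(target = "T", group = "CTRL", ratio = -2)), "positive")

  # Monte-Carlo calibration: ratio 4.5 recovered within 25% in >= 95/100
  hits <- 0L
  for (s in 1:100) {
    tab <- simulateQpcrTable(
      data.frame(target = "T", group = "FPOS_GML", ratio = 4.5),
      noiseSd = 0.3, seed = s)
    fc <- qpcrFoldChange(tab, "T", "FPOS_GML", "CTRL")
    if (abs(fc - 4.5) / 4.5 < 0.25) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})
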