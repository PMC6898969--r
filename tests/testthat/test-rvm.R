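test_that("variance hyperparameters are recovered from model data", {
  set.seed(41)
  v <- sampleGeneVariances(20000, 3, 1)
  s2 <- v * rchisq(20000, 18) / 18
  fit <- fitRVM(s2, 18)
  expect_true(fit@converged)
  expect_gt(rvmShape(fit), 2.5); expect_lt(rvmShape(fit), 3.6)
  expect_gt(rvmScale(fit), 0.85); expect_lt(rvmScale(fit), 1.18)
  expect_equal(moderatedDf(fit), 18 + 2 * rvmShape(fit))

  refit <- fitRVM(s2, 18)
  expect_equal(rvmShape(refit), rvmShape(fit), tolerance = 1e-8)
  expect_equal(rvmScale(refit), rvmScale(fit), tolerance = 1e-8)
})

test_that("fit preconditions and degenerate variance handling", {
  expect_error(fitRVM(runif(100), 0), "degrees of freedom")
  expect_error(suppressWarnings(fitRVM(c(1, -1, 2), 5)), "non-negative")
  expect_error(suppressWarnings(fitRVM(rep(2, 100), 10)), "degenerate")
  capped <- suppressWarnings(fitRVM(rep(2, 100), 10, cap = TRUE))
  expect_equal(rvmShape(capped), 1e6)
  # capped prior mean variance equals the common value
  expect_equal(1 / (capped@a * capped@b), 2)
  set.seed(2)
  few <- sampleGeneVariances(20, 3, 1) * rchisq(20, 18) / 18
  expect_warning(fitRVM(few, 18), "fewer than 50")
})

test_that("zero variances are floored, not fatal", {
  set.seed(8)
  s2 <- c(rep(0, 5), rgamma(500, 3, 3))
  fit <- fitRVM(s2, 10)
  expect_true(rvmShape(fit) > 0 && rvmScale(fit) > 0)
})

test_that("a gene with equal group means gets t = 0 and p = 1", {
  set.seed(3)
  gsd <- sqrt(sampleGeneVariances(60, 3, 1))  # heterogeneous variances
  mat <- matrix(rnorm(60 * 8), 60, 8) * gsd + 8
  dimnames(mat) <- list(sprintf("G%02d", 1:60), paste0("s", 1:8))
  mat[1, ] <- c(1, 2, 3, 4, 4, 3, 2, 1) + 8  # equal means, nonzero var
  se <- makeTinyExperiment(mat, rep(c("CTRL", "FPOS_GML"), each = 4))
  st <- rvmTTest(se, ComparisonSpec("FPOS_GML", "CTRL"))
  expect_equal(st$tMod[1], 0)
  expect_equal(st$p[1], 1)
})

test_that("capped fit with equal variances reproduces the pooled t-test", {
  # large residual df so the moderated reference distribution converges
  nG <- 80; nPer <- 30
  set.seed(12)
  base <- rnorm(2 * nPer)
  base <- (base - mean(base)) / sd(base)
  shift <- rnorm(nG, 0, 0.3)
  mat <- t(vapply(seq_len(nG), function(g) 8 + shift[g] + base,
    numeric(2 * nPer)))
  dimnames(mat) <- list(sprintf("G%02d", 1:nG),
    paste0("s", seq_len(2 * nPer)))
  se <- makeTinyExperiment(mat, rep(c("CTRL", "FPOS_GML"), each = nPer))
  d <- 2 * nPer - 2
  grp <- rep(c("CTRL", "FPOS_GML"), each = nPer)
  xa <- mat[, grp == "FPOS_GML"]; xb <- mat[, grp == "CTRL"]
  mA <- rowMeans(xa); mB <- rowMeans(xb)
  s2 <- (rowSums((xa - mA)^2) + rowSums((xb - mB)^2)) / d
  fit <- suppressWarnings(fitRVM(s2, d, cap = TRUE))
  st <- rvmTTest(se, ComparisonSpec("FPOS_GML", "CTRL"), fit = fit)
  tPooled <- (mA - mB) / sqrt(s2 * (2 / nPer))
  pPooled <- 2 * pt(-abs(tPooled), d)
  expect_equal(st$shrunkS2, s2, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(st$tMod, tPooled, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(st$p, pPooled, tolerance = 0.01, ignore_attr = TRUE)
})

test_that("moderated test is symmetric under group swap", {
  sim <- simulateDataset(simulationConfig(nGenes = 400), seed = 6)
  ab <- rvmTTest(sim$se, ComparisonSpec("FPOS_GML", "CTRL"))
  ba <- rvmTTest(sim$se, ComparisonSpec("CTRL", "FPOS_GML"))
  expect_equal(ba$log2fc, -ab$log2fc)
  expect_equal(ba$tMod, -ab$tMod)
  expect_equal(ba$p, ab$p)
  expect_equal(abs(ba$fc), abs(ab$fc))
})

test_that("fold-change sign convention and DEG calling thresholds", {
  st <- data.frame(gene = c("g1", "g2", "g3", "g4"),
    log2fc = c(0.5, 0.7, -0.7, -0.2),
    fc = c(2^0.5, 2^0.7, -2^0.7, -2^0.2),
    p = c(0.005, 0.005, 0.005, 0.5))
  attr(st, "comparison") <- "FPOS_GML_vs_CTRL"
  degs <- callDegs(st, ComparisonSpec("FPOS_GML", "CTRL"))
  expect_false("g1" %in% degGenes(degs))   # fc 1.41 below 1.5
  expect_true("g2" %in% upGenes(degs))
  expect_true("g3" %in% downGenes(degs))
  expect_false("g4" %in% degGenes(degs))
  expect_equal(length(degs), 2L)
})

test_that("DEG counts partition and are monotone in the thresholds", {
  sim <- simulateDataset(simulationConfig(nGenes = 1000,
    effects = data.frame(gene = sprintf("G%05d", 1:50),
      condition = "FNEG_GML", log2fc = rep(c(1.2, -1.2), 25))),
    seed = 13)
  st <- rvmTTest(sim$se, ComparisonSpec("FNEG_GML", "CTRL"))
  degs <- callDegs(st)
  expect_equal(length(degs), sum(st$significant))
  expect_equal(length(intersect(upGenes(degs), downGenes(degs))), 0L)
  counts <- sapply(c(0.05, 0.01, 0.001), function(pthr)
    sapply(c(1.5, 2, 3), function(fcthr)
      length(callDegs(st, ComparisonSpec("FNEG_GML", "CTRL",
        pthr, fcthr)))))
  # rows: increasing fc threshold; cols: decreasing p threshold
  expect_true(all(diff(counts) <= 0))
  expect_true(all(apply(counts, 1, diff) <= 0))
})

test_that("sensitivity at the study thresholds beats the stricter scan cell", {
  planted <- sprintf("G%05d", 1:200)
  sim <- simulateDataset(simulationConfig(nGenes = 2000,
    effects = data.frame(gene = planted, condition = "FPOS_GML",
      log2fc = rep(c(1.5, -1.5), 100))), seed = 17)
  st <- rvmTTest(sim$se, ComparisonSpec("FPOS_GML", "CTRL"))
  sens <- function(fcthr) {
    hits <- degGenes(callDegs(st, ComparisonSpec("FPOS_GML", "CTRL",
      0.01, fcthr)))
    mean(planted %in% hits)
  }
  expect_gt(sens(1.5), 0.8)
  expect_gt(sens(1.5), sens(2))
})

test_that("groups must exist with at least two samples", {
  sim <- simulateDataset(simulationConfig(nGenes = 60), seed = 1)
  expect_error(rvmTTest(sim$se[, 1:10],
    ComparisonSpec("FPOS_GML", "CTRL")), "FPOS_GML")
})

test_that("overlap table matches the brute-force membership tally", {
  expect_equal(
    overlapAccounting(list(A = c("g1", "g2", "g3"),
                           B = c("g2", "g3", "g4")))$count,
    c(1L, 1L, 2L))

  same <- replicate(4, c("x", "y"), simplify = FALSE)
  names(same) <- LETTERS[1:4]
  tab <- overlapAccounting(same)
  expect_equal(tab$count[nrow(tab)], 2L)
  expect_equal(sum(tab$count), 2L)

  set.seed(99)
  for (rep in 1:5) {
    sets <- lapply(1:3, function(i)
      sample(sprintf("g%02d", 1:30), sample(5:20, 1)))
    names(sets) <- paste0("S", 1:3)
    tab <- overlapAccounting(sets)
    expect_equal(sum(tab$count), length(unique(unlist(sets))))
    oracle <- tallyOverlap(sets)
    for (i in seq_len(nrow(tab))) {
      key <- paste(as.integer(unlist(tab[i, 1:3])), collapse = "")
      expected <- if (key %in% names(oracle)) oracle[[key]] else 0L
      expect_equal(tab$count[i], as.integer(expected))
    }
  }
})
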