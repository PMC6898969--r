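#' LS statistic of a gene set
#'
#' The mean negative natural log of the member genes' p-values:
#' `ls = mean(-log(p))`. Large when the set is enriched for small
#' p-values. Zero p-values are floored at the smallest representable
#' positive double, with a warning.
#'
#' @param p Numeric vector of member p-values in `[0, 1]`.
#' @return The LS statistic (non-negative scalar).
#' @export
#' @examples
#' lsStatistic(c(0.1, 0.01))  # 3.453878
lsStatistic <- function(p) {
    if (!length(p)) stop("need at least one p-value")
    if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
    if (any(p == 0)) {
        warning("zero p-values floored at the machine minimum")
        p[p == 0] <- .Machine$double.xmin
    }
    mean(-log(p))
}

#' KS statistic of a gene set
#'
#' With the member p-values sorted as `p_(1) <= ... <= p_(k)`, the
#' statistic is `max_i (i/k - p_(i))`: the maximal positive departure of
#' the set's p-values below the uniform reference line.
#'
#' @param p Numeric vector of member p-values.
#' @return The KS statistic.
#' @export
#' @examples
#' ksStatistic(c(0.01, 0.2, 0.5))  # 0.5
ksStatistic <- function(p) {
    if (!length(p)) stop("need at least one p-value")
    ps <- sort(p)
    k <- length(ps)
    max(seq_len(k) / k - ps)
}

#' Empirical p-value of a set statistic under the random-set null
#'
#' Compares an observed set statistic with the statistics of `nNull`
#' random gene sets of the same size drawn uniformly without replacement
#' from all genes, using the add-one rule:
#' `p = (1 + #\{null >= observed\}) / (nNull + 1)`, so the attainable
#' minimum is `1/(nNull + 1)` and zero never occurs.
#'
#' @param observed Observed statistic of the real set.
#' @param statFn Statistic function mapping member p-values to a scalar
#'   (e.g. [lsStatistic()] or [ksStatistic()]).
#' @param k Set size (number of resolved members).
#' @param allP P-values of all genes in the experiment.
#' @param nNull Number of random sets (default 10000, minimum 100).
#' @param seed Optional integer seed.
#' @return Empirical p-value in `(0, 1]`.
#' @export
randomSetPvalue <- function(observed, statFn, k, allP, nNull = 10000,
                            seed = NULL) {
    if (k > length(allP))
        stop("set size exceeds the gene population")
    if (nNull < 100) stop("nNull must be >= 100")
    if (!is.null(seed)) set.seed(seed)
    nullStats <- vapply(seq_len(nNull), function(i)
        statFn(allP[sample.int(length(allP), k)]), numeric(1))
    (1 + sum(nullStats >= observed)) / (nNull + 1)
}

#' Maxmean score of a vector of gene scores
#'
#' The larger of the mean positive part and the mean negative part of the
#' member gene scores; detects coordinated one-sided shifts. Direction is
#' the side attaining the maximum (`"up"` on ties).
#'
#' @param z Numeric member gene scores (moderated t statistics).
#' @return List with `stat` and `direction` (`"up"` or `"down"`).
#' @export
#' @examples
#' maxmeanStat(c(2, -1, -3))  # stat 1.333, direction down
maxmeanStat <- function(z) {
    if (!length(z)) stop("need at least one gene score")
    posMean <- mean(pmax(z, 0))
    negMean <- mean(pmax(-z, 0))
    if (posMean >= negMean)
        list(stat = posMean, direction = "up")
    else
        list(stat = negMean, direction = "down")
}

.permZ <- function(x, isA, nA, nB, fit) {
    # moderated t for one (possibly permuted) labeling; frozen fit
    xa <- x[, isA, drop = FALSE]
    xb <- x[, !isA, drop = FALSE]
    mA <- rowMeans(xa); mB <- rowMeans(xb)
    d <- nA + nB - 2
    s2 <- (rowSums((xa - mA)^2) + rowSums((xb - mB)^2)) / d
    a <- fit@a; b <- fit@b
    shrunk <- (d * s2 + 2 / b) / (d + 2 * a)
    (mA - mB) / sqrt(shrunk * (1 / nA + 1 / nB))
}

.standardize <- function(z) (z - mean(z)) / sd(z)

#' Maxmean gene-set test with sample-label permutation null
#'
#' Per-gene scores are the moderated t statistics of the comparison; the
#' set score is the maxmean statistic. The null distribution comes from
#' permuting sample labels (uniformly over assignments preserving the two
#' group sizes) with the variance-model hyperparameters frozen at the
#' observed fit. With `restandardize = TRUE` (default) the per-gene scores
#' of the observed data and of every permutation are centered and scaled
#' by their own across-gene mean and SD before the set score is taken,
#' protecting the test against genome-wide shifts. Empirical p uses the
#' add-one rule.
#'
#' @param se A `SummarizedExperiment`.
#' @param spec A [ComparisonSpec-class].
#' @param geneSet Character vector of member gene ids (must resolve in
#'   `rownames(se)`).
#' @param nPerm Number of label permutations (default 1000).
#' @param seed Optional integer seed.
#' @param restandardize Center/scale gene scores per labeling (default
#'   `TRUE`).
#' @return List with `stat`, `direction`, and empirical `p`.
#' @export
maxmeanTest <- function(se, spec, geneSet, nPerm = 1000, seed = NULL,
                        restandardize = TRUE) {
    stopifnot(is(spec, "ComparisonSpec"))
    members <- intersect(geneSet, rownames(se))
    if (!length(members)) stop("no gene-set member resolves in the matrix")
    ia <- .groupIdx(se, spec@groupA)
    ib <- .groupIdx(se, spec@groupB)
    nA <- length(ia); nB <- length(ib)
    nDistinct <- choose(nA + nB, nA)
    if (nDistinct < 20)
        stop("degenerate permutation space: only ", nDistinct,
             " distinct label assignments")
    x <- SummarizedExperiment::assay(se, "log2")[, c(ia, ib), drop = FALSE]
    obsLab <- rep(c(TRUE, FALSE), c(nA, nB))
    stats0 <- rvmTTest(se, spec)
    fit <- attr(stats0, "fit")
    midx <- match(members, stats0$gene)
    z <- stats0$tMod
    zObs <- if (restandardize) .standardize(z) else z
    obs <- maxmeanStat(zObs[midx])
    if (!is.null(seed)) set.seed(seed)
    hits <- 0L
    for (i in seq_len(nPerm)) {
        lab <- sample(obsLab)
        zp <- .permZ(x, lab, nA, nB, fit)
        if (restandardize) zp <- .standardize(zp)
        if (maxmeanStat(zp[midx])$stat >= obs$stat) hits <- hits + 1L
    }
    list(stat = obs$stat, direction = obs$direction,
         p = (1 + hits) / (nPerm + 1))
}

#' 2-of-3 consensus call over the three gene-set tests
#'
#' Counts how many of the LS, KS and maxmean p-values fall strictly below
#' `alpha`; the set is a consensus hit when at least two do.
#'
#' @param lsP,ksP,maxmeanP The three p-values.
#' @param alpha Per-test significance threshold (default 0.05, strict
#'   inequality).
#' @return List with `nSignificant` and logical `consensus`.
#' @export
#' @examples
#' consensusCall(0.04, 0.2, 0.01)  # 2 significant, consensus TRUE
consensusCall <- function(lsP, ksP, maxmeanP, alpha = 0.05) {
    p <- c(lsP, ksP, maxmeanP)
    stopifnot(length(p) == 3L, all(p >= 0 & p <= 1))
    n <- sum(p < alpha)
    list(nSignificant = n, consensus = n >= 2L)
}

#' Gene-set analysis with LS, KS, maxmean and the consensus rule
#'
#' Scores every resolvable gene set of a collection: LS and KS statistics
#' against a random-set null of matched size, the maxmean statistic
#' against a shared sample-label permutation null (one set of label
#' permutations reused across sets), and the 2-of-3 consensus verdict at
#' `alpha`.
#'
#' @param se A `SummarizedExperiment`.
#' @param spec A [ComparisonSpec-class].
#' @param gsc A [GeneSetCollection-class].
#' @param alpha Per-test significance threshold (default 0.05).
#' @param nNull Random sets per LS/KS null (default 10000).
#' @param nPerm Label permutations for maxmean (default 1000).
#' @param minSetSize Minimum resolved set size (default 3); smaller sets
#'   are skipped and reported in attribute `"skipped"`.
#' @param seed Optional master seed.
#' @param restandardize See [maxmeanTest()].
#' @return A `data.frame` with one row per scored set: `set`, `k`,
#'   `lsStat`, `lsP`, `ksStat`, `ksP`, `maxmeanStat`, `maxmeanDirection`,
#'   `maxmeanP`, `nSignificant`, `consensus`.
#' @export
#' @examples
#' sim <- simulateDataset(simulationConfig(nGenes = 300, nDecoySets = 5),
#'     seed = 1)
#' res <- geneSetAnalysis(sim$se, ComparisonSpec("FPOS_GML", "CTRL"),
#'     sim$geneSets, nNull = 200, nPerm = 100, seed = 1)
#' head(res)
geneSetAnalysis <- function(se, spec, gsc, alpha = 0.05, nNull = 10000,
                            nPerm = 1000, minSetSize = 3L, seed = NULL,
                            restandardize = TRUE) {
    stopifnot(is(gsc, "GeneSetCollection"))
    res <- resolveGeneSets(gsc, rownames(se), minSetSize)
    sets <- res$resolved
    if (!length(sets)) stop("no gene set resolves at minSetSize")
    stats0 <- rvmTTest(se, spec)
    fit <- attr(stats0, "fit")
    allP <- stats0$p
    z <- stats0$tMod
    zObs <- if (restandardize) .standardize(z) else z
    geneIdx <- lapply(sets, match, stats0$gene)

    if (!is.null(seed)) set.seed(seed)
    lsObs <- vapply(geneIdx, function(ix) lsStatistic(allP[ix]), numeric(1))
    ksObs <- vapply(geneIdx, function(ix) ksStatistic(allP[ix]), numeric(1))
    sizes <- lengths(sets)
    lsP <- ksP <- setNames(numeric(length(sets)), names(sets))
    for (k in unique(sizes)) {
        which_k <- which(sizes == k)
        lsHits <- ksHits <- integer(length(which_k))
        for (i in seq_len(nNull)) {
            ix <- sample.int(length(allP), k)
            pk <- allP[ix]
            lsN <- lsStatistic(pk)
            ksN <- ksStatistic(pk)
            lsHits <- lsHits + (lsN >= lsObs[which_k])
            ksHits <- ksHits + (ksN >= ksObs[which_k])
        }
        lsP[which_k] <- (1 + lsHits) / (nNull + 1)
        ksP[which_k] <- (1 + ksHits) / (nNull + 1)
    }

    ia <- .groupIdx(se, spec@groupA)
    ib <- .groupIdx(se, spec@groupB)
    nA <- length(ia); nB <- length(ib)
    x <- SummarizedExperiment::assay(se, "log2")[, c(ia, ib), drop = FALSE]
    obsLab <- rep(c(TRUE, FALSE), c(nA, nB))
    mmObs <- lapply(geneIdx, function(ix) maxmeanStat(zObs[ix]))
    mmHits <- integer(length(sets))
    for (i in seq_len(nPerm)) {
        lab <- sample(obsLab)
        zp <- .permZ(x, lab, nA, nB, fit)
        if (restandardize) zp <- .standardize(zp)
        for (s in seq_along(sets)) {
            if (maxmeanStat(zp[geneIdx[[s]]])$stat >= mmObs[[s]]$stat)
                mmHits[s] <- mmHits[s] + 1L
        }
    }
    mmP <- (1 + mmHits) / (nPerm + 1)

    out <- data.frame(
        set = names(sets), k = sizes,
        lsStat = lsObs, lsP = lsP, ksStat = ksObs, ksP = ksP,
        maxmeanStat = vapply(mmObs, `[[`, numeric(1), "stat"),
        maxmeanDirection = vapply(mmObs, `[[`, character(1), "direction"),
        maxmeanP = mmP, row.names = NULL)
    cons <- mapply(consensusCall, out$lsP, out$ksP, out$maxmeanP,
        MoreArgs = list(alpha = alpha), SIMPLIFY = FALSE)
    out$nSignificant <- vapply(cons, `[[`, numeric(1), "nSignificant")
    out$consensus <- vapply(cons, `[[`, logical(1), "consensus")
    attr(out, "skipped") <- res$skipped
    attr(out, "unresolved") <- res$unresolved
    out
}
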