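#' Fit the random-variance model to per-gene residual variances
#'
#' Assumes gene-specific inverse variances are gamma-distributed with shape
#' `a` and scale `b`, under which the observed pooled residual variance
#' satisfies `s^2 * a * b ~ F(d, 2a)` across genes. `a` and `b` are
#' estimated by maximum likelihood over all genes.
#'
#' Zero variances (possible with discretised input) are floored at the 1st
#' percentile of the positive variances so the log-likelihood stays finite.
#' If the variance distribution is degenerate (all values essentially
#' equal) the shape parameter is unbounded; by default this is an error,
#' with `cap = TRUE` the fit returns `a = aMax` and `b` such that the prior
#' mean variance equals the common value.
#'
#' @param variances Non-negative per-gene pooled residual variances
#'   (ideally >= 50 genes; fewer triggers a warning).
#' @param d Residual degrees of freedom of each variance
#'   (`n_a + n_b - 2` for a two-group comparison).
#' @param cap If `TRUE`, degenerate inputs return a capped fit instead of
#'   an error.
#' @param aMax Cap for the shape parameter (default 1e6).
#' @return An [RvmFit-class].
#' @export
#' @examples
#' v <- sampleGeneVariances(2000, 3, 1, seed = 1)
#' s2 <- v * rchisq(2000, 18) / 18  # observed variances at d = 18
#' fitRVM(s2, d = 18)
fitRVM <- function(variances, d, cap = FALSE, aMax = 1e6) {
    if (length(d) != 1L || !is.finite(d) || d < 1)
        stop("residual degrees of freedom d must be >= 1")
    if (any(!is.finite(variances)) || any(variances < 0))
        stop("variances must be finite and non-negative")
    n <- length(variances)
    if (n < 50L)
        warning("fewer than 50 genes; random-variance fit will be unstable")
    v <- variances
    pos <- v[v > 0]
    if (!length(pos))
        stop("all variances are zero; cannot fit the variance model")
    if (any(v == 0))
        v[v == 0] <- quantile(pos, 0.01)
    if (sd(v) < 1e-10 * mean(v)) {
        if (!cap)
            stop("degenerate variance distribution: shape parameter ",
                 "unbounded (use cap = TRUE for a capped fit)")
        b <- 1 / (aMax * mean(v))
        return(new("RvmFit", a = aMax, b = b, d = as.numeric(d),
            logLik = NA_real_, converged = FALSE, nGenes = n))
    }
    nll <- function(par) {
        a <- exp(par[1L]); b <- exp(par[2L])
        -sum(df(v * a * b, df1 = d, df2 = 2 * a, log = TRUE) + log(a * b))
    }
    a0 <- 2
    b0 <- 1 / (mean(v) * (a0 - 1))
    opt <- optim(log(c(a0, b0)), nll, method = "Nelder-Mead",
        control = list(maxit = 5000, reltol = 1e-12))
    a <- exp(opt$par[1L]); b <- exp(opt$par[2L])
    if (a > aMax) {
        if (!cap)
            stop("degenerate variance distribution: fitted shape exceeds ",
                 "cap (use cap = TRUE)")
        a <- aMax
    }
    new("RvmFit", a = a, b = b, d = as.numeric(d),
        logLik = -opt$value, converged = opt$convergence == 0L,
        nGenes = n)
}

.groupIdx <- function(se, label) {
    idx <- which(as.character(sampleGroups(se)) == label)
    if (length(idx) < 2L)
        stop("group '", label, "' absent or has fewer than 2 samples")
    idx
}

#' Random-variance moderated t-test for one comparison
#'
#' For each gene, the pooled residual variance is shrunk towards the prior
#' mean variance `tau = 1/(a*b)` of the fitted hierarchical model:
#' `shrunkS2 = (d*s2 + 2*a*tau) / (d + 2*a)`, and the moderated statistic
#' `tMod = (meanA - meanB) / sqrt(shrunkS2 * (1/nA + 1/nB))` is referred to
#' a t distribution with `d + 2a` degrees of freedom (two-sided).
#'
#' Fold changes are reported with the microarray sign convention: `fc =
#' 2^log2fc` when `log2fc >= 0` and `-2^(-log2fc)` otherwise, so a halving
#' appears as -2 and the threshold "fold change +-1.5" applies to `|fc|`.
#'
#' @param se A `SummarizedExperiment` from [msExperiment()] or
#'   [simulateDataset()].
#' @param spec A [ComparisonSpec-class].
#' @param fit Optional [RvmFit-class]; when `NULL` (default) the model is
#'   fitted to this comparison's pooled variances.
#' @return A `data.frame` with one row per gene: `gene`, `meanA`, `meanB`,
#'   `log2fc`, `fc`, `s2`, `shrunkS2`, `tMod`, `dfMod`, `p`, `significant`,
#'   `direction`. The fit used is attached as attribute `"fit"`.
#' @export
#' @examples
#' sim <- simulateDataset(simulationConfig(nGenes = 300), seed = 1)
#' stats <- rvmTTest(sim$se, ComparisonSpec("FPOS_GML", "CTRL"))
#' head(stats)
rvmTTest <- function(se, spec, fit = NULL) {
    stopifnot(is(spec, "ComparisonSpec"))
    ia <- .groupIdx(se, spec@groupA)
    ib <- .groupIdx(se, spec@groupB)
    x <- SummarizedExperiment::assay(se, "log2")
    xa <- x[, ia, drop = FALSE]
    xb <- x[, ib, drop = FALSE]
    nA <- length(ia); nB <- length(ib)
    d <- nA + nB - 2
    mA <- rowMeans(xa)
    mB <- rowMeans(xb)
    s2 <- (rowSums((xa - mA)^2) + rowSums((xb - mB)^2)) / d
    if (is.null(fit))
        fit <- fitRVM(s2, d)
    a <- fit@a; b <- fit@b
    tau <- 1 / (a * b)
    shrunk <- (d * s2 + 2 * a * tau) / (d + 2 * a)
    tMod <- (mA - mB) / sqrt(shrunk * (1 / nA + 1 / nB))
    dfMod <- fit@d + 2 * a
    p <- 2 * pt(-abs(tMod), df = dfMod)
    log2fc <- mA - mB
    fc <- ifelse(log2fc >= 0, 2^log2fc, -(2^(-log2fc)))
    significant <- p < spec@pThreshold & abs(fc) >= spec@fcThreshold
    direction <- ifelse(log2fc >= 0, "up", "down")
    res <- data.frame(gene = rownames(x), meanA = mA, meanB = mB,
        log2fc = log2fc, fc = fc, s2 = s2, shrunkS2 = shrunk,
        tMod = tMod, dfMod = dfMod, p = p,
        significant = significant, direction = direction,
        row.names = NULL)
    attr(res, "fit") <- fit
    attr(res, "comparison") <- paste0(spec@groupA, "_vs_", spec@groupB)
    res
}

#' Call differentially expressed genes at the comparison's thresholds
#'
#' A gene is significant iff `p < pThreshold` and `|fc| >= fcThreshold`;
#' significant genes are partitioned into up- and down-regulated by the
#' sign of the log2 fold change.
#'
#' @param stats Per-gene statistics from [rvmTTest()].
#' @param spec The [ComparisonSpec-class] carrying the thresholds (defaults
#'   to the thresholds the stats were computed under when omitted).
#' @return A [DegSet-class].
#' @export
callDegs <- function(stats, spec = NULL) {
    if (!is.null(spec)) {
        stopifnot(is(spec, "ComparisonSpec"))
        sig <- stats$p < spec@pThreshold &
            abs(stats$fc) >= spec@fcThreshold
    } else {
        sig <- stats$significant
    }
    label <- attr(stats, "comparison")
    if (is.null(label)) label <- "A_vs_B"
    new("DegSet", comparison = label,
        up = stats$gene[sig & stats$log2fc > 0],
        down = stats$gene[sig & stats$log2fc < 0])
}

#' Exclusive-subset overlap table for several DEG sets
#'
#' For every non-empty subset of the comparisons, counts the genes
#' significant in exactly that subset (the cells of a Venn diagram). The
#' counts sum to the size of the union of all sets.
#'
#' @param degSets Named list of two or more [DegSet-class] objects (or
#'   plain character vectors of gene ids).
#' @return A `data.frame` with one logical membership column per
#'   comparison and a `count` column; one row per non-empty subset.
#' @export
#' @examples
#' overlapAccounting(list(A = c("g1", "g2", "g3"), B = c("g2", "g3", "g4")))
overlapAccounting <- function(degSets) {
    if (length(degSets) < 2L)
        stop("need at least 2 DEG sets")
    sets <- lapply(degSets, function(s)
        if (is(s, "DegSet")) degGenes(s) else as.character(s))
    if (is.null(names(sets)))
        names(sets) <- paste0("set", seq_along(sets))
    k <- length(sets)
    universe <- unique(unlist(sets))
    member <- vapply(sets, function(s) universe %in% s,
        logical(length(universe)))
    if (length(universe) == 1L) member <- matrix(member, nrow = 1L)
    patterns <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1L, , drop = FALSE]
    names(patterns) <- names(sets)
    patterns$count <- vapply(seq_len(nrow(patterns)), function(i) {
        target <- as.logical(patterns[i, seq_len(k)])
        sum(apply(member, 1L, function(row) all(row == target)))
    }, integer(1))
    rownames(patterns) <- NULL
    patterns
}
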