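#' Balanced null split of two groups into pseudo-groups
#'
#' Divides the samples of the two compared groups into two pseudo-groups,
#' each containing exactly half of each real group, assigned uniformly at
#' random without replacement. A comparison between the pseudo-groups is
#' then null by construction: any real group difference cancels.
#'
#' @param sheet A sample sheet data frame or a `SummarizedExperiment`.
#' @param spec A [ComparisonSpec-class] naming the two groups to split.
#' @param seed Optional integer seed.
#' @param oddPolicy For odd group sizes: `"error"` (default) or
#'   `"alternate"`, which assigns the extra sample of each group to pseudo-
#'   group 1 or 2 alternately by `permIndex`.
#' @param permIndex Permutation index used by the `"alternate"` policy.
#' @return List with character vectors `g1` and `g2` of sample ids;
#'   disjoint and jointly covering both groups.
#' @export
#' @examples
#' sim <- simulateDataset(simulationConfig(nGenes = 60), seed = 1)
#' balancedNullPartition(sim$se, ComparisonSpec("FPOS_GML", "CTRL"),
#'     seed = 7)
balancedNullPartition <- function(sheet, spec, seed = NULL,
                                  oddPolicy = c("error", "alternate"),
                                  permIndex = 1L) {
    oddPolicy <- match.arg(oddPolicy)
    stopifnot(is(spec, "ComparisonSpec"))
    if (is(sheet, "SummarizedExperiment"))
        sheet <- data.frame(
            sample_id = colnames(sheet),
            group = as.character(sampleGroups(sheet)))
    idsA <- sheet$sample_id[sheet$group == spec@groupA]
    idsB <- sheet$sample_id[sheet$group == spec@groupB]
    if (length(idsA) < 2L || length(idsB) < 2L)
        stop("both groups need >= 2 samples for a balanced split")
    if ((length(idsA) %% 2L || length(idsB) %% 2L) &&
        oddPolicy == "error")
        stop("balanced split requires even group sizes")
    if (!is.null(seed)) set.seed(seed)
    half <- function(ids) sample(ids, length(ids) %/% 2L)
    hA <- half(idsA); hB <- half(idsB)
    g1 <- c(hA, hB)
    g2 <- setdiff(c(idsA, idsB), g1)
    if (oddPolicy == "alternate") {
        # the floor-half split already left the extra samples in g2;
        # alternate permutations move them to g1 instead
        extra <- c(if (length(idsA) %% 2L) setdiff(idsA, hA)[1L],
                   if (length(idsB) %% 2L) setdiff(idsB, hB)[1L])
        if (length(extra) && permIndex %% 2L == 0L) {
            g1 <- c(g1, extra)
            g2 <- setdiff(g2, extra)
        }
    }
    list(g1 = sort(g1), g2 = sort(g2))
}

.pseudoExperiment <- function(se, split) {
    ids <- c(split$g1, split$g2)
    sub <- se[, ids]
    cd <- SummarizedExperiment::colData(sub)
    cd$group <- factor(ifelse(ids %in% split$g1, "CTRL", "FPOS_GML"),
        levels = msGroups())
    SummarizedExperiment::colData(sub) <- cd
    sub
}

.distinctSplits <- function(se, spec, nPerm, seedStream) {
    splits <- list()
    keys <- character()
    tries <- 0L
    while (length(splits) < nPerm) {
        tries <- tries + 1L
        if (tries > 100L * nPerm)
            stop("could not find ", nPerm,
                 " distinct balanced splits (design too small)")
        sp <- balancedNullPartition(se, spec, seed = seedStream[tries],
            oddPolicy = "alternate",
            permIndex = length(splits) + 1L)
        key <- paste(sort(c(paste(sp$g1, collapse = ","),
                            paste(sp$g2, collapse = ","))),
                     collapse = "|")
        if (!key %in% keys) {
            splits[[length(splits) + 1L]] <- sp
            keys <- c(keys, key)
        }
    }
    splits
}

.permStats <- function(se, spec, nPerm, seed, refit) {
    obsStats <- rvmTTest(se, spec)
    if (!is.null(seed)) set.seed(seed)
    seedStream <- sample.int(.Machine$integer.max - 1L, 200L * nPerm)
    splits <- .distinctSplits(se, spec, nPerm, seedStream)
    frozen <- if (refit) NULL else attr(obsStats, "fit")
    nullStats <- lapply(splits, function(sp) {
        pse <- .pseudoExperiment(se, sp)
        rvmTTest(pse, ComparisonSpec("FPOS_GML", "CTRL",
            spec@pThreshold, spec@fcThreshold), fit = frozen)
    })
    list(obs = obsStats, null = nullStats, splits = splits)
}

.countDegs <- function(stats, pThr, fcThr) {
    sum(stats$p < pThr & abs(stats$fc) >= fcThr)
}

#' Balanced-permutation FDR at one stringency condition
#'
#' The experimental DEG count at `(pThr, fcThr)` on the true labels is
#' compared with the median DEG count across `nPerm` balanced null
#' permutations, each of which reruns the full class comparison (including
#' the random-variance refit, unless `refit = FALSE`) on pseudo-labels:
#' `FDR% = 100 * median(null counts) / experimental count`.
#'
#' @param se A `SummarizedExperiment`.
#' @param spec A [ComparisonSpec-class].
#' @param pThr,fcThr Thresholds of the cell (default: those in `spec`).
#' @param nPerm Number of distinct balanced permutations (default 10).
#' @param seed Optional master seed; permutation seeds derive from it.
#' @param refit Refit the variance-model hyperparameters inside each
#'   permutation (default `TRUE`).
#' @return A list of class `"StringencyCell"`: `pThr`, `fcThr`,
#'   `experimental`, `nullCounts`, `medianNull`, `fdrPct` (`NA` with a
#'   warning when the experimental count is zero).
#' @export
#' @examples
#' sim <- simulateDataset(simulationConfig(nGenes = 400), seed = 1)
#' cell <- permutationFdr(sim$se, ComparisonSpec("FPOS_GML", "CTRL"),
#'     nPerm = 3, seed = 1)
#' cell$fdrPct
permutationFdr <- function(se, spec, pThr = NULL, fcThr = NULL,
                           nPerm = 10, seed = NULL, refit = TRUE) {
    if (is.null(pThr)) pThr <- spec@pThreshold
    if (is.null(fcThr)) fcThr <- spec@fcThreshold
    ps <- .permStats(se, spec, nPerm, seed, refit)
    experimental <- .countDegs(ps$obs, pThr, fcThr)
    nullCounts <- vapply(ps$null, .countDegs, numeric(1), pThr, fcThr)
    medianNull <- median(nullCounts)
    if (experimental == 0L) {
        warning("no experimental DEGs at (p < ", pThr, ", |FC| >= ",
                fcThr, "); FDR% undefined")
        fdrPct <- NA_real_
    } else {
        fdrPct <- 100 * medianNull / experimental
    }
    structure(list(pThr = pThr, fcThr = fcThr,
        experimental = experimental, nullCounts = nullCounts,
        medianNull = medianNull, fdrPct = fdrPct),
        class = "StringencyCell")
}

#' @export
print.StringencyCell <- function(x, ...) {
    cat(sprintf(
        "StringencyCell (p < %g, |FC| >= %g): experimental = %d, ",
        x$pThr, x$fcThr, x$experimental))
    cat(sprintf("median null = %g, FDR%% = %s\n", x$medianNull,
        ifelse(is.na(x$fdrPct), "NA", sprintf("%.2f", x$fdrPct))))
    invisible(x)
}

#' Stringency scan over p-value and fold-change thresholds
#'
#' Evaluates the balanced-permutation FDR on a grid of `(p, FC)`
#' stringency conditions. All grid cells share the same permutation
#' splits, so the scan varies thresholds, not labelings; within each
#' permutation the null count is therefore monotone non-increasing in
#' stringency.
#'
#' @param se A `SummarizedExperiment`.
#' @param spec A [ComparisonSpec-class] naming the two groups.
#' @param pGrid,fcGrid Threshold grids (defaults `c(0.05, 0.01)` and
#'   `c(1.5, 2)`).
#' @param nPerm Number of balanced permutations shared by all cells
#'   (default 10).
#' @param seed Optional master seed.
#' @param refit Refit the variance model inside each permutation.
#' @return A `data.frame` with one row per grid cell (`pThr`, `fcThr`,
#'   `experimental`, `medianNull`, `fdrPct`) and the per-cell null counts
#'   as attribute `"nullCounts"` (cells x permutations matrix).
#' @export
stringencyScan <- function(se, spec, pGrid = c(0.05, 0.01),
                           fcGrid = c(1.5, 2), nPerm = 10, seed = NULL,
                           refit = TRUE) {
    if (!length(pGrid) || !length(fcGrid))
        stop("threshold grid must be non-empty")
    ps <- .permStats(se, spec, nPerm, seed, refit)
    grid <- expand.grid(pThr = pGrid, fcThr = fcGrid,
        KEEP.OUT.ATTRS = FALSE)
    nullCounts <- t(vapply(seq_len(nrow(grid)), function(i)
        vapply(ps$null, .countDegs, numeric(1),
            grid$pThr[i], grid$fcThr[i]),
        numeric(nPerm)))
    grid$experimental <- vapply(seq_len(nrow(grid)), function(i)
        .countDegs(ps$obs, grid$pThr[i], grid$fcThr[i]), numeric(1))
    grid$medianNull <- apply(nullCounts, 1L, median)
    grid$fdrPct <- ifelse(grid$experimental > 0,
        100 * grid$medianNull / grid$experimental, NA_real_)
    attr(grid, "nullCounts") <- nullCounts
    grid
}

#' Pooled FDR across several comparisons
#'
#' The study-wide ("overall") FDR pools the per-comparison cells at one
#' stringency condition as the ratio of summed median null counts to
#' summed experimental counts, in percent.
#'
#' @param cells List of `"StringencyCell"` results (one per comparison) at
#'   the same thresholds.
#' @return Single numeric pooled FDR percentage (`NA` if all experimental
#'   counts are zero).
#' @export
pooledFdr <- function(cells) {
    exp <- sum(vapply(cells, `[[`, numeric(1), "experimental"))
    med <- sum(vapply(cells, `[[`, numeric(1), "medianNull"))
    if (exp == 0) return(NA_real_)
    100 * med / exp
}
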