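#' Delta-Ct and relative expression against the reference gene
#'
#' `dct = ct_target - ct_reference`; relative expression is
#' `2^(-dct)` under perfect doubling per cycle (the "factor 2" rule), so
#' a target amplifying 5 cycles later than GAPDH has relative expression
#' `2^-5 = 0.03125`.
#'
#' @param ctTarget,ctReference Numeric Ct values in cycles, each in
#'   `(0, 45]`; `ctReference` must be present for every target value.
#' @return Data frame with columns `dct` and `relExpr`.
#' @export
#' @examples
#' deltaCt(25, 20)  # dct 5, relExpr 0.03125
deltaCt <- function(ctTarget, ctReference) {
    if (length(ctReference) != length(ctTarget))
        stop("a reference Ct is required for every target Ct")
    ok <- function(ct) all(is.finite(ct) & ct > 0 & ct <= 45)
    if (!ok(ctTarget) || !ok(ctReference))
        stop("Ct values must lie in (0, 45]")
    dct <- ctTarget - ctReference
    data.frame(dct = dct, relExpr = 2^(-dct))
}

#' Group fold change from a qPCR Ct table
#'
#' The default convention works on the Ct scale (a geometric mean of the
#' per-sample ratios): `fc = 2^(-(mean dct_A - mean dct_B))`. The
#' alternative `"ratio-of-means"` divides the arithmetic means of the
#' per-sample relative expressions.
#'
#' @param table Data frame with columns `sample_id`, `group`, `target`,
#'   `ct_target`, `ct_reference` (see [simulateQpcrTable()]).
#' @param target Target gene to quantify.
#' @param groupA,groupB Groups to compare (fold change of A over B).
#' @param method `"dct-means"` (default) or `"ratio-of-means"`.
#' @return Positive linear fold change.
#' @export
qpcrFoldChange <- function(table, target, groupA, groupB,
                           method = c("dct-means", "ratio-of-means")) {
    method <- match.arg(method)
    rows <- table[table$target == target, , drop = FALSE]
    dc <- deltaCt(rows$ct_target, rows$ct_reference)
    a <- rows$group == groupA
    b <- rows$group == groupB
    if (sum(a) < 2L || sum(b) < 2L)
        stop("need >= 2 samples per group for target '", target, "'")
    if (method == "dct-means")
        2^(-(mean(dc$dct[a]) - mean(dc$dct[b])))
    else
        mean(dc$relExpr[a]) / mean(dc$relExpr[b])
}

#' Mann-Whitney (Wilcoxon rank-sum) comparison of two groups
#'
#' Exact two-sided p-value when the combined sample size is at most 20 and
#' there are no ties; normal approximation with tie correction otherwise.
#' Identical values across both groups give p = 1 with a warning.
#'
#' @param a,b Numeric vectors of the two groups' values.
#' @return List with `u` (the Mann-Whitney U statistic for group `a`) and
#'   `p` (two-sided).
#' @export
#' @examples
#' mannWhitney(c(1, 2, 3), c(4, 5, 6))  # U 0, exact p 0.1
mannWhitney <- function(a, b) {
    if (!length(a) || !length(b))
        stop("both groups must be non-empty")
    if (length(unique(c(a, b))) == 1L) {
        warning("all values identical across both groups")
        return(list(u = length(a) * length(b) / 2, p = 1))
    }
    ties <- anyDuplicated(c(a, b)) > 0L
    exact <- (length(a) + length(b) <= 20L) && !ties
    wt <- suppressWarnings(wilcox.test(a, b, exact = exact,
        correct = !exact))
    list(u = unname(wt$statistic), p = wt$p.value)
}

#' Full qPCR group comparison for one target
#'
#' Combines the fold change of [qpcrFoldChange()] with the Mann-Whitney
#' comparison of the per-sample relative expressions.
#'
#' @inheritParams qpcrFoldChange
#' @return Data frame row: `target`, `groupA`, `groupB`, `foldChange`,
#'   `u`, `p`.
#' @export
#' @examples
#' tab <- simulateQpcrTable(
#'     data.frame(target = "TNFR1", group = "FPOS_GML", ratio = 4.5),
#'     seed = 1)
#' qpcrCompare(tab, "TNFR1", "FPOS_GML", "CTRL")
qpcrCompare <- function(table, target, groupA, groupB,
                        method = c("dct-means", "ratio-of-means")) {
    fc <- qpcrFoldChange(table, target, groupA, groupB, method)
    rows <- table[table$target == target, , drop = FALSE]
    dc <- deltaCt(rows$ct_target, rows$ct_reference)
    mw <- mannWhitney(dc$relExpr[rows$group == groupA],
                      dc$relExpr[rows$group == groupB])
    data.frame(target = target, groupA = groupA, groupB = groupB,
        foldChange = fc, u = mw$u, p = mw$p)
}
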