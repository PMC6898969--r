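#' Default TNF pro-death and pro-survival gene panels
#'
#' The TNF signalling dichotomy: TNFR1/RIP1-mediated necroptotic and
#' apoptotic cell-death genes (RIPK1, RIPK3, MLKL, the de-ubiquitinases
#' RNF11 and CYLD, LOX, HSP70, TNFAIP3, CASP3, CASP7, TNFR1) versus
#' TNFR1/TNFR2/NF-kB-mediated cell-survival genes (TNFR2, CASP8, TRADD,
#' FADD, CFLAR, IKK-B, NFKB, RELA, AKT, XIAP). Symbols are informal
#' pathway names, kept in a user-editable mapping file rather than
#' hard-coded official identifiers; supply `path` to use your own
#' two-column (gene, panel) TSV.
#'
#' @param path Optional path to a custom panel TSV with columns `gene`
#'   and `panel` (values `"death"`/`"survival"`).
#' @return Data frame with columns `gene` and `panel`; the two panels are
#'   disjoint and non-empty.
#' @export
#' @examples
#' table(tnfPanels()$panel)
tnfPanels <- function(path = NULL) {
    if (is.null(path))
        path <- system.file("extdata", "tnf_panels.tsv",
            package = "cortexMS", mustWork = TRUE)
    p <- read.delim(path, colClasses = "character",
        stringsAsFactors = FALSE)
    if (!all(c("gene", "panel") %in% names(p)))
        stop("panel file needs columns 'gene' and 'panel'")
    if (!all(p$panel %in% c("death", "survival")))
        stop("panel values must be 'death' or 'survival'")
    overlap <- intersect(p$gene[p$panel == "death"],
                         p$gene[p$panel == "survival"])
    if (length(overlap))
        stop("panels must be disjoint; shared: ",
             paste(overlap, collapse = ", "))
    if (!all(c("death", "survival") %in% p$panel))
        stop("both panels must be non-empty")
    p
}

#' TNF pathway balance report for one condition
#'
#' Summarises a comparison's per-gene statistics over the pro-death and
#' pro-survival panels: the panel means of the log2 fold changes, their
#' difference as the balance index
#' `balanceIndex = mean(log2fc death) - mean(log2fc survival)`, and a
#' verdict: `death-shifted` when the index exceeds `delta`,
#' `survival-shifted` below `-delta`, otherwise `balanced`. Genes weight
#' equally; the index is a descriptive formalisation of the heatmap
#' dichotomy, not a significance test.
#'
#' @param stats Per-gene statistics from [rvmTTest()] for one condition
#'   vs control.
#' @param panels Panel definition data frame (default [tnfPanels()]).
#' @param delta Verdict dead-band on the log2 scale (default 0.2).
#' @return List of class `"BalanceReport"`: `condition`,
#'   `meanLog2fcDeath`, `meanLog2fcSurvival`, `balanceIndex`, `verdict`,
#'   `perGene` (gene, panel, log2fc, p), and `unresolved` (panel members
#'   absent from the stats).
#' @export
#' @examples
#' sim <- simulateDataset(simulationConfig(nGenes = 100), seed = 1)
#' stats <- rvmTTest(sim$se, ComparisonSpec("FPOS_GML", "CTRL"))
#' computeBalance(stats)$verdict
computeBalance <- function(stats, panels = tnfPanels(), delta = 0.2) {
    idx <- match(panels$gene, stats$gene)
    unresolved <- panels$gene[is.na(idx)]
    for (pn in c("death", "survival")) {
        inPanel <- panels$panel == pn
        if (all(is.na(idx[inPanel])))
            stop("panel '", pn, "' fully unresolved; missing: ",
                 paste(panels$gene[inPanel], collapse = ", "))
    }
    keep <- !is.na(idx)
    perGene <- data.frame(
        gene = panels$gene[keep],
        panel = panels$panel[keep],
        log2fc = stats$log2fc[idx[keep]],
        p = stats$p[idx[keep]])
    mDeath <- mean(perGene$log2fc[perGene$panel == "death"])
    mSurv <- mean(perGene$log2fc[perGene$panel == "survival"])
    index <- mDeath - mSurv
    verdict <- if (index > delta) "death-shifted"
        else if (index < -delta) "survival-shifted"
        else "balanced"
    structure(list(
        condition = attr(stats, "comparison"),
        meanLog2fcDeath = mDeath,
        meanLog2fcSurvival = mSurv,
        balanceIndex = index,
        verdict = verdict,
        perGene = perGene,
        unresolved = unresolved), class = "BalanceReport")
}

#' @export
print.BalanceReport <- function(x, ...) {
    cat(sprintf("BalanceReport [%s]\n",
        ifelse(is.null(x$condition), "?", x$condition)))
    cat(sprintf(
        "  mean log2FC death = %.3f, survival = %.3f, index = %.3f\n",
        x$meanLog2fcDeath, x$meanLog2fcSurvival, x$balanceIndex))
    cat("  verdict:", x$verdict, "\n")
    if (length(x$unresolved))
        cat("  unresolved panel genes:",
            paste(x$unresolved, collapse = ", "), "\n")
    invisible(x)
}

#' Heatmap row order for the TNF panels
#'
#' Orders panel genes for display: within each panel, rows follow the
#' average-linkage/uncentered-Pearson dendrogram leaf order
#' ([hierarchicalCluster()]); the panels stay contiguous with the death
#' panel first.
#'
#' @param mat Expression matrix (genes x samples) containing the panel
#'   genes.
#' @param panels Panel definition data frame (default [tnfPanels()]).
#' @return Character vector: the panel genes present in `mat`, in display
#'   order.
#' @export
panelHeatmapOrder <- function(mat, panels = tnfPanels()) {
    orderOne <- function(genes) {
        genes <- intersect(genes, rownames(mat))
        if (length(genes) == 0L)
            stop("no panel gene present in the matrix")
        if (length(genes) == 1L) return(genes)
        hc <- hierarchicalCluster(mat[genes, , drop = FALSE])
        genes[hc$order]
    }
    c(orderOne(panels$gene[panels$panel == "death"]),
      orderOne(panels$gene[panels$panel == "survival"]))
}
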