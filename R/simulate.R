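#' SimulationConfig: study-design parameters for the synthetic generator
#'
#' Encodes the 5-group cortical design (controls plus follicle-positive and
#' follicle-negative MS cases, each case contributing one grey matter lesion
#' and one normal-appearing grey matter array), the hierarchical variance
#' model the moderated t-test assumes, and the planted differential-
#' expression effects.
#'
#' @slot nGenes Number of genes (default 8000).
#' @slot nCtrl,nFposCases,nFnegCases Design counts (defaults 10/10/10; each
#'   case yields one GML and one NAGM array, giving 50 arrays in total).
#' @slot mu0,muSd Mean and SD of per-gene baseline means on the log2 scale
#'   (defaults 8 and 1, the typical microarray intensity range).
#' @slot aTrue,bTrue Gamma shape and scale of the per-gene inverse
#'   variances (defaults 3 and 1); must satisfy `aTrue > 1`.
#' @slot caseSd SD of the gene-specific case-level random effect shared by
#'   the GML and NAGM arrays of one case (default 0.2).
#' @slot effects Planted-effect table: data frame with columns `gene`,
#'   `condition` (a non-control group label) and `log2fc`.
#' @slot nDecoySets,decoySetSize Number and size of decoy gene sets sampled
#'   from non-planted genes (defaults 50 and 20).
#' @name SimulationConfig-class
#' @aliases SimulationConfig-class
#' @exportClass SimulationConfig
setClass("SimulationConfig",
    representation(
        nGenes = "integer", nCtrl = "integer",
        nFposCases = "integer", nFnegCases = "integer",
        mu0 = "numeric", muSd = "numeric",
        aTrue = "numeric", bTrue = "numeric", caseSd = "numeric",
        effects = "data.frame",
        nDecoySets = "integer", decoySetSize = "integer"
    )
)

setValidity("SimulationConfig", function(object) {
    msgs <- character()
    if (object@nGenes < 2L) msgs <- c(msgs, "nGenes must be >= 2")
    if (any(c(object@nCtrl, object@nFposCases, object@nFnegCases) < 2L))
        msgs <- c(msgs, "all design counts must be >= 2")
    if (!is.finite(object@aTrue) || object@aTrue <= 1)
        msgs <- c(msgs, "aTrue must be > 1")
    if (!is.finite(object@bTrue) || object@bTrue <= 0)
        msgs <- c(msgs, "bTrue must be > 0")
    if (object@caseSd < 0) msgs <- c(msgs, "caseSd must be >= 0")
    if (object@muSd < 0) msgs <- c(msgs, "muSd must be >= 0")
    eff <- object@effects
    if (nrow(eff)) {
        if (!all(c("gene", "condition", "log2fc") %in% names(eff)))
            msgs <- c(msgs,
                "effects needs columns gene, condition, log2fc")
        else if (!all(is.finite(eff$log2fc)))
            msgs <- c(msgs, "planted log2fc values must be finite")
    }
    if (length(msgs)) msgs else TRUE
})

#' Construct a SimulationConfig
#'
#' @param nGenes,nCtrl,nFposCases,nFnegCases,mu0,muSd,aTrue,bTrue,caseSd
#'   See [SimulationConfig-class]; defaults reproduce the 50-array design.
#' @param effects Planted-effect data frame (`gene`, `condition`,
#'   `log2fc`); empty by default (global null).
#' @param nDecoySets,decoySetSize Decoy gene-set configuration.
#' @return A validated [SimulationConfig-class].
#' @export
#' @examples
#' simulationConfig(nGenes = 500)
simulationConfig <- function(nGenes = 8000, nCtrl = 10, nFposCases = 10,
                             nFnegCases = 10, mu0 = 8, muSd = 1,
                             aTrue = 3, bTrue = 1, caseSd = 0.2,
                             effects = data.frame(gene = character(),
                                 condition = character(),
                                 log2fc = numeric()),
                             nDecoySets = 50, decoySetSize = 20) {
    new("SimulationConfig",
        nGenes = as.integer(nGenes), nCtrl = as.integer(nCtrl),
        nFposCases = as.integer(nFposCases),
        nFnegCases = as.integer(nFnegCases),
        mu0 = mu0, muSd = muSd, aTrue = aTrue, bTrue = bTrue,
        caseSd = caseSd, effects = effects,
        nDecoySets = as.integer(nDecoySets),
        decoySetSize = as.integer(decoySetSize))
}

#' Draw gene-specific variances from the hierarchical variance model
#'
#' Inverse variances (precisions) are gamma-distributed with shape `aTrue`
#' and scale `bTrue`, so their mean is `aTrue * bTrue`. Under this model a
#' pooled residual variance with `d` degrees of freedom satisfies
#' `s^2 * a * b ~ F(d, 2a)` across genes, which is what [fitRVM()] fits.
#'
#' @param nGenes Number of variances to draw.
#' @param aTrue,bTrue Positive gamma shape and scale of the precisions.
#' @param seed Optional integer seed for reproducibility.
#' @return Numeric vector of `nGenes` strictly positive variances.
#' @export
#' @examples
#' sampleGeneVariances(5, aTrue = 3, bTrue = 1, seed = 1)
sampleGeneVariances <- function(nGenes, aTrue, bTrue, seed = NULL) {
    if (!is.finite(aTrue) || aTrue <= 0 || !is.finite(bTrue) || bTrue <= 0)
        stop("aTrue and bTrue must be positive")
    if (!is.null(seed)) set.seed(seed)
    1 / rgamma(nGenes, shape = aTrue, scale = bTrue)
}

.designSheet <- function(config) {
    ctrl <- data.frame(
        sample_id = sprintf("CTRL_%02d", seq_len(config@nCtrl)),
        group = "CTRL",
        case_id = sprintf("C%02d", seq_len(config@nCtrl)))
    fpos <- do.call(rbind, lapply(seq_len(config@nFposCases), function(i)
        data.frame(
            sample_id = sprintf("FP%02d_%s", i, c("GML", "NAGM")),
            group = c("FPOS_GML", "FPOS_NAGM"),
            case_id = sprintf("FP%02d", i))))
    fneg <- do.call(rbind, lapply(seq_len(config@nFnegCases), function(i)
        data.frame(
            sample_id = sprintf("FN%02d_%s", i, c("GML", "NAGM")),
            group = c("FNEG_GML", "FNEG_NAGM"),
            case_id = sprintf("FN%02d", i))))
    rbind(ctrl, fpos, fneg)
}

.panelGeneIds <- function() {
    p <- tnfPanels()
    p$gene
}

#' Generate a synthetic cortical expression dataset with ground truth
#'
#' Emulates the 50-array design: each value is
#' `mu_g + plantedEffect(g, group(s)) + caseEffect(g, case(s)) + noise`,
#' with noise N(0, sigma_g^2) and sigma_g^2 drawn from the hierarchical
#' variance model via [sampleGeneVariances()]. The first genes are named
#' after the TNF pro-death and pro-survival panels (see [tnfPanels()]) so
#' panel-level analyses resolve against the matrix; the gene-set collection
#' contains those two panels plus decoy sets sampled uniformly without
#' replacement from non-planted genes.
#'
#' @param config A [SimulationConfig-class].
#' @param seed Optional integer seed; identical config + seed give
#'   identical output.
#' @return List with `se` (a `SummarizedExperiment`, assay `"log2"`),
#'   `geneSets` (a [GeneSetCollection-class]), and `truth` (list with
#'   `effects`, the planted-effect table, and `sets`, per-set per-condition
#'   enrichment status).
#' @export
#' @examples
#' sim <- simulateDataset(simulationConfig(nGenes = 200), seed = 1)
#' dim(sim$se)
simulateDataset <- function(config, seed = NULL) {
    stopifnot(is(config, "SimulationConfig"))
    validObject(config)
    if (!is.null(seed)) set.seed(seed)
    panel <- .panelGeneIds()
    if (config@nGenes < length(panel) + 10L)
        stop("nGenes too small to host the TNF panels plus decoys")
    geneIds <- c(panel,
        sprintf("G%05d", seq_len(config@nGenes - length(panel))))
    sheet <- .designSheet(config)
    conds <- setdiff(msGroups(), "CTRL")
    eff <- config@effects
    if (nrow(eff)) {
        badG <- setdiff(eff$gene, geneIds)
        if (length(badG))
            stop("effect table references unknown gene(s): ",
                 paste(head(badG, 3), collapse = ", "))
        badC <- setdiff(eff$condition, conds)
        if (length(badC))
            stop("effect table references unknown condition(s): ",
                 paste(badC, collapse = ", "))
    }
    nG <- config@nGenes
    nS <- nrow(sheet)
    mu <- rnorm(nG, config@mu0, config@muSd)
    sigma2 <- sampleGeneVariances(nG, config@aTrue, config@bTrue)
    effM <- matrix(0, nG, nS, dimnames = list(geneIds, sheet$sample_id))
    if (nrow(eff)) {
        gi <- match(eff$gene, geneIds)
        for (k in seq_len(nrow(eff))) {
            cols <- which(sheet$group == eff$condition[k])
            effM[gi[k], cols] <- effM[gi[k], cols] + eff$log2fc[k]
        }
    }
    cases <- unique(sheet$case_id)
    caseEff <- matrix(rnorm(nG * length(cases), 0, config@caseSd),
        nG, length(cases))
    caseM <- caseEff[, match(sheet$case_id, cases), drop = FALSE]
    noise <- matrix(rnorm(nG * nS), nG, nS) * sqrt(sigma2)
    mat <- mu + effM + caseM + noise
    dimnames(mat) <- list(geneIds, sheet$sample_id)
    se <- msExperiment(mat, sheet)

    planted <- unique(eff$gene)
    p <- tnfPanels()
    sets <- list(
        TNF_DEATH = p$gene[p$panel == "death"],
        TNF_SURVIVAL = p$gene[p$panel == "survival"])
    freeGenes <- setdiff(geneIds, c(planted, panel))
    for (i in seq_len(config@nDecoySets)) {
        sets[[sprintf("DECOY_%03d", i)]] <-
            sample(freeGenes, min(config@decoySetSize, length(freeGenes)))
    }
    gsc <- GeneSetCollection(sets)

    setTruth <- expand.grid(set = names(sets), condition = conds,
        stringsAsFactors = FALSE)
    setTruth$enriched <- vapply(seq_len(nrow(setTruth)), function(i) {
        members <- sets[[setTruth$set[i]]]
        any(eff$gene %in% members &
            eff$condition == setTruth$condition[i] & eff$log2fc != 0)
    }, logical(1))

    list(se = se, geneSets = gsc,
         truth = list(effects = eff, sets = setTruth),
         config = config)
}

#' Generate a synthetic qPCR Ct table
#'
#' Emulates SYBR-green style Ct measurements normalised against a GAPDH
#' reference: for sample s of group g,
#' `Ct_ref = baselineRef - L_s + noise` and
#' `Ct_target = baselineTarget - (L_s + log2(ratio(target, g))) + noise`,
#' where `L_s` is a per-sample log2 loading factor (cancelling in delta-Ct)
#' and `ratio` is the true relative expression of the target in that group
#' (1 for groups not listed).
#'
#' @param targets Data frame with columns `target`, `group`, `ratio`
#'   (linear, > 0) giving each target's true relative expression per group.
#' @param nPerGroup Samples per group (default 10, the study design).
#' @param groups Group labels to simulate; defaults to `CTRL` plus the
#'   groups named in `targets`.
#' @param noiseSd Ct measurement noise SD in cycles (default 0.3).
#' @param sampleSd SD of the per-sample log2 loading factor (default 0.2).
#' @param baselineTarget,baselineRef Baseline Ct of target and reference at
#'   unit expression (defaults 26 and 20 cycles).
#' @param seed Optional integer seed.
#' @return Data frame with columns `sample_id`, `group`, `target`,
#'   `ct_target`, `ct_reference`.
#' @export
#' @examples
#' tab <- simulateQpcrTable(
#'     data.frame(target = "TNFR1", group = "FPOS_GML", ratio = 4.5),
#'     seed = 1)
#' head(tab)
simulateQpcrTable <- function(targets, nPerGroup = 10, groups = NULL,
                              noiseSd = 0.3, sampleSd = 0.2,
                              baselineTarget = 26, baselineRef = 20,
                              seed = NULL) {
    stopifnot(all(c("target", "group", "ratio") %in% names(targets)))
    if (any(!is.finite(targets$ratio) | targets$ratio <= 0))
        stop("true expression ratios must be positive")
    if (!is.null(seed)) set.seed(seed)
    if (is.null(groups))
        groups <- unique(c("CTRL", targets$group))
    out <- list()
    for (tg in unique(targets$target)) {
        for (g in groups) {
            ratio <- targets$ratio[targets$target == tg &
                                   targets$group == g]
            if (!length(ratio)) ratio <- 1
            ids <- sprintf("%s_%02d", g, seq_len(nPerGroup))
            L <- rnorm(nPerGroup, 0, sampleSd)
            ctRef <- baselineRef - L + rnorm(nPerGroup, 0, noiseSd)
            ctTgt <- baselineTarget - (L + log2(ratio)) +
                rnorm(nPerGroup, 0, noiseSd)
            out[[length(out) + 1L]] <- data.frame(
                sample_id = ids, group = g, target = tg,
                ct_target = ctTgt, ct_reference = ctRef)
        }
    }
    tab <- do.call(rbind, out)
    rownames(tab) <- NULL
    tab
}
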