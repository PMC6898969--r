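#' @import methods
#' @importFrom stats median optim pt quantile rgamma rnorm sd var
#'   wilcox.test df setNames
#' @importFrom utils head read.delim write.table
#' @importFrom S4Vectors DataFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#'   colData<-
NULL

#' Group vocabulary of the cortical study design
#'
#' The five array groups of the motor-cortex design: non-neurological
#' controls, and grey matter lesion (GML) or normal-appearing grey matter
#' (NAGM) arrays from follicle-positive (FPOS) or follicle-negative (FNEG)
#' secondary progressive MS cases.
#'
#' @return Character vector of the five admissible group labels.
#' @export
#' @examples
#' msGroups()
msGroups <- function() {
    c("CTRL", "FPOS_GML", "FPOS_NAGM", "FNEG_GML", "FNEG_NAGM")
}

#' ComparisonSpec: a two-group comparison with significance thresholds
#'
#' Bundles the two group labels being compared with the gene-level
#' significance rule (p-value threshold and linear-scale fold-change
#' threshold applied to the fold-change magnitude).
#'
#' @slot groupA,groupB Group labels; `groupA` minus `groupB` defines the
#'   sign of the log2 fold change.
#' @slot pThreshold Gene-level p-value threshold, strictly between 0 and 1.
#' @slot fcThreshold Linear fold-change threshold (> 1) applied to the
#'   fold-change magnitude.
#' @name ComparisonSpec-class
#' @aliases ComparisonSpec-class
#' @exportClass ComparisonSpec
setClass("ComparisonSpec",
    representation(
        groupA = "character",
        groupB = "character",
        pThreshold = "numeric",
        fcThreshold = "numeric"
    )
)

setValidity("ComparisonSpec", function(object) {
    msgs <- character()
    if (length(object@groupA) != 1L || length(object@groupB) != 1L)
        msgs <- c(msgs, "groupA and groupB must be single group labels")
    if (length(object@groupA) == 1L && length(object@groupB) == 1L &&
        identical(object@groupA, object@groupB))
        msgs <- c(msgs, "groupA and groupB must differ")
    if (length(object@pThreshold) != 1L ||
        !is.finite(object@pThreshold) ||
        object@pThreshold <= 0 || object@pThreshold >= 1)
        msgs <- c(msgs, "pThreshold must lie in (0, 1)")
    if (length(object@fcThreshold) != 1L ||
        !is.finite(object@fcThreshold) || object@fcThreshold <= 1)
        msgs <- c(msgs, "fcThreshold must be > 1 (linear scale)")
    if (length(msgs)) msgs else TRUE
})

#' Construct a ComparisonSpec
#'
#' @param groupA,groupB Group labels to compare (`groupA` vs `groupB`).
#' @param pThreshold Gene-level p-value threshold (default 0.01).
#' @param fcThreshold Linear fold-change threshold (default 1.5).
#' @return A [ComparisonSpec-class] object.
#' @export
#' @examples
#' ComparisonSpec("FPOS_GML", "CTRL")
ComparisonSpec <- function(groupA, groupB, pThreshold = 0.01,
                           fcThreshold = 1.5) {
    new("ComparisonSpec", groupA = as.character(groupA),
        groupB = as.character(groupB),
        pThreshold = as.numeric(pThreshold),
        fcThreshold = as.numeric(fcThreshold))
}

setMethod("show", "ComparisonSpec", function(object) {
    cat(sprintf("ComparisonSpec: %s vs %s (p < %g, |FC| >= %g)\n",
        object@groupA, object@groupB, object@pThreshold,
        object@fcThreshold))
})

#' GeneSetCollection: named gene sets
#'
#' A light-weight container for named gene sets as read from a GMT file.
#' Set names are unique, members are character gene identifiers, and every
#' set is non-empty.
#'
#' @slot sets Named list of character vectors of member gene ids.
#' @slot descriptions Named character vector, one free-text description per
#'   set (possibly empty strings).
#' @name GeneSetCollection-class
#' @aliases GeneSetCollection-class
#' @exportClass GeneSetCollection
setClass("GeneSetCollection",
    representation(sets = "list", descriptions = "character")
)

setValidity("GeneSetCollection", function(object) {
    msgs <- character()
    nm <- names(object@sets)
    if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
        msgs <- c(msgs, "set names must be present and unique")
    if (!all(vapply(object@sets, is.character, logical(1))))
        msgs <- c(msgs, "set members must be character vectors")
    if (any(lengths(object@sets) == 0L))
        msgs <- c(msgs, "empty gene sets are not allowed")
    if (length(object@descriptions) != length(object@sets))
        msgs <- c(msgs, "one description per set required")
    if (length(msgs)) msgs else TRUE
})

#' Construct a GeneSetCollection
#'
#' @param sets Named list of character vectors of gene identifiers.
#' @param descriptions Optional character vector of per-set descriptions.
#' @return A [GeneSetCollection-class].
#' @export
#' @examples
#' GeneSetCollection(list(setA = c("G1", "G2"), setB = c("G2", "G3", "G4")))
GeneSetCollection <- function(sets, descriptions = NULL) {
    if (is.null(descriptions))
        descriptions <- rep("", length(sets))
    descriptions <- setNames(as.character(descriptions), names(sets))
    new("GeneSetCollection", sets = sets, descriptions = descriptions)
}

#' @describeIn GeneSetCollection-class Number of sets.
#' @param x A `GeneSetCollection`.
#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@sets))

#' @describeIn GeneSetCollection-class Set names.
#' @export
setMethod("names", "GeneSetCollection", function(x) names(x@sets))

#' @describeIn GeneSetCollection-class Extract one set's members.
#' @param i Set name or index.
#' @export
setMethod("[[", "GeneSetCollection", function(x, i) x@sets[[i]])

#' Member lists of a GeneSetCollection
#'
#' @param x A [GeneSetCollection-class].
#' @return The named list of member vectors.
#' @export
geneSets <- function(x) {
    stopifnot(is(x, "GeneSetCollection"))
    x@sets
}

setMethod("show", "GeneSetCollection", function(object) {
    cat(sprintf("GeneSetCollection with %d sets (sizes %s)\n",
        length(object@sets),
        paste(range(lengths(object@sets)), collapse = "-")))
})

#' RvmFit: fitted random-variance model hyperparameters
#'
#' The hierarchical variance model shares information across genes by
#' assuming gene-specific inverse variances are gamma-distributed with shape
#' `a` and scale `b`; under it, the scaled observed residual variance
#' `s^2 * a * b` follows an F(d, 2a) distribution across genes. The fitted
#' `a` and `b` drive variance shrinkage and augment the t-test degrees of
#' freedom to `d + 2a`.
#'
#' @slot a Fitted gamma shape (> 0).
#' @slot b Fitted gamma scale (> 0).
#' @slot d Residual degrees of freedom of the per-gene variances.
#' @slot logLik Maximised log-likelihood.
#' @slot converged Logical optimiser convergence flag.
#' @slot nGenes Number of genes used in the fit.
#' @name RvmFit-class
#' @aliases RvmFit-class
#' @exportClass RvmFit
setClass("RvmFit",
    representation(a = "numeric", b = "numeric", d = "numeric",
        logLik = "numeric", converged = "logical", nGenes = "integer")
)

setValidity("RvmFit", function(object) {
    msgs <- character()
    if (object@a <= 0 || object@b <= 0)
        msgs <- c(msgs, "a and b must be positive")
    if (object@d < 1)
        msgs <- c(msgs, "residual degrees of freedom d must be >= 1")
    if (length(msgs)) msgs else TRUE
})

#' @describeIn RvmFit-class Fitted gamma shape hyperparameter.
#' @param fit An `RvmFit`.
#' @export
rvmShape <- function(fit) { stopifnot(is(fit, "RvmFit")); fit@a }

#' @describeIn RvmFit-class Fitted gamma scale hyperparameter.
#' @export
rvmScale <- function(fit) { stopifnot(is(fit, "RvmFit")); fit@b }

#' @describeIn RvmFit-class Residual degrees of freedom used in the fit.
#' @export
residualDf <- function(fit) { stopifnot(is(fit, "RvmFit")); fit@d }

#' @describeIn RvmFit-class Moderated degrees of freedom `d + 2a`.
#' @export
moderatedDf <- function(fit) { stopifnot(is(fit, "RvmFit")); fit@d + 2 * fit@a }

setMethod("show", "RvmFit", function(object) {
    cat(sprintf(
        "RvmFit: a = %.4g, b = %.4g (d = %g, moderated df = %.2f)\n",
        object@a, object@b, object@d, object@d + 2 * object@a))
    cat(sprintf("  logLik = %.2f over %d genes; converged: %s\n",
        object@logLik, object@nGenes, object@converged))
})

#' DegSet: significant genes of one comparison, split by direction
#'
#' @slot comparison Label of the comparison ("A_vs_B").
#' @slot up,down Character vectors of up- and down-regulated significant
#'   genes; disjoint by construction.
#' @name DegSet-class
#' @aliases DegSet-class
#' @exportClass DegSet
setClass("DegSet",
    representation(comparison = "character", up = "character",
        down = "character")
)

setValidity("DegSet", function(object) {
    if (length(intersect(object@up, object@down)))
        "up and down gene lists must be disjoint"
    else TRUE
})

#' @describeIn DegSet-class Up-regulated significant genes.
#' @param x A `DegSet`.
#' @export
upGenes <- function(x) { stopifnot(is(x, "DegSet")); x@up }

#' @describeIn DegSet-class Down-regulated significant genes.
#' @export
downGenes <- function(x) { stopifnot(is(x, "DegSet")); x@down }

#' @describeIn DegSet-class All significant genes (union of up and down).
#' @export
degGenes <- function(x) { stopifnot(is(x, "DegSet")); c(x@up, x@down) }

#' @describeIn DegSet-class Total number of significant genes.
#' @export
setMethod("length", "DegSet", function(x) length(x@up) + length(x@down))

setMethod("show", "DegSet", function(object) {
    cat(sprintf("DegSet %s: %d genes (%d up, %d down)\n",
        object@comparison, length(object@up) + length(object@down),
        length(object@up), length(object@down)))
})
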