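#' Uncentered Pearson correlation between matrix rows
#'
#' The uncentered (cosine-like) correlation
#' `r_u(x, y) = sum(x*y) / sqrt(sum(x^2) * sum(y^2))`, the similarity
#' behind classic expression-heatmap clustering. Undefined for all-zero
#' rows, which raise an error naming the row.
#'
#' @param x Numeric matrix; rows are the items being compared.
#' @return Symmetric matrix of pairwise uncentered correlations.
#' @export
#' @examples
#' uncenteredCor(rbind(a = c(1, 2), b = c(2, 4), c = c(1, 0)))
uncenteredCor <- function(x) {
    x <- as.matrix(x)
    ss <- rowSums(x^2)
    if (any(ss == 0)) {
        bad <- rownames(x)[ss == 0]
        if (is.null(bad)) bad <- which(ss == 0)
        stop("uncentered correlation undefined for all-zero row: ",
             bad[1L])
    }
    tcrossprod(x) / sqrt(outer(ss, ss))
}

#' Average-linkage hierarchical clustering with the uncentered metric
#'
#' Agglomerates matrix rows using distance `1 - r_u` (see
#' [uncenteredCor()]) and unweighted average linkage, with a deterministic
#' tie-break: among minimum-distance pairs, the pair with the lowest
#' indices (lexicographically) merges first. Average linkage is reducible,
#' so merge heights are non-decreasing.
#'
#' @param x Numeric matrix with at least 2 rows; rows are clustered.
#' @return An object of class `hclust` (merge matrix, heights, leaf
#'   `order`, `labels`), plottable with the base tools.
#' @export
#' @examples
#' m <- rbind(a = c(1, 2, 3), b = c(2, 4, 6), c = c(3, 1, 0),
#'            d = c(-1, 2, 1))
#' hc <- hierarchicalCluster(m)
#' hc$merge
hierarchicalCluster <- function(x) {
    x <- as.matrix(x)
    n <- nrow(x)
    if (n < 2L)
        stop("need at least 2 rows to cluster")
    labels <- rownames(x)
    if (is.null(labels)) labels <- as.character(seq_len(n))
    D <- 1 - uncenteredCor(x)
    diag(D) <- Inf
    active <- seq_len(n)            # position -> current cluster
    id <- -seq_len(n)               # hclust code of each active cluster
    size <- rep(1L, n)
    merge <- matrix(0L, n - 1L, 2L)
    height <- numeric(n - 1L)
    for (step in seq_len(n - 1L)) {
        m <- min(D)
        cand <- which(D == m, arr.ind = TRUE)
        cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
        cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]
        i <- cand[1L, 1L]; j <- cand[1L, 2L]
        merge[step, ] <- c(id[i], id[j])
        height[step] <- m
        # unweighted average linkage (UPGMA) update into slot i
        newRow <- (size[i] * D[i, ] + size[j] * D[j, ]) /
            (size[i] + size[j])
        D[i, ] <- newRow
        D[, i] <- newRow
        D[i, i] <- Inf
        D[j, ] <- Inf
        D[, j] <- Inf
        size[i] <- size[i] + size[j]
        size[j] <- 0L
        id[i] <- step
        id[j] <- NA_integer_
    }
    order <- .leafOrder(merge, n)
    structure(list(merge = merge, height = height, order = order,
        labels = labels, method = "average",
        dist.method = "uncentered-pearson", call = match.call()),
        class = "hclust")
}

.leafOrder <- function(merge, n) {
    expand <- function(k) {
        if (k < 0L) return(-k)
        c(expand(merge[k, 1L]), expand(merge[k, 2L]))
    }
    expand(nrow(merge))
}
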