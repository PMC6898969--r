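# Independent brute-force oracles used to validate the implementations.

# O(n^3) average-linkage oracle: keeps every cluster's member rows and
# recomputes all pairwise mean distances from the original distance matrix
# at every merge (no Lance-Williams shortcut). Mirrors the contract:
# merged cluster occupies the lower slot; ties broken by lowest slot pair.
bruteAvgLink <- function(x) {
  D0 <- 1 - cortexMS::uncenteredCor(x)
  n <- nrow(x)
  members <- as.list(seq_len(n))
  id <- -seq_len(n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    best <- c(NA, NA); bestD <- Inf
    for (i in seq_len(n - 1L)) {
      if (is.null(members[[i]])) next
      for (j in (i + 1L):n) {
        if (is.null(members[[j]])) next
        dij <- mean(D0[members[[i]], members[[j]]])
        if (dij < bestD - 1e-12) { bestD <- dij; best <- c(i, j) }
      }
    }
    i <- best[1L]; j <- best[2L]
    merge[step, ] <- c(id[i], id[j])
    height[step] <- bestD
    members[[i]] <- c(members[[i]], members[[j]])
    members[j] <- list(NULL)
    id[i] <- step
  }
  list(merge = merge, height = height)
}

# Exhaustive Mann-Whitney two-sided p: enumerate all group assignments of
# the combined sample and tally U statistics.
enumMannWhitney <- function(a, b) {
  pooled <- c(a, b)
  m <- length(a); n <- length(b)
  combs <- utils::combn(m + n, m)
  uFor <- function(idx) {
    aa <- pooled[idx]; bb <- pooled[-idx]
    sum(outer(aa, bb, ">")) + 0.5 * sum(outer(aa, bb, "=="))
  }
  uNull <- apply(combs, 2L, uFor)
  uObs <- uFor(seq_len(m))
  pLow <- mean(uNull <= uObs)
  pHigh <- mean(uNull >= uObs)
  min(1, 2 * min(pLow, pHigh))
}

# Per-gene membership-vector tally oracle for the Venn overlap table.
tallyOverlap <- function(sets) {
  genes <- unique(unlist(sets))
  pat <- vapply(genes, function(g)
    paste(as.integer(vapply(sets, function(s) g %in% s, logical(1))),
          collapse = ""), character(1))
  table(pat)
}

# Small labeled experiment with explicit values, for deterministic tests.
makeTinyExperiment <- function(mat, groups, cases = NULL) {
  if (is.null(cases)) cases <- paste0("K", seq_along(groups))
  sheet <- data.frame(sample_id = colnames(mat), group = groups,
                      case_id = cases)
  cortexMS::msExperiment(mat, sheet)
}
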