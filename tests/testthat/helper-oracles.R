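# Independent reference implementations used to cross-check the package.

# Brute-force greedy closest-pair merging: recomputes the full pairwise
# distance list at every iteration instead of exploiting sortedness.
# Tie-break mirrors the documented rule: among minimal-gap pairs, the one
# with the smaller lower value merges first.
brute_cluster <- function(logS, weight, d, inclusive = FALSE) {
  v <- logS
  w <- weight
  repeat {
    n <- length(v)
    if (n == 1L) break
    best <- NULL
    for (a in seq_len(n - 1L)) {
      for (b in (a + 1L):n) {
        gap <- abs(v[a] - v[b])
        lower <- min(v[a], v[b])
        if (is.null(best) || gap < best$gap ||
            (gap == best$gap && lower < best$lower)) {
          best <- list(a = a, b = b, gap = gap, lower = lower)
        }
      }
    }
    hit <- if (inclusive) best$gap <= d else best$gap < d
    if (!hit) break
    wm <- w[best$a] + w[best$b]
    vm <- (w[best$a] * v[best$a] + w[best$b] * v[best$b]) / wm
    keep <- setdiff(seq_len(n), c(best$a, best$b))
    v <- c(v[keep], vm)
    w <- c(w[keep], wm)
  }
  o <- order(v)
  data.frame(logS = v[o], weight = w[o])
}

# Double-loop redundancy oracle: for every record of dataset i, scan every
# record of dataset j directly.
brute_redundancy <- function(datasets, tol = 0.01) {
  n <- length(datasets)
  ids <- vapply(datasets, function(d) d$id, character(1))
  A <- B <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    ri <- datasets[[i]]$records
    for (j in seq_len(n)) {
      rj <- datasets[[j]]$records
      same <- diff <- 0L
      for (k in seq_len(nrow(ri))) {
        hit_same <- FALSE
        hit_diff <- FALSE
        for (l in seq_len(nrow(rj))) {
          if (i == j && k == l) next
          if (ri$smiles[k] != rj$smiles[l]) next
          if (abs(ri$logS[k] - rj$logS[l]) <= tol) hit_same <- TRUE
          else hit_diff <- TRUE
        }
        same <- same + hit_same
        diff <- diff + hit_diff
      }
      A[i, j] <- 100 * same / nrow(ri)
      B[i, j] <- 100 * diff / nrow(ri)
    }
  }
  list(A = A, B = B)
}
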