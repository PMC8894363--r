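#' Inter-dataset redundancy matrices
#'
#' For an ordered list of datasets, computes the two asymmetric percentage
#' matrices: `A[i, j]` is the percent of records in dataset i whose
#' molecule can be found in dataset j with an identical solubility value
#' (|difference| <= `tol`), `B[i, j]` the same with a different value
#' (|difference| > `tol`). Membership, not multiplicity, in j is what
#' counts: a record of i contributes at most once per cell, but can
#' contribute to both A and B when the molecule has several records in j —
#' so `A[i, j] + B[i, j]` can exceed 100. A record never matches itself, so
#' the diagonal of B measures intra-dataset value conflicts and, after
#' within-dataset normalization, `A[i, i]` is 0.
#'
#' @param datasets List of standardized, normalized `solubility_dataset`
#'   objects with distinct ids.
#' @param tol Identity tolerance (default 0.01).
#' @return An object of class `redundancy_matrices`: list with `ids` and
#'   percentage matrices `A` and `B` (dimnames = ids).
#' @export
redundancy_matrices <- function(datasets, tol = 0.01) {
  stopifnot(is.list(datasets), length(datasets) >= 1L)
  ids <- vapply(datasets, function(d) d$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate dataset ids", call. = FALSE)
  n <- length(datasets)
  A <- B <- matrix(0, n, n, dimnames = list(ids, ids))
  by_mol <- lapply(datasets, function(d) split(d$records$logS,
                                              d$records$smiles))
  for (i in seq_len(n)) {
    ri <- datasets[[i]]$records
    ni <- nrow(ri)
    if (ni == 0L) next
    for (j in seq_len(n)) {
      vals_j <- by_mol[[j]]
      same <- diff <- logical(ni)
      mol_idx <- match(ri$smiles, names(vals_j))
      # position of each record within its own molecule group (self-exclusion)
      for (k in seq_len(ni)) {
        mi <- mol_idx[k]
        if (is.na(mi)) next
        vj <- vals_j[[mi]]
        if (i == j) {
          # drop one occurrence equal to this record's own value
          self <- match(ri$logS[k], vj)
          vj <- vj[-self]
        }
        if (!length(vj)) next
        dlt <- abs(vj - ri$logS[k])
        same[k] <- any(dlt <= tol)
        diff[k] <- any(dlt > tol)
      }
      A[i, j] <- 100 * sum(same) / ni
      B[i, j] <- 100 * sum(diff) / ni
    }
  }
  structure(list(ids = ids, A = A, B = B), class = "redundancy_matrices")
}

#' @export
print.redundancy_matrices <- function(x, ...) {
  cat("Same-value redundancy A[i, j] (%):\n")
  print(round(x$A, 2))
  cat("Different-value redundancy B[i, j] (%):\n")
  print(round(x$B, 2))
  invisible(x)
}

#' Write redundancy matrices as two CSV tables
#' @param x A `redundancy_matrices` object.
#' @param path_same,path_diff Output CSV paths for A and B.
#' @return Invisibly, the two paths.
#' @export
write_redundancy <- function(x, path_same, path_diff) {
  stopifnot(inherits(x, "redundancy_matrices"))
  utils::write.csv(round(x$A, 2), path_same)
  utils::write.csv(round(x$B, 2), path_diff)
  invisible(c(path_same, path_diff))
}
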