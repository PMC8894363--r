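#' Merge identical-valued records of one molecule
#'
#' Two records of the same molecule count as identical when their LogS
#' values differ by at most `tol` (0.01 LogS by default). Identical values
#' are merged greedily by [partial_cluster()] with the gap set to the
#' tolerance (inclusive boundary): each merged record's logS is the
#' weight-weighted mean and its weight the sum, so weight mass is
#' conserved.
#'
#' @param records data.frame of records sharing one standardized SMILES.
#' @param tol Identity tolerance (default 0.01).
#' @return data.frame of merged records (metadata columns taken from the
#'   first record of each merged cluster), sorted by logS.
#' @export
merge_identical <- function(records, tol = 0.01) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L, tol > 0)
  if (length(unique(records$smiles)) != 1L) {
    stop("merge_identical expects records of a single molecule",
         call. = FALSE)
  }
  merged <- partial_cluster(records$logS, records$weight, d = tol,
                            inclusive = TRUE)
  # carry metadata from the input record nearest each merged value
  idx <- vapply(merged$logS, function(v) which.min(abs(records$logS - v)),
                integer(1))
  out <- records[idx, , drop = FALSE]
  out$logS <- merged$logS
  out$weight <- merged$weight
  rownames(out) <- NULL
  out
}

#' Rescale each molecule's record weights to sum to one
#'
#' Repetitive-record normalization: after identical-value merging, the
#' weights of a molecule's surviving records are rescaled proportionally so
#' they total exactly 1.0, i.e. each distinct value is weighted by its
#' frequency of occurrence. Prevents repeated molecules from dominating
#' training.
#'
#' @param ds A `solubility_dataset`.
#' @return The dataset with per-molecule weights summing to 1 (within
#'   1e-12).
#' @export
normalize_molecule_weights <- function(ds) {
  stopifnot(inherits(ds, "solubility_dataset"))
  rec <- ds$records
  if (nrow(rec)) {
    totals <- tapply(rec$weight, rec$smiles, sum)
    if (any(totals <= 0)) {
      stop("molecule with zero total weight cannot be normalized",
           call. = FALSE)
    }
    rec$weight <- rec$weight / as.numeric(totals[rec$smiles])
  }
  solubility_dataset(ds$id, rec, quality_weight = ds$quality_weight,
                     group = ds$group)
}

#' Within-dataset repetitive-record normalization
#'
#' [merge_identical()] per molecule followed by
#' [normalize_molecule_weights()]: afterwards no two records of a molecule
#' differ by <= `tol` and every molecule's weights sum to 1.0. The pass is
#' idempotent.
#'
#' @param ds A standardized, filtered `solubility_dataset`.
#' @param tol Identity tolerance (default 0.01).
#' @return The normalized `solubility_dataset`.
#' @export
normalize_dataset <- function(ds, tol = 0.01) {
  stopifnot(inherits(ds, "solubility_dataset"))
  rec <- ds$records
  if (nrow(rec)) {
    pieces <- lapply(split(rec, rec$smiles), merge_identical, tol = tol)
    # preserve first-appearance order of molecules
    first <- vapply(split(seq_len(nrow(rec)), rec$smiles), min, integer(1))
    rec <- do.call(rbind, pieces[order(first[names(pieces)])])
    rownames(rec) <- NULL
  }
  ds <- solubility_dataset(ds$id, rec, quality_weight = ds$quality_weight,
                           group = ds$group)
  normalize_molecule_weights(ds)
}
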