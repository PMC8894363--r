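#' Standardize SMILES strings
#'
#' Produces one unique canonical SMILES per molecule via the fixed pipeline
#' parse -> sanitize -> largest-fragment keep -> charge neutralization ->
#' canonical output (the MolVS default flow, executed by RDKit). Two inputs
#' denoting the same structure map to the same output, and the function is
#' idempotent on its own output. Unparseable input yields `NA` rather than
#' an error, so callers can tally removals.
#'
#' @param smiles Character vector of SMILES.
#' @return Character vector of standardized SMILES, `NA` where
#'   standardization failed.
#' @examples
#' \dontrun{
#' standardize_smiles(c("OCC", "CCO"))  # both "CCO"
#' }
#' @export
standardize_smiles <- function(smiles) {
  if (!length(smiles)) return(character(0))
  chem_properties(smiles)$canonical
}

#' Standardize every record of a dataset
#'
#' Records whose SMILES fail standardization are removed (never a hard
#' stop); the rest are rewritten to canonical form with order preserved.
#'
#' @param ds A `solubility_dataset`.
#' @return A list with `dataset` (the standardized `solubility_dataset`)
#'   and `report`: `n_input`, `n_failed`, `failed_indices`, and
#'   `canonical_map` (named character vector original -> standard SMILES
#'   for surviving records).
#' @export
standardize_dataset <- function(ds) {
  stopifnot(inherits(ds, "solubility_dataset"))
  n_input <- nrow(ds$records)
  if (n_input == 0L) {
    return(list(dataset = ds,
                report = list(n_input = 0L, n_failed = 0L,
                              failed_indices = integer(0),
                              canonical_map = character(0))))
  }
  canon <- standardize_smiles(ds$records$smiles)
  failed <- which(is.na(canon))
  keep <- setdiff(seq_len(n_input), failed)
  records <- ds$records[keep, , drop = FALSE]
  cmap <- stats::setNames(canon[keep], ds$records$smiles[keep])
  records$smiles <- canon[keep]
  rownames(records) <- NULL
  out <- solubility_dataset(ds$id, records,
                            quality_weight = ds$quality_weight,
                            group = ds$group)
  list(dataset = out,
       report = list(n_input = n_input, n_failed = length(failed),
                     failed_indices = failed,
                     canonical_map = cmap[!duplicated(names(cmap))]))
}
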