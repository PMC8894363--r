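#' May one dataset be curated with another?
#'
#' The curation schedule over quality groups: a dataset may be curated with
#' datasets of its own group carrying an equal or higher quality weight
#' (inter-group curation in the published nomenclature), and a low-quality
#' dataset may additionally be curated with any high-quality dataset
#' (intra-group curation). No other operations are allowed; a kinetic
#' dataset has no thermodynamic partners and can only be curated with
#' itself.
#'
#' @param target,source `solubility_dataset` objects carrying `group` and
#'   (for thermodynamic sets) `quality_weight`.
#' @return `TRUE` or `FALSE`.
#' @export
is_allowed_source <- function(target, source) {
  stopifnot(inherits(target, "solubility_dataset"),
            inherits(source, "solubility_dataset"))
  if (identical(target$id, source$id)) return(TRUE)
  if (target$group == "kinetic" || source$group == "kinetic") return(FALSE)
  if (target$group == source$group) {
    return(source$quality_weight >= target$quality_weight)
  }
  source$group == "high" && target$group == "low"
}

#' Effective weight of a record within its dataset
#'
#' The final quality weight of a record is the record's own weight
#' multiplied by the assigned weight of its dataset.
#'
#' @param weight Record weight(s).
#' @param ds The `solubility_dataset` the record(s) belong to.
#' @return Numeric effective weight(s).
#' @export
effective_weight <- function(weight, ds) {
  stopifnot(inherits(ds, "solubility_dataset"))
  if (is.null(ds$quality_weight)) {
    stop("kinetic dataset '", ds$id,
         "' has no quality weight and cannot serve as a weighted source",
         call. = FALSE)
  }
  weight * ds$quality_weight
}

#' Cap per-molecule total weights at a threshold
#'
#' Accumulated curated weights are truncated: for each molecule whose
#' weights total W > threshold, every record weight is scaled by
#' threshold / W (relative proportions preserved); molecules below the
#' threshold are left unchanged and thereby devalued relative to capped,
#' multiply-attested molecules.
#'
#' @param records data.frame with `smiles` and `weight` columns.
#' @param threshold Positive cap (default 1.0).
#' @return The records with capped weights.
#' @export
apply_weight_cap <- function(records, threshold = 1.0) {
  stopifnot(is.data.frame(records), threshold > 0)
  if (!nrow(records)) return(records)
  totals <- tapply(records$weight, records$smiles, sum)
  scale <- pmin(1, threshold / as.numeric(totals[records$smiles]))
  records$weight <- records$weight * scale
  records
}

#' Curate a dataset with scheduled source datasets
#'
#' The three-step cross-dataset curation workflow:
#' (1) pool the target with its sources and keep only records whose
#' molecule occurs in the target; (2) per molecule, convert record weights
#' to effective weights (record weight x dataset quality weight) and merge
#' close values with [partial_cluster()] at gap `d`; (3) cap each
#' molecule's total weight at the configured threshold. Every source must
#' be allowed by the curation schedule ([is_allowed_source()]).
#'
#' A kinetic target is only curated against itself (its records enter with
#' their own weights, since no dataset-level quality weight exists).
#'
#' @param target A standardized, filtered, normalized `solubility_dataset`.
#' @param sources List of allowed source datasets (the target itself may be
#'   included or not; its records always participate).
#' @param cfg A [curation_config()].
#' @return A curated `solubility_dataset` with id `<target id>.cure`;
#'   attribute `audit` carries cluster counts and weight mass before/after
#'   the cap.
#' @export
curate_dataset <- function(target, sources = list(), cfg = curation_config()) {
  stopifnot(inherits(target, "solubility_dataset"), is.list(sources))
  for (s in sources) {
    if (!is_allowed_source(target, s)) {
      stop("curation schedule violation: '", s$id,
           "' is not an allowed source for '", target$id, "'",
           call. = FALSE)
    }
  }
  sources <- Filter(function(s) !identical(s$id, target$id), sources)

  pool_one <- function(ds) {
    rec <- ds$records[, c("smiles", "logS", "weight")]
    qw <- if (is.null(ds$quality_weight)) 1.0 else ds$quality_weight
    rec$weight <- rec$weight * qw
    rec
  }
  pooled <- do.call(rbind, lapply(c(list(target), sources), pool_one))
  target_mols <- unique(target$records$smiles)
  pooled <- pooled[pooled$smiles %in% target_mols, , drop = FALSE]
  pooled <- pooled[pooled$weight > 0, , drop = FALSE]
  if (!nrow(pooled)) stop("curation produced an empty dataset", call. = FALSE)

  mass_before <- sum(pooled$weight)
  groups <- split(pooled, pooled$smiles)
  clustered <- lapply(groups, function(g) {
    cl <- partial_cluster(g$logS, g$weight, d = cfg$merge_gap_d)
    data.frame(smiles = g$smiles[1], logS = cl$logS, weight = cl$weight,
               stringsAsFactors = FALSE)
  })
  first <- vapply(split(seq_len(nrow(pooled)), pooled$smiles), min,
                  integer(1))
  rec <- do.call(rbind, clustered[order(first[names(clustered)])])
  rownames(rec) <- NULL

  rec <- apply_weight_cap(rec, cfg$weight_cap_threshold)
  out <- solubility_dataset(paste0(target$id, ".cure"), rec,
                            quality_weight = target$quality_weight,
                            group = target$group)
  attr(out, "audit") <- list(
    n_pooled = nrow(pooled),
    n_molecules = length(groups),
    n_clusters = nrow(rec),
    weight_mass_before_cap = mass_before,
    weight_mass_after_cap = sum(rec$weight)
  )
  out
}
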