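#' Does a record pass the experiment-environment window?
#'
#' True iff the temperature (when present) lies within 25 +/- 5 degrees C
#' and the pH (when present) lies within 7 +/- 1. Absent fields never
#' disqualify a record: most thermodynamic sources carry no environment
#' columns yet are retained.
#'
#' @param records data.frame of records (columns `temperature` / `pH`
#'   optional, `NA` treated as absent).
#' @param cfg A [curation_config()].
#' @return Logical vector, one element per record.
#' @export
passes_environment <- function(records, cfg = curation_config()) {
  n <- nrow(records)
  ok <- rep(TRUE, n)
  if ("temperature" %in% names(records)) {
    t <- records$temperature
    ok <- ok & (is.na(t) | abs(t - cfg$temp_center) <= cfg$temp_halfwidth)
  }
  if ("pH" %in% names(records)) {
    p <- records$pH
    ok <- ok & (is.na(p) | abs(p - cfg$ph_center) <= cfg$ph_halfwidth)
  }
  ok
}

#' Does a molecule contain a blacklisted element?
#'
#' Matching is on parsed atoms of the standardized structure, never on
#' SMILES substrings.
#'
#' @param smiles Character vector of standardized SMILES.
#' @param blacklist Element symbols; defaults to
#'   [default_element_blacklist()].
#' @return Logical vector.
#' @export
contains_blacklisted_element <- function(smiles,
                                         blacklist = default_element_blacklist()) {
  props <- chem_properties(smiles)
  if (any(!props$ok)) {
    stop("unparseable SMILES passed to element filter: ",
         paste(utils::head(smiles[!props$ok], 3), collapse = ", "),
         call. = FALSE)
  }
  vapply(strsplit(props$elements, " ", fixed = TRUE),
         function(el) any(el %in% blacklist), logical(1))
}

#' Does a molecule contain an SF5/SF6 group?
#'
#' True iff some sulfur atom is bonded to at least five fluorine atoms;
#' such groups are rarely used in drug design and are cleaned out.
#'
#' @param smiles Character vector of standardized SMILES.
#' @return Logical vector.
#' @export
contains_forbidden_group <- function(smiles) {
  props <- chem_properties(smiles)
  if (any(!props$ok)) {
    stop("unparseable SMILES passed to group filter", call. = FALSE)
  }
  props$sf56
}

#' Apply environment and toxicity filtering to a dataset
#'
#' Removes records outside the experiment-environment window (or flags
#' them, under `env_policy = "keep_unfiltered"`, via an `env_flag` extras
#' column) and always removes records whose molecule carries a blacklisted
#' element or an SF5/SF6 group. A record failing several predicates is
#' counted once, in the order environment, element, group.
#'
#' @param ds A standardized `solubility_dataset`.
#' @param cfg A [curation_config()].
#' @return A list with `dataset` and `report` (`n_removed_env`,
#'   `n_removed_element`, `n_removed_group`, `removed_reasons` named by
#'   input record index).
#' @export
filter_dataset <- function(ds, cfg = curation_config()) {
  stopifnot(inherits(ds, "solubility_dataset"))
  rec <- ds$records
  n <- nrow(rec)
  env_ok <- passes_environment(rec, cfg)
  bad_elem <- contains_blacklisted_element(rec$smiles, cfg$element_blacklist)
  bad_group <- contains_forbidden_group(rec$smiles)

  reason <- rep(NA_character_, n)
  reason[bad_group] <- "forbidden_group"
  reason[bad_elem] <- "blacklisted_element"
  if (cfg$env_policy == "remove") reason[!env_ok] <- "environment"

  removed <- which(!is.na(reason))
  keep <- setdiff(seq_len(n), removed)
  out_rec <- rec[keep, , drop = FALSE]
  if (cfg$env_policy == "keep_unfiltered") {
    out_rec$env_flag <- ifelse(env_ok[keep], "", "off_window")
  }
  rownames(out_rec) <- NULL
  report <- list(
    n_removed_env = sum(reason == "environment", na.rm = TRUE),
    n_removed_element = sum(reason == "blacklisted_element", na.rm = TRUE),
    n_removed_group = sum(reason == "forbidden_group", na.rm = TRUE),
    removed_reasons = stats::setNames(reason[removed], removed)
  )
  list(dataset = solubility_dataset(ds$id, out_rec,
                                    quality_weight = ds$quality_weight,
                                    group = ds$group),
       report = report)
}
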