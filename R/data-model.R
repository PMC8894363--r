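#' Construct a solubility dataset
#'
#' The central container of the curation workflow: an ordered table of
#' solubility records plus a dataset-level quality weight and quality group.
#' Records are rows of a data.frame with at least `smiles` (character),
#' `logS` (numeric, log10 mol/L) and `weight` (numeric, >= 0). Optional
#' columns `temperature` (degrees C) and `pH` feed the environment filter;
#' any further character columns (e.g. `star_flag`, `group`, `comment`)
#' are carried opaquely.
#'
#' @param id Dataset identifier string.
#' @param records data.frame of records; a `source_id` column is added/
#'   overwritten with `id`. Missing `weight` defaults to 1.0 per record.
#' @param quality_weight Dataset quality weight in `[0, 1]`, or `NULL` for
#'   kinetic datasets (which carry no thermodynamic quality weight).
#' @param group Quality group: `"high"`, `"low"` or `"kinetic"`.
#' @return An object of class `solubility_dataset`.
#' @export
solubility_dataset <- function(id, records,
                               quality_weight = NULL,
                               group = c("high", "low", "kinetic")) {
  group <- match.arg(group)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.data.frame(records))
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  for (col in c("smiles", "logS")) {
    if (!col %in% names(records)) {
      stop("records must have a '", col, "' column", call. = FALSE)
    }
  }
  if (!"weight" %in% names(records)) records$weight <- rep(1.0, nrow(records))
  records$smiles <- as.character(records$smiles)
  records$logS <- as.numeric(records$logS)
  records$weight <- as.numeric(records$weight)
  records$source_id <- rep(id, length.out = nrow(records))
  if (nrow(records)) {
    if (any(!is.finite(records$logS))) {
      stop("all logS values must be finite", call. = FALSE)
    }
    if (any(!is.finite(records$weight) | records$weight < 0)) {
      stop("all record weights must be finite and >= 0", call. = FALSE)
    }
  }
  if (group == "kinetic") {
    if (!is.null(quality_weight)) {
      stop("kinetic datasets carry no quality weight", call. = FALSE)
    }
  } else if (!is.null(quality_weight)) {
    stopifnot(is.numeric(quality_weight), length(quality_weight) == 1L,
              quality_weight >= 0, quality_weight <= 1)
    quality_weight <- as.numeric(quality_weight)
  }
  rownames(records) <- NULL
  structure(
    list(id = id, records = records,
         quality_weight = quality_weight, group = group),
    class = "solubility_dataset"
  )
}

#' @export
print.solubility_dataset <- function(x, ...) {
  qw <- if (is.null(x$quality_weight)) "none" else
    format(x$quality_weight, digits = 4)
  cat(sprintf(
    "<solubility_dataset '%s'> %d records, %d molecules, group=%s, weight=%s\n",
    x$id, nrow(x$records), length(unique(x$records$smiles)), x$group, qw))
  invisible(x)
}

#' Number of records in a solubility dataset
#' @param x A `solubility_dataset`.
#' @return Integer record count.
#' @export
n_records <- function(x) nrow(x$records)

#' Curation configuration
#'
#' Bundles every tunable of the workflow. Defaults follow the published
#' protocol: records are identical when their LogS values differ by at most
#' 0.01; cross-dataset values merge below a gap of `d = 0.5` LogS; the
#' accepted experiment window is 25 +/- 5 degrees C and pH 7 +/- 1; the
#' per-molecule curated weight total is capped at 1.0.
#'
#' @param identical_tol Identity tolerance in LogS units (default 0.01).
#' @param merge_gap_d Partial-clustering merge gap `d` (default 0.5).
#' @param temp_center,temp_halfwidth Accepted temperature window (25 +/- 5).
#' @param ph_center,ph_halfwidth Accepted pH window (7 +/- 1).
#' @param element_blacklist Character vector of forbidden element symbols;
#'   defaults to [default_element_blacklist()].
#' @param weight_cap_threshold Per-molecule curated weight cap (default 1.0).
#' @param env_policy `"remove"` drops off-window records; `"keep_unfiltered"`
#'   keeps them but flags them (the "ranked low" alternative).
#' @param dataset_weights Optional named numeric map id -> quality weight.
#' @param groups Optional named character map id -> group.
#' @return An object of class `curation_config`.
#' @export
curation_config <- function(identical_tol = 0.01,
                            merge_gap_d = 0.5,
                            temp_center = 25, temp_halfwidth = 5,
                            ph_center = 7, ph_halfwidth = 1,
                            element_blacklist = default_element_blacklist(),
                            weight_cap_threshold = 1.0,
                            env_policy = c("remove", "keep_unfiltered"),
                            dataset_weights = NULL,
                            groups = NULL) {
  env_policy <- match.arg(env_policy)
  stopifnot(identical_tol > 0, merge_gap_d > 0,
            identical_tol < merge_gap_d,
            temp_halfwidth > 0, ph_halfwidth > 0,
            weight_cap_threshold > 0)
  structure(
    list(identical_tol = identical_tol, merge_gap_d = merge_gap_d,
         temp_center = temp_center, temp_halfwidth = temp_halfwidth,
         ph_center = ph_center, ph_halfwidth = ph_halfwidth,
         element_blacklist = unique(element_blacklist),
         weight_cap_threshold = weight_cap_threshold,
         env_policy = env_policy,
         dataset_weights = dataset_weights, groups = groups),
    class = "curation_config"
  )
}

#' Default heavy-metal / metalloid element blacklist
#'
#' The published list, stored as a set (the printed list repeats Ti, Sb and
#' Pt and includes boron); matching is on parsed atoms, never on substrings,
#' so Cl can not trigger C or Li.
#'
#' @return Character vector of element symbols.
#' @export
default_element_blacklist <- function() {
  unique(c("U", "Ge", "Pr", "La", "Dy", "Ti", "Zr", "Rh", "Lu", "Mo", "Sm",
           "Sb", "Nd", "Gd", "Cd", "Ce", "In", "Pt", "As", "Ir", "Ba", "B",
           "Hg", "Se", "Sn", "Fe", "Si", "Al", "Bi", "Pb", "Pd", "Ag", "Au",
           "Cu", "Co", "Ni", "Ru", "Mg", "Zn", "Mn", "Cr", "Ca", "K", "Li"))
}

#' Reference quality weights and groups of the seven source datasets
#'
#' The published weight assignment: AQUA, PHYS, ESOL and OCHEM form the
#' high-quality group, AQSOL and CHEMBL the low-quality group, and KINECT is
#' the kinetic set with no thermodynamic quality weight.
#'
#' @return data.frame with columns `id`, `quality_weight` (`NA` for the
#'   kinetic set) and `group`.
#' @export
solubility_sources <- function() {
  data.frame(
    id = c("AQUA", "PHYS", "ESOL", "OCHEM", "AQSOL", "CHEMBL", "KINECT"),
    quality_weight = c(1.0, 1.0, 1.0, 0.85, 0.4, 0.8, NA_real_),
    group = c("high", "high", "high", "high", "low", "low", "kinetic"),
    stringsAsFactors = FALSE
  )
}
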