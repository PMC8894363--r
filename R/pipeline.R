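#' Run the full curation pipeline
#'
#' Executes standardize -> filter -> normalize -> redundancy -> curate over
#' a configured collection and writes `<target>.cln.csv`,
#' `<target>.cure.csv`, the two redundancy CSV tables and a JSON audit of
#' all counts into `out_dir`.
#'
#' @param config Either the path of a JSON pipeline config or an
#'   equivalent list. Fields: `datasets` — list of
#'   `{id, path, format, quality_weight, group}` entries (or, when calling
#'   from R, ready-made `solubility_dataset` objects); optional `curation`
#'   — named overrides for [curation_config()]; optional `sources` —
#'   explicit source ids for the curation step (default: every dataset the
#'   schedule allows).
#' @param target_id Id of the dataset to curate.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the curated dataset, the redundancy
#'   matrices and the audit list.
#' @export
run_pipeline <- function(config, target_id, out_dir = ".") {
  if (is.character(config)) config <- jsonlite::read_json(config)
  cfg <- do.call(curation_config, config$curation %||% list())
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  datasets <- lapply(config$datasets, function(d) {
    if (inherits(d, "solubility_dataset")) return(d)
    qw <- d$quality_weight
    if (!is.null(qw) && is.na(qw)) qw <- NULL
    read_dataset(d$path, format = d$format %||% "csv", id = d$id,
                 quality_weight = qw, group = d$group %||% "high")
  })
  ids <- vapply(datasets, function(d) d$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate dataset ids", call. = FALSE)
  if (!target_id %in% ids) {
    stop("unknown target dataset: ", target_id, call. = FALSE)
  }

  audit <- list(target = target_id)
  clean <- lapply(datasets, function(ds) {
    st <- standardize_dataset(ds)
    fl <- filter_dataset(st$dataset, cfg)
    nm <- normalize_dataset(fl$dataset, tol = cfg$identical_tol)
    audit[[ds$id]] <<- list(
      n_org = n_records(ds),
      n_failed_standardization = st$report$n_failed,
      n_removed_env = fl$report$n_removed_env,
      n_removed_element = fl$report$n_removed_element,
      n_removed_group = fl$report$n_removed_group,
      n_cln = n_records(nm)
    )
    nm
  })
  names(clean) <- ids

  red <- redundancy_matrices(clean, tol = cfg$identical_tol)
  write_redundancy(red,
                   file.path(out_dir, "redundancy_same.csv"),
                   file.path(out_dir, "redundancy_diff.csv"))

  target <- clean[[target_id]]
  sources <- if (!is.null(config$sources)) {
    lapply(unlist(config$sources), function(sid) {
      if (!sid %in% ids) stop("unknown source dataset: ", sid, call. = FALSE)
      clean[[sid]]
    })
  } else {
    Filter(function(s) is_allowed_source(target, s), clean)
  }
  cured <- curate_dataset(target, sources, cfg)
  audit$curation <- attr(cured, "audit")
  audit$n_cure <- n_records(cured)

  write_dataset(target, file.path(out_dir, paste0(target_id, ".cln.csv")))
  write_dataset(cured, file.path(out_dir, paste0(target_id, ".cure.csv")))
  jsonlite::write_json(audit, file.path(out_dir, "audit.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(cured = cured, redundancy = red, audit = audit,
                 clean = clean))
}
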