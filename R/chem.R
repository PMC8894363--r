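#' @keywords internal
#' @noRd
.chem_cache <- new.env(parent = emptyenv())

#' Locate the python interpreter used for the RDKit bridge
#'
#' The chemistry layer (standardization, atom enumeration, scaffolds, SDF
#' reading) is delegated to RDKit through a batch subprocess. The interpreter
#' is resolved from option `solcure.python`, then env var `SOLCURE_PYTHON`,
#' then `python` / `python3` on PATH.
#' @return Path to the python executable.
#' @keywords internal
python_binary <- function() {
  cand <- getOption("solcure.python", Sys.getenv("SOLCURE_PYTHON", ""))
  if (nzchar(cand)) return(cand)
  for (bin in c("python", "python3")) {
    p <- Sys.which(bin)
    if (nzchar(p)) return(unname(p))
  }
  stop("No python interpreter found; set options(solcure.python = ...)")
}

chem_script <- function() {
  p <- system.file("python", "chem_tools.py", package = "solcure")
  if (!nzchar(p)) stop("chem_tools.py not found in installed package")
  p
}

run_chem_tool <- function(args) {
  out <- suppressWarnings(system2(python_binary(), args,
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop("RDKit helper failed (exit ", status, "):\n",
         paste(out, collapse = "\n"))
  }
  invisible(out)
}

#' Compute chemistry properties for a batch of SMILES
#'
#' One subprocess call per batch of uncached structures; results are cached
#' for the R session, keyed on the input string, so repeated pipeline stages
#' (and test runs within one session) pay the RDKit start-up cost once.
#'
#' @param smiles Character vector of SMILES strings.
#' @return A data.frame with one row per input: `query`, `ok` (logical,
#'   parse + standardization success), `canonical` (standardized canonical
#'   SMILES, `NA` on failure), `elements` (space-separated element symbols),
#'   `sf56` (logical, sulfur bearing >= 5 fluorines), `scaffold`
#'   (Bemis-Murcko scaffold SMILES, `""` for acyclic molecules).
#' @keywords internal
chem_properties <- function(smiles) {
  stopifnot(is.character(smiles))
  missing <- unique(smiles[!vapply(smiles, exists, logical(1),
                                   envir = .chem_cache, inherits = FALSE)])
  missing <- missing[nzchar(missing)]
  if (length(missing)) {
    fin <- tempfile(fileext = ".smi")
    fout <- tempfile(fileext = ".tsv")
    on.exit(unlink(c(fin, fout)), add = TRUE)
    writeLines(missing, fin)
    run_chem_tool(c(chem_script(), "props", fin, fout))
    res <- utils::read.delim(fout, header = FALSE, sep = "\t",
                             quote = "", colClasses = "character",
                             na.strings = NULL)
    if (nrow(res) != length(missing)) {
      stop("RDKit helper returned ", nrow(res), " rows for ",
           length(missing), " inputs")
    }
    for (k in seq_along(missing)) {
      assign(missing[k],
             list(ok = res[k, 1] == "1",
                  canonical = if (res[k, 1] == "1") res[k, 2] else NA_character_,
                  elements = res[k, 3],
                  sf56 = res[k, 4] == "1",
                  scaffold = res[k, 5]),
             envir = .chem_cache)
    }
  }
  rows <- lapply(smiles, function(s) {
    if (!nzchar(s)) {
      return(list(ok = FALSE, canonical = NA_character_, elements = "",
                  sf56 = FALSE, scaffold = ""))
    }
    get(s, envir = .chem_cache, inherits = FALSE)
  })
  data.frame(
    query = smiles,
    ok = vapply(rows, `[[`, logical(1), "ok"),
    canonical = vapply(rows, `[[`, character(1), "canonical"),
    elements = vapply(rows, `[[`, character(1), "elements"),
    sf56 = vapply(rows, `[[`, logical(1), "sf56"),
    scaffold = vapply(rows, `[[`, character(1), "scaffold"),
    stringsAsFactors = FALSE
  )
}
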