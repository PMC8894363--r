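#' Read a solubility dataset from CSV or SDF
#'
#' CSV files must carry at least `Smiles` and `LogS` columns (comma
#' separated, UTF-8, header row, "." decimal); `Weight` is optional and
#' defaults to 1.0 per record. `temperature` / `pH` columns (several common
#' spellings) are mapped to the environment fields; any remaining columns
#' are carried along as opaque extras. Rows whose LogS does not parse as a
#' finite number are skipped and tallied. SDF input is read through RDKit;
#' the LogS value is taken from the first matching property alias.
#'
#' @param path Input file.
#' @param format `"csv"` or `"sdf"`.
#' @param id Dataset identifier.
#' @param quality_weight,group Passed to [solubility_dataset()].
#' @param logS_aliases Property/column names accepted for the LogS value
#'   (SDF; first match wins).
#' @return A `solubility_dataset`; attribute `n_skipped` carries the count
#'   of rows dropped for unparseable LogS.
#' @export
read_dataset <- function(path, format = c("csv", "sdf"), id,
                         quality_weight = NULL, group = "high",
                         logS_aliases = c("LogS", "logS", "LOGS",
                                          "LogS value", "logs")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "csv") {
    read_dataset_csv(path, id, quality_weight, group)
  } else {
    read_dataset_sdf(path, id, quality_weight, group, logS_aliases)
  }
}

find_column <- function(nms, aliases) {
  hit <- which(tolower(nms) %in% tolower(aliases))
  if (length(hit)) hit[1] else 0L
}

read_dataset_csv <- function(path, id, quality_weight, group) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character")
  if (nrow(raw) == 0L) stop("empty dataset: ", path, call. = FALSE)
  i_smi <- find_column(names(raw), "Smiles")
  i_logs <- find_column(names(raw), c("LogS", "LogS value"))
  if (i_smi == 0L) stop("missing required column: Smiles", call. = FALSE)
  if (i_logs == 0L) stop("missing required column: LogS", call. = FALSE)
  i_w <- find_column(names(raw), "Weight")
  i_t <- find_column(names(raw), c("temperature", "temp", "Temperature"))
  i_ph <- find_column(names(raw), c("pH", "ph", "pH value"))

  logS <- suppressWarnings(as.numeric(raw[[i_logs]]))
  keep <- is.finite(logS) & nzchar(raw[[i_smi]])
  n_skipped <- sum(!keep)

  rec <- data.frame(smiles = raw[[i_smi]][keep], logS = logS[keep],
                    stringsAsFactors = FALSE)
  rec$weight <- if (i_w > 0L) {
    w <- suppressWarnings(as.numeric(raw[[i_w]][keep]))
    ifelse(is.finite(w), w, 1.0)
  } else 1.0
  if (i_t > 0L) {
    rec$temperature <- suppressWarnings(as.numeric(raw[[i_t]][keep]))
  }
  if (i_ph > 0L) rec$pH <- suppressWarnings(as.numeric(raw[[i_ph]][keep]))
  for (j in setdiff(seq_along(raw), c(i_smi, i_logs, i_w, i_t, i_ph))) {
    rec[[names(raw)[j]]] <- raw[[j]][keep]
  }
  ds <- solubility_dataset(id, rec, quality_weight = quality_weight,
                           group = group)
  attr(ds, "n_skipped") <- n_skipped
  ds
}

read_dataset_sdf <- function(path, id, quality_weight, group, logS_aliases) {
  fout <- tempfile(fileext = ".jsonl")
  on.exit(unlink(fout), add = TRUE)
  run_chem_tool(c(chem_script(), "sdf", path, fout,
                  paste(logS_aliases, collapse = ",")))
  lines <- readLines(fout)
  if (!length(lines)) stop("empty dataset: ", path, call. = FALSE)
  recs <- lapply(lines, jsonlite::fromJSON)
  smiles <- vapply(recs, function(r) r$smiles %||% NA_character_, character(1))
  logS <- suppressWarnings(as.numeric(
    vapply(recs, function(r) r$logS %||% NA_character_, character(1))))
  keep <- !is.na(smiles) & is.finite(logS)
  n_skipped <- sum(!keep)
  rec <- data.frame(smiles = smiles[keep], logS = logS[keep],
                    weight = 1.0, stringsAsFactors = FALSE)
  grab <- function(r, keys) {
    for (k in keys) if (k %in% names(r$props)) return(r$props[[k]])
    NA_character_
  }
  temp <- suppressWarnings(as.numeric(vapply(
    recs[keep], grab, character(1), c("temperature", "Temperature"))))
  ph <- suppressWarnings(as.numeric(vapply(
    recs[keep], grab, character(1), c("pH", "pH value", "ph"))))
  if (any(is.finite(temp))) rec$temperature <- temp
  if (any(is.finite(ph))) rec$pH <- ph
  ds <- solubility_dataset(id, rec, quality_weight = quality_weight,
                           group = group)
  attr(ds, "n_skipped") <- n_skipped
  ds
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a solubility dataset to CSV
#'
#' Emits exactly the three canonical columns `Smiles`, `LogS`, `Weight`.
#' Numerics are written with full double precision so a read/write round
#' trip reproduces values within 1e-9.
#'
#' @param ds A `solubility_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "solubility_dataset"))
  out <- data.frame(
    Smiles = ds$records$smiles,
    LogS = format_full(ds$records$logS),
    Weight = format_full(ds$records$weight),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

format_full <- function(x) formatC(x, digits = 17, format = "g")
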