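#' Allocate split sizes from ratios
#'
#' Floor allocation with the remainder going to train; afterwards any bin
#' with a nonzero ratio but zero size is topped up with one record taken
#' from train, so small datasets still yield usable validation/test bins.
#' @keywords internal
split_sizes <- function(n, ratios) {
  stopifnot(length(ratios) == 3L, all(ratios > 0),
            abs(sum(ratios) - 1) < 1e-9)
  sizes <- floor(n * ratios)
  sizes[1] <- sizes[1] + (n - sum(sizes))
  for (b in 2:3) {
    if (ratios[b] > 0 && sizes[b] == 0L && sizes[1] > 1L) {
      sizes[1] <- sizes[1] - 1L
      sizes[b] <- 1L
    }
  }
  as.integer(sizes)
}

new_split_assignment <- function(train, val, test, seed, mode) {
  structure(list(train = as.integer(train), val = as.integer(val),
                 test = as.integer(test), seed = seed, mode = mode),
            class = "split_assignment")
}

#' @export
print.split_assignment <- function(x, ...) {
  cat(sprintf("<split_assignment mode=%s seed=%d> train=%d val=%d test=%d\n",
              x$mode, x$seed, length(x$train), length(x$val),
              length(x$test)))
  invisible(x)
}

#' Random train/validation/test split
#'
#' Deterministic for a given seed; sizes follow floor allocation of the
#' ratios with the remainder assigned to train.
#'
#' @param ds A `solubility_dataset`.
#' @param ratios Length-3 positive vector summing to 1; the conventional
#'   partition is `c(0.8, 0.1, 0.1)`.
#' @param seed Integer RNG seed.
#' @return A `split_assignment` with disjoint, exhaustive index vectors
#'   `train`, `val`, `test`.
#' @export
random_split <- function(ds, ratios = c(0.8, 0.1, 0.1), seed = 0L) {
  stopifnot(inherits(ds, "solubility_dataset"))
  n <- nrow(ds$records)
  if (n < 3L) stop("dataset too small to split three ways", call. = FALSE)
  sizes <- split_sizes(n, ratios)
  perm <- withr_seed(seed, sample.int(n))
  new_split_assignment(perm[seq_len(sizes[1])],
                       perm[sizes[1] + seq_len(sizes[2])],
                       perm[sizes[1] + sizes[2] + seq_len(sizes[3])],
                       seed, "random")
}

# evaluate expr under a local RNG seed without disturbing the global stream
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Bemis-Murcko scaffold split
#'
#' Records are grouped by the Bemis-Murcko scaffold (two-dimensional
#' ring/linker framework) of their standardized SMILES; acyclic molecules
#' share a single "no-ring" group. Whole groups, largest first (ties broken
#' by a seeded shuffle), are placed in the first bin of train -> val ->
#' test whose quota is unfilled, so no scaffold ever spans two bins. A
#' single scaffold covering more than the train ratio yields a warning and
#' an oversized train bin.
#'
#' @inheritParams random_split
#' @return A `split_assignment` (mode `"scaffold"`).
#' @export
scaffold_split <- function(ds, ratios = c(0.8, 0.1, 0.1), seed = 0L) {
  stopifnot(inherits(ds, "solubility_dataset"))
  n <- nrow(ds$records)
  if (n < 3L) stop("dataset too small to split three ways", call. = FALSE)
  props <- chem_properties(ds$records$smiles)
  if (any(!props$ok)) stop("unparseable SMILES in scaffold split",
                           call. = FALSE)
  groups <- split(seq_len(n), props$scaffold)
  sizes <- vapply(groups, length, integer(1))
  if (max(sizes) > ratios[1] * n) {
    warning("a single scaffold covers more than the train ratio; ",
            "train bin will be oversized", call. = FALSE)
  }
  ord <- withr_seed(seed, {
    shuffled <- sample.int(length(groups))
    shuffled[order(sizes[shuffled], decreasing = TRUE)]
  })
  quota <- split_sizes(n, ratios)
  bins <- list(integer(0), integer(0), integer(0))
  for (g in ord) {
    placed <- FALSE
    for (b in 1:3) {
      if (length(bins[[b]]) < quota[b]) {
        bins[[b]] <- c(bins[[b]], groups[[g]])
        placed <- TRUE
        break
      }
    }
    if (!placed) bins[[3]] <- c(bins[[3]], groups[[g]])
  }
  new_split_assignment(bins[[1]], bins[[2]], bins[[3]], seed, "scaffold")
}

#' Materialize a split as three datasets
#'
#' @param ds A `solubility_dataset`.
#' @param split A `split_assignment` from [random_split()] or
#'   [scaffold_split()].
#' @return Named list of `solubility_dataset`s: `train`, `val`, `test`.
#' @export
apply_split <- function(ds, split) {
  stopifnot(inherits(ds, "solubility_dataset"),
            inherits(split, "split_assignment"))
  take <- function(idx, suffix) {
    rec <- ds$records[idx, , drop = FALSE]
    rownames(rec) <- NULL
    solubility_dataset(paste0(ds$id, suffix), rec,
                       quality_weight = ds$quality_weight, group = ds$group)
  }
  list(train = take(split$train, ".train"),
       val = take(split$val, ".val"),
       test = take(split$test, ".test"))
}
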