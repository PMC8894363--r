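#' Built-in SMILES vocabulary for the synthetic generator
#'
#' The base list holds 268 drug-like structures (decorated aromatic and
#' heterocyclic cores, simple chains, common drug molecules), each verified
#' to survive the standardization pipeline unchanged, so synthetic
#' collections are already canonical and pipeline stages can be tested
#' without network access. When more molecules are requested than the base
#' list holds, disubstituted-core decorations are enumerated
#' combinatorially and canonicalized through the standardizer (hence stable
#' by construction); the enumeration order is deterministic.
#'
#' @param n Minimum number of molecules needed; `NULL` returns the base
#'   list.
#' @return Character vector of canonical SMILES (length >= `n`).
#' @export
smiles_vocabulary <- function(n = NULL) {
  base <- readLines(system.file("extdata", "smiles_vocab.txt",
                                package = "solcure"))
  if (is.null(n) || n <= length(base)) return(base)
  if (is.null(.chem_cache$vocab_ext) || length(.chem_cache$vocab_ext) < n) {
    subs <- c("C", "CC", "CCC", "C(C)C", "O", "OC", "OCC", "N", "NC",
              "N(C)C", "F", "Cl", "Br", "C#N", "C(=O)O", "C(=O)N",
              "C(=O)OC", "C(F)(F)F", "OC(=O)C", "S(=O)(=O)N", "CO", "CN",
              "C(=O)C", "CCO")
    cores <- c("%sc1ccc(%s)cc1", "%sc1cccc(%s)c1", "%sc1ccc(%s)cn1",
               "%sc1ccc2cc(%s)ccc2c1", "%sc1ccc(-c2ccc(%s)cc2)cc1",
               "%sc1ccc(N2CCN(%s)CC2)cc1", "%sc1ccc(%s)nc1",
               "%sc1cnc(%s)cn1")
    grid <- expand.grid(a = subs, b = subs, core = cores,
                        stringsAsFactors = FALSE)
    cand <- sprintf(grid$core, grid$a, grid$b)
    canon <- chem_properties(cand)$canonical
    ext <- unique(c(base, canon[!is.na(canon)]))
    .chem_cache$vocab_ext <- ext
  }
  vocab <- .chem_cache$vocab_ext
  if (n > length(vocab)) {
    stop("requested vocabulary size ", n, " exceeds capacity ",
         length(vocab), call. = FALSE)
  }
  vocab
}

# standardizer-stable molecules carrying blacklisted elements, used as
# contamination for filter tests
metal_vocabulary <- function() {
  c("C[Hg]C", "CC[Pb](CC)(CC)CC", "C[Si](C)(C)C", "OB(O)c1ccccc1",
    "C[Sn](C)(C)C", "[Li]CCCC")
}

#' Specification of a synthetic multi-dataset collection
#'
#' Describes the statistical world the curation workflow assumes: a shared
#' pool of molecules with planted true LogS values; several datasets each
#' covering a fraction of the pool; repeated/contradictory records where a
#' record either reproduces the true value exactly (probability
#' `p_same_value`) or carries Gaussian noise around it; and contamination
#' records (off-window environments, heavy-metal molecules) at stated
#' rates.
#'
#' Per-dataset fields (each a list entry of `datasets`): `id`,
#' `quality_weight` (`NA`/`NULL` for kinetic), `group`, `n_records`
#' (`NA` = one record per member molecule), `p_overlap` (probability a pool
#' molecule is covered), `p_same_value`, `noise_sd` (LogS units),
#' `env_outlier_rate`, `metal_rate`.
#'
#' Defaults mirror a three-source world of one clean high-quality set, one
#' mid-weight high-quality set and one noisy low-quality set with roughly
#' half-pool coverage and a 40% exact-agreement rate, comparable to the
#' overlap structure seen across public solubility sources.
#'
#' @param n_molecules Size of the shared molecule pool (<= vocabulary).
#' @param datasets List of per-dataset spec lists (see above).
#' @param seed Integer seed; generation is fully reproducible.
#' @param truth_mean,truth_sd Distribution of planted true LogS values;
#'   default N(-3, 1.5), a typical drug-like LogS range.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_molecules = 150,
                           datasets = list(
                             list(id = "SYN_HI", quality_weight = 1.0,
                                  group = "high", n_records = NA,
                                  p_overlap = 0.6, p_same_value = 0.4,
                                  noise_sd = 0.3, env_outlier_rate = 0,
                                  metal_rate = 0),
                             list(id = "SYN_MID", quality_weight = 0.85,
                                  group = "high", n_records = NA,
                                  p_overlap = 0.5, p_same_value = 0.4,
                                  noise_sd = 0.5, env_outlier_rate = 0.02,
                                  metal_rate = 0.02),
                             list(id = "SYN_LO", quality_weight = 0.4,
                                  group = "low", n_records = NA,
                                  p_overlap = 0.5, p_same_value = 0.2,
                                  noise_sd = 0.8, env_outlier_rate = 0.05,
                                  metal_rate = 0.03)),
                           seed = 1L,
                           truth_mean = -3, truth_sd = 1.5) {
  vocab_cap <- 4000L  # base list + combinatorial decorations
  if (n_molecules > vocab_cap) {
    stop("n_molecules exceeds vocabulary capacity (", vocab_cap, ")",
         call. = FALSE)
  }
  defaults <- list(quality_weight = NULL, group = "high", n_records = NA,
                   p_overlap = 0.5, p_same_value = 0.4, noise_sd = 0.5,
                   env_outlier_rate = 0, metal_rate = 0)
  datasets <- lapply(datasets, function(d) {
    d <- utils::modifyList(defaults, d)
    if (!is.null(d$quality_weight) && is.na(d$quality_weight)) {
      d$quality_weight <- NULL
    }
    stopifnot(!is.null(d$id),
              d$p_overlap >= 0, d$p_overlap <= 1,
              d$p_same_value >= 0, d$p_same_value <= 1,
              d$noise_sd >= 0, d$env_outlier_rate >= 0,
              d$env_outlier_rate <= 1, d$metal_rate >= 0, d$metal_rate <= 1,
              is.na(d$n_records) || d$n_records >= 1)
    d
  })
  ids <- vapply(datasets, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate dataset ids", call. = FALSE)
  structure(list(n_molecules = n_molecules, datasets = datasets,
                 seed = as.integer(seed), truth_mean = truth_mean,
                 truth_sd = truth_sd),
            class = "synthetic_spec")
}

#' Generate a synthetic multi-dataset collection with planted truth
#'
#' For each dataset of the spec: every pool molecule is included
#' independently with probability `p_overlap`; each member molecule gets
#' one record (plus, when `n_records` exceeds the member count, extra
#' repeat records sampled from the members). Whether a record reproduces
#' the planted true value exactly is governed by a per-molecule latent
#' "measurement difficulty" `u ~ U(0, 1)` shared across datasets: the
#' record is exact iff `u < p_same_value` for its dataset, otherwise it is
#' `truth + N(0, noise_sd)` (noise independent per record). The shared
#' latent makes easy molecules agree everywhere, so for two datasets with
#' equal `p_same_value` the cross-dataset exact-agreement fraction is
#' `p_same_value` itself (not its square). Contamination is then
#' injected: off-window temperatures (50 degrees C) at `env_outlier_rate`
#' and heavy-metal molecules at `metal_rate`.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `datasets` (list of `solubility_dataset`) and `truth`
#'   (data.frame `smiles`, `logS`).
#' @export
generate_collection <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr_seed(spec$seed, {
    vocab <- smiles_vocabulary(spec$n_molecules)
    pool <- sample(vocab, spec$n_molecules)
    truth <- data.frame(smiles = pool,
                        logS = stats::rnorm(spec$n_molecules,
                                            spec$truth_mean, spec$truth_sd),
                        stringsAsFactors = FALSE)
    difficulty <- stats::runif(spec$n_molecules)
    datasets <- lapply(spec$datasets, function(d) {
      members <- which(stats::runif(spec$n_molecules) < d$p_overlap)
      if (!length(members)) members <- sample.int(spec$n_molecules, 1L)
      idx <- members
      if (!is.na(d$n_records) && d$n_records > length(members)) {
        idx <- c(members, sample(members, d$n_records - length(members),
                                 replace = TRUE))
      } else if (!is.na(d$n_records) && d$n_records < length(members)) {
        idx <- sample(members, d$n_records)
      }
      n <- length(idx)
      exact <- difficulty[idx] < d$p_same_value
      value <- truth$logS[idx] +
        ifelse(exact, 0, stats::rnorm(n, 0, d$noise_sd))
      rec <- data.frame(smiles = truth$smiles[idx], logS = value,
                        weight = 1.0, stringsAsFactors = FALSE)
      metal <- stats::runif(n) < d$metal_rate
      if (any(metal)) {
        rec$smiles[metal] <- sample(metal_vocabulary(), sum(metal),
                                    replace = TRUE)
        rec$logS[metal] <- stats::rnorm(sum(metal), spec$truth_mean,
                                        spec$truth_sd)
      }
      env <- stats::runif(n) < d$env_outlier_rate
      if (any(env) || d$env_outlier_rate > 0) {
        rec$temperature <- ifelse(env, 50, NA_real_)
      }
      solubility_dataset(d$id, rec, quality_weight = d$quality_weight,
                         group = d$group)
    })
    list(datasets = datasets, truth = truth)
  })
}

#' Expected redundancy matrices for a synthetic spec
#'
#' Closed-form expectations of the same-value (A) and different-value (B)
#' percentages under the generator's model, for statistical comparison
#' with [redundancy_matrices()] on a generated collection. A record of
#' dataset i finds its molecule in dataset j with probability
#' `p_overlap_j`; because exactness is driven by the shared per-molecule
#' difficulty latent, the pair is exact-exact with probability
#' `min(p_same_i, p_same_j)`, one-sided-noisy with probability
#' `|p_same_i - p_same_j|`, and double-noisy otherwise, each noisy case
#' agreeing only through the Gaussian overlap within `tol`. The formulas
#' assume one record per member molecule and no contamination (valid when
#' `n_records` is `NA` and the contamination rates are near zero);
#' diagonals are 0 under that assumption because identical intra-dataset
#' values have been merged.
#'
#' @param spec A [synthetic_spec()].
#' @param tol Identity tolerance (default 0.01).
#' @return List with matrices `A` and `B` (percent, dimnames = ids).
#' @export
expected_redundancy <- function(spec, tol = 0.01) {
  stopifnot(inherits(spec, "synthetic_spec"))
  ds <- spec$datasets
  k <- length(ds)
  ids <- vapply(ds, `[[`, character(1), "id")
  A <- B <- matrix(0, k, k, dimnames = list(ids, ids))
  p_abs_norm <- function(sd) {
    if (sd == 0) 1 else stats::pnorm(tol, 0, sd) - stats::pnorm(-tol, 0, sd)
  }
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      psi <- ds[[i]]$p_same_value
      psj <- ds[[j]]$p_same_value
      si <- ds[[i]]$noise_sd
      sj <- ds[[j]]$noise_sd
      # shared-difficulty latent: exact_i iff u < psi, exact_j iff u < psj
      p_both <- min(psi, psj)
      p_i_only <- max(0, psi - psj)
      p_j_only <- max(0, psj - psi)
      p_neither <- 1 - max(psi, psj)
      p_agree <- p_both +
        p_i_only * p_abs_norm(sj) +
        p_j_only * p_abs_norm(si) +
        p_neither * p_abs_norm(sqrt(si^2 + sj^2))
      A[i, j] <- 100 * ds[[j]]$p_overlap * p_agree
      B[i, j] <- 100 * ds[[j]]$p_overlap * (1 - p_agree)
    }
  }
  list(A = A, B = B)
}
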