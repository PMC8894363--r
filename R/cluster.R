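#' Greedy partial clustering of weighted solubility values
#'
#' The merge engine shared by within-dataset identical-value merging and
#' cross-dataset curation. At each step the two closest values are found;
#' if their gap is below the threshold `d` (strictly below by default) they
#' are replaced by their weight-weighted mean, with weights summed as the
#' new quality weight; otherwise the loop stops. On the real line the
#' closest pair is always adjacent after sorting, so the greedy loop works
#' on sorted values; ties on the minimal gap are broken toward the pair
#' with the smaller lower value, which makes the procedure deterministic.
#'
#' Weight mass and the overall weighted mean are exactly conserved by any
#' sequence of merges. The output is sorted by logS; the guarantee is that
#' the final closest pair has gap >= d (merging moves centroids, so larger
#' historical gaps are not re-examined).
#'
#' @param logS Numeric vector of solubility values (finite, non-empty).
#' @param weight Positive weights, same length.
#' @param d Merge gap in LogS units; the recommended default is 0.5.
#' @param inclusive If `TRUE`, merge when the gap is `<= d` (used for the
#'   identity tolerance, where values differing by at most `tol` count as
#'   identical); if `FALSE` (default) merge only when strictly `< d`.
#' @return A data.frame with columns `logS` and `weight`, sorted by `logS`.
#' @export
partial_cluster <- function(logS, weight = rep(1, length(logS)), d = 0.5,
                            inclusive = FALSE) {
  stopifnot(length(logS) >= 1L, length(weight) == length(logS),
            d > 0, all(is.finite(logS)), all(is.finite(weight)),
            all(weight > 0))
  o <- order(logS)
  v <- logS[o]
  w <- weight[o]
  while (length(v) > 1L) {
    gaps <- v[-1L] - v[-length(v)]
    i <- which.min(gaps)  # leftmost minimal gap: smaller lower value wins ties
    hit <- if (inclusive) gaps[i] <= d else gaps[i] < d
    if (!hit) break
    wm <- w[i] + w[i + 1L]
    vm <- (w[i] * v[i] + w[i + 1L] * v[i + 1L]) / wm
    v <- c(v[seq_len(i - 1L)], vm, v[-seq_len(i + 1L)])
    w <- c(w[seq_len(i - 1L)], wm, w[-seq_len(i + 1L)])
  }
  data.frame(logS = v, weight = w)
}
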