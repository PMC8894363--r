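#' Weighted root-mean-square error
#'
#' `sqrt(sum(w_i * (pred_i - obs_i)^2) / n)`: the per-record quality
#' weights scale each squared error but the divisor stays `n`, so with
#' unit weights this is exactly the classic RMSE. Note the statistic is
#' deliberately not scale-free in the weights (it is the training/test
#' metric used with weighted records); a sum-of-weights divisor is
#' available behind `normalize = TRUE` but is never the default.
#'
#' @param y_true Observed values.
#' @param y_pred Predicted values.
#' @param weights Quality weights (>= 0); default unit weights.
#' @param normalize If `TRUE`, divide by `sum(weights)` instead of `n`.
#' @return The (weighted) RMSE.
#' @export
weighted_rmse <- function(y_true, y_pred, weights = NULL, normalize = FALSE) {
  n <- length(y_true)
  if (length(y_pred) != n) stop("length mismatch", call. = FALSE)
  if (n < 1L) stop("need at least one record", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n) stop("length mismatch", call. = FALSE)
  stopifnot(all(is.finite(weights)), all(weights >= 0))
  denom <- if (normalize) sum(weights) else n
  sqrt(sum(weights * (y_pred - y_true)^2) / denom)
}

#' Pearson correlation coefficient r
#'
#' `r = sum((x - mean(x)) (y - mean(y))) / (sqrt(sum((x - mean(x))^2)) *
#' sqrt(sum((y - mean(y))^2)))`; its square r^2 = 1 indicates a perfect
#' linear correlation between predicted and observed values.
#'
#' @param x,y Numeric vectors of equal length >= 2, neither constant.
#' @return r in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("length mismatch", call. = FALSE)
  if (n < 2L) stop("need at least two points", call. = FALSE)
  dx <- x - mean(x)
  dy <- y - mean(y)
  sx <- sqrt(sum(dx^2))
  sy <- sqrt(sum(dy^2))
  if (sx == 0 || sy == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  sum(dx * dy) / (sx * sy)
}

#' Spearman rank-order correlation coefficient Rs
#'
#' Both vectors are ranked (average ranks on ties) and
#' `Rs = 1 - 6 sum(d_i^2) / (n (n^2 - 1))` is returned, with `d_i` the rank
#' difference of observation i. Rs = 1 indicates a perfect ranking. The
#' closed form assumes no ties; with ties the standard extension — the
#' Pearson correlation of the average ranks — is used instead.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return Rs in `[-1, 1]`.
#' @export
spearman_rs <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("length mismatch", call. = FALSE)
  if (n < 2L) stop("need at least two points", call. = FALSE)
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (anyDuplicated(rx) || anyDuplicated(ry)) {
    return(pearson_r(rx, ry))
  }
  1 - 6 * sum((rx - ry)^2) / (n * (n^2 - 1))
}

#' Evaluate a prediction table with all workflow metrics
#'
#' @param y_true,y_pred,weights As in [weighted_rmse()].
#' @return Named list: `rmse`, `weighted_rmse`, `r2`, `spearman_rs`.
#' @export
evaluate_predictions <- function(y_true, y_pred, weights = NULL) {
  list(
    rmse = weighted_rmse(y_true, y_pred),
    weighted_rmse = weighted_rmse(y_true, y_pred, weights),
    r2 = pearson_r(y_pred, y_true)^2,
    spearman_rs = spearman_rs(y_pred, y_true)
  )
}
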