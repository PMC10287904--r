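# Regression metrics for affinity prediction: MSE, Pearson, Spearman, the
# concordance index over affinity-ordered pairs, and the rm2 metric that
# penalizes the gap between the fitted and through-origin correlation.

#' Concordance index
#'
#' Over all pairs with distinct true affinities, the fraction of pairs
#' whose predicted ordering agrees with the true ordering; predicted ties
#' count 0.5. Pairs tied in the true affinity are excluded from the
#' denominator.
#'
#' @param y_true,y_pred numeric vectors of equal length >= 2.
#' @return scalar in `[0, 1]`.
#' @export
concordance_index <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 2L)
  dt <- outer(y_true, y_true, "-")
  dp <- outer(y_pred, y_pred, "-")
  sel <- upper.tri(dt) & dt != 0
  if (!any(sel)) stop("all true affinities identical: concordance undefined")
  agree <- sign(dt[sel]) == sign(dp[sel])
  tied <- dp[sel] == 0
  (sum(agree & !tied) + 0.5 * sum(tied)) / sum(sel)
}

#' rm2 metric
#'
#' `rm2 = r^2 * (1 - sqrt(|r^2 - r0^2|))` where `r^2` is the squared
#' Pearson correlation and `r0^2` the coefficient of determination of the
#' through-origin regression of the observed on the predicted values
#' (slope `k = sum(y * yhat) / sum(yhat^2)`).
#'
#' @param y_true,y_pred numeric vectors of equal length >= 3 with nonzero
#'   variance.
#' @return scalar.
#' @export
rm2 <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 3L)
  if (stats::sd(y_true) == 0 || stats::sd(y_pred) == 0)
    stop("degenerate variance in rm2")
  r2 <- stats::cor(y_true, y_pred)^2
  k <- sum(y_true * y_pred) / sum(y_pred^2)
  ss_res <- sum((y_true - k * y_pred)^2)
  ss_tot <- sum((y_true - mean(y_true))^2)
  r02 <- 1 - ss_res / ss_tot
  r2 * (1 - sqrt(abs(r2 - r02)))
}

#' Bundle of standard affinity-regression metrics
#'
#' @param y_true,y_pred numeric vectors of equal length >= 2.
#' @return a `metrics_report`: list with `mse`, `pearson`, `spearman`,
#'   `ci`, `rm2` and `n`.
#' @export
basic_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  stopifnot(length(y_true) >= 2L)
  maybe <- function(expr) tryCatch(suppressWarnings(expr),
                                   error = function(e) NA_real_)
  structure(list(
    mse = mean((y_true - y_pred)^2),
    pearson = maybe(stats::cor(y_true, y_pred)),
    spearman = maybe(stats::cor(y_true, y_pred, method = "spearman")),
    ci = maybe(concordance_index(y_true, y_pred)),
    rm2 = if (length(y_true) >= 3L) maybe(rm2(y_true, y_pred)) else NA_real_,
    n = length(y_true)), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("n=%d  MSE=%.4f  CI=%.4f  rm2=%.4f  pearson=%.4f  spearman=%.4f\n",
              x$n, x$mse, x$ci, x$rm2, x$pearson, x$spearman))
  invisible(x)
}
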