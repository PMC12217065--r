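#' Pearson correlation with full sum-of-squares bookkeeping
#'
#' Computes the sample correlation coefficient `r = S_XY / sqrt(S_XX * S_YY)`
#' together with the quantities a redundancy analysis needs: the coefficient
#' of determination, the regression/residual sums of squares of the implied
#' simple least-squares fit of `y` on `x`, the sample covariance (computed
#' with the `1/(n-1)` convention), and both standard deviations.
#'
#' @param x,y Numeric vectors of equal length (>= 2), each with nonzero
#'   variance.
#' @return A one-row tibble with columns `r`, `r_squared`, `ss_reg`, `s_yy`,
#'   `sse`, `cov`, `s_x`, `s_y`. The invariants `-1 <= r <= 1`,
#'   `|cov| <= s_x * s_y` and `s_yy = ss_reg + sse` hold by construction.
#' @examples
#' correlation_coefficient(c(1, 2, 3, 4), c(2, 1, 4, 3))
#' @export
correlation_coefficient <- function(x, y) {
  check_paired_numeric(x, y)
  if (var(x) == 0 || var(y) == 0) {
    abort("undefined correlation: input vector has zero variance")
  }
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  r <- sxy / sqrt(sxx * syy)
  r <- max(-1, min(1, r))
  tibble(
    r = r,
    r_squared = r^2,
    ss_reg = r^2 * syy,
    s_yy = syy,
    sse = (1 - r^2) * syy,
    cov = sxy / (n - 1),
    s_x = sqrt(sxx / (n - 1)),
    s_y = sqrt(syy / (n - 1))
  )
}

#' Coefficient of determination of predictions against observations
#'
#' `r_squared = 1 - SSE / S_YY` with `SSE = sum((y - y_hat)^2)` and
#' `S_YY = sum((y - mean(y))^2)`. The reported `r` is the Pearson correlation
#' between observations and predictions (the multiple correlation coefficient
#' in a regression context).
#'
#' @param y Observed numeric vector (nonconstant).
#' @param y_hat Predicted values, same length as `y`.
#' @return A one-row tibble with columns `r`, `r_squared`, `ss_reg`, `s_yy`,
#'   `sse`, `cov`, `s_x`, `s_y` (the last three describe the (y, y_hat) pair;
#'   `r` is `NA` when `y_hat` is constant).
#' @examples
#' coefficient_of_determination(1:4, c(1.1, 1.9, 3.2, 3.8))
#' @export
coefficient_of_determination <- function(y, y_hat) {
  check_paired_numeric(y, y_hat)
  if (var(y) == 0) abort("undefined coefficient of determination: y is constant")
  n <- length(y)
  syy <- sum((y - mean(y))^2)
  sse <- sum((y - y_hat)^2)
  r <- if (var(y_hat) == 0) NA_real_ else {
    max(-1, min(1, cor(y, y_hat)))
  }
  tibble(
    r = r,
    r_squared = 1 - sse / syy,
    ss_reg = syy - sse,
    s_yy = syy,
    sse = sse,
    cov = sum((y - mean(y)) * (y_hat - mean(y_hat))) / (n - 1),
    s_x = sqrt(syy / (n - 1)),
    s_y = sd(y_hat)
  )
}

check_paired_numeric <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y)) abort("inputs must be numeric vectors")
  if (length(x) != length(y)) abort("inputs must have equal length")
  if (length(x) < 2) abort("inputs must have length >= 2")
  if (anyNA(x) || anyNA(y)) abort("inputs must not contain NA")
  invisible(TRUE)
}

#' Greedy correlation-based redundancy filter
#'
#' Scans columns left to right; a column is dropped iff its absolute Pearson
#' correlation with an already-kept column exceeds `threshold` (first-seen
#' column wins). Constant columns, whose correlation is undefined, are kept
#' and flagged with a warning.
#'
#' @param features Numeric matrix or data frame (samples x d). An `id` or
#'   `label` column of a feature tibble should be removed first.
#' @param threshold Absolute-correlation threshold in (0, 1].
#' @return Sorted integer vector of kept column indices (1-based), with an
#'   attribute `flagged` listing constant columns that were kept untested.
#' @examples
#' m <- cbind(a = 1:10, b = (1:10) * 2, c = rnorm(10))
#' correlation_redundancy_filter(m, threshold = 0.95)
#' @export
correlation_redundancy_filter <- function(features, threshold = 0.95) {
  m <- as.matrix(features)
  if (!is.numeric(m)) abort("features must be numeric")
  d <- ncol(m)
  if (d < 1) abort("features must have at least one column")
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    abort("threshold must lie in (0, 1]")
  }
  const <- apply(m, 2, function(col) var(col) == 0)
  kept <- integer(0)
  flagged <- integer(0)
  for (j in seq_len(d)) {
    if (const[j]) {
      kept <- c(kept, j)
      flagged <- c(flagged, j)
      next
    }
    testable <- kept[!const[kept]]
    redundant <- length(testable) > 0 &&
      any(abs(suppressWarnings(cor(m[, j], m[, testable, drop = FALSE]))) > threshold)
    if (!redundant) kept <- c(kept, j)
  }
  if (length(flagged) > 0) {
    warn(paste0(
      "constant column(s) kept but not testable for redundancy: ",
      paste(flagged, collapse = ", ")
    ))
  }
  structure(sort(kept), flagged = flagged)
}
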