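# Eigenvalue-method weighting and consistency evaluation.

#' Column-normalize a pairwise comparison matrix
#'
#' Divides every column by its sum, giving a column-stochastic matrix whose
#' row means are the classical approximate priority weights.
#'
#' @param x A `pcm` (or positive matrix).
#' @return Matrix with every column summing to 1.
#' @export
column_normalize <- function(x) {
  m <- unclass(as.matrix(x))
  sweep(m, 2, colSums(m), "/")
}

#' Priority weights of a pairwise comparison matrix
#'
#' `method = "eigen"` (default) computes the principal right eigenvector by
#' power iteration: starting from the uniform vector, repeatedly multiply by
#' the matrix and renormalize to unit sum, stopping when the largest
#' component change falls below `tol`. For a positive matrix the iteration
#' converges to the Perron vector. `method = "rowmean"` takes row means of
#' the column-normalized matrix, the classical hand-calculation
#' approximation; the two agree closely for matrices with an acceptable
#' consistency ratio.
#'
#' @param x A valid `pcm`.
#' @param method `"eigen"` or `"rowmean"`.
#' @param tol Convergence tolerance on the max component change.
#' @param max_iter Iteration cap for the power method.
#' @return Named numeric weight vector summing to 1.
#' @export
ahp_weights <- function(x, method = c("eigen", "rowmean"), tol = 1e-12,
                        max_iter = 10000L) {
  method <- match.arg(method)
  m <- unclass(as.matrix(x))
  n <- nrow(m)
  labels <- rownames(m)
  if (method == "rowmean") {
    w <- rowMeans(column_normalize(m))
    return(stats::setNames(w / sum(w), labels))
  }
  w <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    w_new <- as.vector(m %*% w)
    w_new <- w_new / sum(w_new)
    if (max(abs(w_new - w)) < tol) {
      return(stats::setNames(w_new, labels))
    }
    w <- w_new
  }
  stop(sprintf(
    "power iteration did not converge in %d iterations (residual %.3e)",
    max_iter, max(abs(as.vector(m %*% w) / sum(m %*% w) - w))),
    call. = FALSE)
}

#' Saaty's maximum-eigenvalue estimator
#'
#' `lambda_max = mean_i (A w)_i / w_i`. Equal to the matrix order `n` for a
#' perfectly consistent matrix and `>= n` otherwise; when `w` is the exact
#' principal eigenvector the estimator equals the principal eigenvalue.
#'
#' @param x A valid `pcm`.
#' @param w Positive weight vector (need not be the eigenvector).
#' @return The estimate.
#' @export
lambda_max <- function(x, w) {
  m <- unclass(as.matrix(x))
  if (length(w) != nrow(m))
    stop("weight vector length does not match the matrix order",
         call. = FALSE)
  if (any(w <= 0))
    stop("invalid weights: all components must be positive", call. = FALSE)
  mean(as.vector(m %*% w) / w)
}

#' Random consistency index
#'
#' Saaty's tabulated average consistency index of random reciprocal matrices
#' of order `n`. Values are tabulated for `n <= 8`; the standard extension to
#' `n = 9, 10` (1.45, 1.49) is available behind `extended = TRUE`.
#'
#' @param n Matrix order.
#' @param extended Allow `n` of 9 or 10.
#' @return The random index RI(n).
#' @export
saaty_random_index <- function(n, extended = FALSE) {
  ri <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41)
  if (extended) ri <- c(ri, 1.45, 1.49)
  if (n < 1 || n > length(ri))
    stop(sprintf(
      "no random index tabulated for n = %d%s", n,
      if (!extended && n <= 10) " (use extended = TRUE)" else ""),
      call. = FALSE)
  ri[n]
}

#' Consistency report from a lambda-max value
#'
#' Computes `CI = (lambda_max - n) / (n - 1)` and `CR = CI / RI(n)`; the
#' matrix passes when `CR < 0.10`. For `n <= 2` no inconsistency is possible
#' (RI is 0) and CR is defined as 0.
#'
#' @param lambda_max Maximum-eigenvalue estimate.
#' @param n Matrix order (>= 2).
#' @param extended Passed to [saaty_random_index()].
#' @return An object of class `consistency_report` with fields `lambda_max`,
#'   `ci`, `ri`, `cr`, `n`, `passed`.
#' @export
consistency <- function(lambda_max, n, extended = FALSE) {
  if (n < 2) stop("consistency is defined for n >= 2", call. = FALSE)
  ri <- saaty_random_index(n, extended = extended)
  ci <- (lambda_max - n) / (n - 1)
  cr <- if (n <= 2 || ri == 0) 0 else ci / ri
  structure(
    list(lambda_max = lambda_max, ci = ci, ri = ri, cr = cr, n = n,
         passed = cr < 0.10),
    class = "consistency_report"
  )
}

#' Consistency report for a pairwise comparison matrix
#'
#' Convenience wrapper: derives weights, applies Saaty's estimator, and
#' builds the [consistency()] report. The default convention follows the
#' classical hand calculation: the estimator is evaluated at the row-mean
#' weights and rounded to 4 decimals before CI/CR are formed, which is the
#' precision at which these diagnostics are conventionally reported.
#' `lambda_convention = "eigen"` instead uses the principal eigenvector
#' (giving the exact principal eigenvalue) without rounding.
#'
#' @param x A valid `pcm`.
#' @param lambda_convention `"rowmean"` (classical, rounded to
#'   `round_digits`) or `"eigen"` (exact, unrounded).
#' @param round_digits Decimals for the rowmean convention.
#' @param extended Passed to [saaty_random_index()].
#' @return A `consistency_report`; its `convention` field records which was
#'   used.
#' @export
pcm_consistency <- function(x, lambda_convention = c("rowmean", "eigen"),
                            round_digits = 4L, extended = FALSE) {
  lambda_convention <- match.arg(lambda_convention)
  n <- nrow(x)
  w <- ahp_weights(x, method = if (lambda_convention == "eigen") "eigen"
                   else "rowmean")
  lm <- lambda_max(x, w)
  if (lambda_convention == "rowmean") lm <- round(lm, round_digits)
  rep <- consistency(lm, n, extended = extended)
  rep$convention <- lambda_convention
  rep
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf(
    "n = %d  lambda_max = %.4f  CI = %.4f  RI = %.2f  CR = %.6f  [%s]\n",
    x$n, x$lambda_max, x$ci, x$ri, x$cr,
    if (x$passed) "consistent, CR < 0.10" else "INCONSISTENT, CR >= 0.10"))
  invisible(x)
}
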