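#' Moore-Penrose pseudo-inverse
#'
#' SVD-based pseudo-inverse with the usual relative tolerance on singular
#' values; used by the confound-projection operations.
#'
#' @param m numeric matrix.
#' @param tol relative singular-value tolerance.
#' @return the pseudo-inverse of `m`.
#' @export
pinv <- function(m, tol = .Machine$double.eps * max(dim(m))) {
  m <- as.matrix(m)
  s <- svd(m)
  keep <- s$d > tol * max(s$d, 0)
  if (!any(keep)) return(matrix(0, ncol(m), nrow(m)))
  s$v[, keep, drop = FALSE] %*%
    ((1 / s$d[keep]) * t(s$u[, keep, drop = FALSE]))
}

#' Intraclass correlation, two-way absolute agreement, single measures
#'
#' ICC(2,1) between the columns of a subjects-by-raters matrix, from the
#' two-way ANOVA mean squares.
#'
#' @param ratings numeric matrix, one row per subject, one column per rater.
#' @return scalar ICC.
#' @export
icc_agreement <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings)
  k <- ncol(ratings)
  stopifnot(n > 1, k > 1)
  g <- mean(ratings)
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  ssr <- k * sum((row_m - g)^2)
  ssc <- n * sum((col_m - g)^2)
  sst <- sum((ratings - g)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# stop() with a consistent prefix for user-facing contract violations
abort_if <- function(cond, msg) if (cond) stop(msg, call. = FALSE)
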