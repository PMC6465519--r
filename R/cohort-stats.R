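## Cohort-level statistics: coefficient of variation and its equality
## test, group comparisons, correlation.

#' Coefficient of variation in percent
#'
#' `100 * sd(x) / mean(x)` with the n-1 sample SD. Scale-invariant for
#' positive rescalings; undefined (error) for zero mean.
#'
#' @param values numeric vector, length >= 2.
#' @return CoV in percent.
#' @examples
#' coefficientOfVariation(c(1, 2, 3))  # 50
#' @export
coefficientOfVariation <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  m <- mean(values)
  if (m == 0) stop("undefined CoV: zero mean")
  100 * sd(values) / m
}

#' Asymptotic test of equality of coefficients of variation
#'
#' The asymptotic chi-square statistic of Feltz and Miller for k
#' independent samples:
#' `D = sum(m_i * (c_i - cbar)^2) / (cbar^2 * (0.5 + cbar^2))` with
#' `m_i = n_i - 1` and the pooled `cbar = sum(m_i c_i) / sum(m_i)`,
#' referred to a chi-square distribution with k - 1 degrees of freedom
#' (upper tail). CoVs enter as fractions, not percent; the statistic is
#' unit-free.
#'
#' @param covs numeric vector of per-sample CoVs as fractions.
#' @param ns integer vector of sample sizes (each >= 2).
#' @return a list of class `"covTest"`: `cov` (input CoVs), `n`,
#'   `statistic`, `df`, `p_value`.
#' @examples
#' covEqualityTest(c(0.2204, 0.0982), c(47L, 47L))
#' @export
covEqualityTest <- function(covs, ns) {
  k <- length(covs)
  stopifnot(k >= 2L, length(ns) == k)
  if (any(ns < 2L)) stop("each sample size must be >= 2")
  if (all(covs == 0)) stop("degenerate test: all CoVs are zero")
  m <- ns - 1
  cbar <- sum(m * covs) / sum(m)
  stat <- sum(m * (covs - cbar)^2) / (cbar^2 * (0.5 + cbar^2))
  res <- list(cov = covs, n = ns, statistic = stat, df = k - 1L,
              p_value = pchisq(stat, df = k - 1L, lower.tail = FALSE))
  class(res) <- "covTest"
  res
}

#' @export
print.covTest <- function(x, ...) {
  cat("Equality of coefficients of variation (asymptotic chi-square)\n")
  cat(sprintf("  CoVs: %s | n: %s\n",
              paste(sprintf("%.4f", x$cov), collapse = ", "),
              paste(x$n, collapse = ", ")))
  cat(sprintf("  chi-sq = %.3f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Welch two-sample t-test from summary statistics
#'
#' Welch's unequal-variance statistic and Welch-Satterthwaite degrees of
#' freedom computed from group means, SDs and sizes; two-sided p-value.
#' The difference is taken as `mean_a - mean_b`.
#'
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b group summaries (SDs > 0,
#'   n >= 2).
#' @return a list with `t`, `df`, `p_value`.
#' @examples
#' # age comparison, HC minus MS
#' welchTFromSummary(36.23, 9.73, 47, 37.69, 9.22, 47)
#' @export
welchTFromSummary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  stopifnot(sd_a > 0, sd_b > 0, n_a >= 2, n_b >= 2)
  va <- sd_a^2 / n_a
  vb <- sd_b^2 / n_b
  t <- (mean_a - mean_b) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
  list(t = t, df = df, p_value = 2 * pt(-abs(t), df))
}

#' Welch t-test, 2x2 chi-square, and Pearson correlation helpers
#'
#' Thin wrappers with fixed conventions: Welch (unequal variance) t from
#' raw values; chi-square on a 2x2 table without continuity correction;
#' Pearson r together with the adjusted R-squared of the simple linear
#' regression of `y` on `x`.
#'
#' @param values_a,values_b numeric vectors.
#' @return `welchT`: list with `t`, `df`, `p_value`.
#' @export
welchT <- function(values_a, values_b) {
  ht <- t.test(values_a, values_b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' @rdname welchT
#' @param table 2x2 contingency table (matrix of counts).
#' @return `chiSquare2x2`: list with `statistic`, `df`, `p_value`.
#' @export
chiSquare2x2 <- function(table) {
  stopifnot(identical(dim(as.matrix(table)), c(2L, 2L)))
  ht <- suppressWarnings(chisq.test(as.matrix(table), correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' @rdname welchT
#' @param x,y numeric vectors of equal length.
#' @return `pearsonWithAdjR2`: list with `r`, `adj_r2`, `p_value`.
#' @export
pearsonWithAdjR2 <- function(x, y) {
  if (sd(x) == 0 || sd(y) == 0)
    stop("undefined correlation: constant input vector")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), adj_r2 = sm$adj.r.squared,
       p_value = ct$p.value)
}
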