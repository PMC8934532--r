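# Classical statistical primitives shared by the genomic and expression
# modules.  These are thin, validated interfaces over the standard
# implementations in stats; keeping them behind one surface makes the
# downstream modules explicit about exactly which conventions they use
# (two-sided point-probability Fisher test, step-up BH, pooled-variance t).

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Two-sided p-value by the point-probability method: the sum of
#' hypergeometric probabilities of all tables with the same margins whose
#' point probability does not exceed that of the observed table (with a
#' relative tolerance of 1e-7 on the comparison).
#'
#' @param table 2x2 matrix of nonnegative integer counts (rows = group,
#'   columns = outcome).
#' @return The two-sided p-value.
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("need a 2x2 table")
  if (any(table < 0) || any(table != round(table))) {
    stop("cell counts must be nonnegative integers")
  }
  if (any(rowSums(table) == 0) && any(colSums(table) == 0) || sum(table) == 0) {
    stop("degenerate table: need at least one positive margin in each dimension")
  }
  stats::fisher.test(table)$p.value
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; output order matches input
#' order, adjusted values are capped at 1.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Pooled-variance two-sample t-test
#'
#' Classical equal-variance two-sided t-test with
#' `df = length(x) + length(y) - 2`.
#'
#' @param x,y Numeric vectors with at least 2 values each.
#' @return List with `t`, `df`, `p_value`, `mean_x`, `mean_y`.
#' @export
two_sample_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("need at least 2 values per group")
  sp2 <- ((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
    (length(x) + length(y) - 2)
  if (sp2 <= 0) stop("pooled variance is zero")
  ht <- stats::t.test(x, y, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, mean_x = mean(x), mean_y = mean(y))
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length >= 2 with nonzero variance.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    stop("need two vectors of equal length >= 2")
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("correlation undefined for zero-variance input")
  }
  stats::cor(x, y)
}

#' Upper-tail chi-squared probability
#'
#' `P(X > x)` for a chi-squared variable; with `df = 1` this equals
#' `erfc(sqrt(x / 2))`.
#'
#' @param x Test statistic, >= 0.
#' @param df Degrees of freedom (default 1).
#' @return Upper-tail probability.
#' @export
chi2_sf <- function(x, df = 1) {
  if (any(x < 0)) stop("statistic must be >= 0")
  stats::pchisq(x, df = df, lower.tail = FALSE)
}
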