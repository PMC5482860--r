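# Cohort statistics: two-tailed Pearson correlation and the two-sample
# t-test with a variance-homogeneity pre-check, the tests used on the
# somatic-tissue comparisons.

#' Two-tailed Pearson correlation
#'
#' Product-moment correlation with the two-sided p-value from the t
#' transform on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`, non-constant.
#' @return A list with `r`, `p`, `n`.
#' @export
#' @examples
#' pearson_r(1:10, (1:10)^2)
pearson_r <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input; correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' Two-sample t-test with variance-homogeneity pre-check
#'
#' Checks variance homogeneity with the F test first; when homogeneity is
#' not rejected (at `var_alpha`) the pooled-variance t-test is used,
#' otherwise the Welch unequal-variance form. Two-sided throughout.
#' Significance stars follow the usual convention (`*` < 0.05, `**` < 0.01,
#' `***` < 0.001).
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @param paired Paired test (skips the homogeneity check).
#' @param var_alpha Level of the homogeneity pre-check (default 0.05).
#' @return A list with `t`, `df`, `p`, `var_equal`, `method`, `stars`.
#' @export
two_sample_ttest <- function(x, y, paired = FALSE, var_alpha = 0.05) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2 || length(y) < 2) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  if (paired) {
    if (length(x) != length(y)) stop("paired test needs equal lengths", call. = FALSE)
    tt <- stats::t.test(x, y, paired = TRUE)
    var_equal <- NA
  } else {
    hom_p <- stats::var.test(x, y)$p.value
    var_equal <- is.na(hom_p) || hom_p >= var_alpha
    tt <- stats::t.test(x, y, var.equal = var_equal)
  }
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, var_equal = var_equal, method = tt$method,
       stars = significance_stars(tt$p.value))
}
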