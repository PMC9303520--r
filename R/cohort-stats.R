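# Statistical kernel shared by the pipeline: chi-square on 2x2 tables,
# Kruskal-Wallis, two-sample t, ANCOVA group F, Pearson r with p, BH-FDR.
# All tests delegate to base R's stats routines; this layer fixes the
# conventions used throughout (no continuity correction, pooled-variance t
# by default, extra-sum-of-squares F) and returns a uniform result record.

test_result <- function(statistic, p, df, method) {
  structure(
    list(statistic = unname(statistic), p = unname(p),
         df = unname(df), method = method),
    class = "r1_test"
  )
}

#' @export
print.r1_test <- function(x, ...) {
  cat(x$method, "\n  statistic =", format(x$statistic),
      " df =", format(x$df), " p =", format(x$p), "\n")
  invisible(x)
}

#' Pearson chi-square test on a 2x2 contingency table
#'
#' Uncorrected (no Yates continuity correction) chi-square test of
#' independence, the convention used for the cohort's sex-by-group
#' comparison. Equivalent to the closed form
#' \eqn{\chi^2 = N(ad-bc)^2 / (r_1 r_2 c_1 c_2)} with 1 degree of freedom.
#'
#' @param counts 2x2 matrix of nonnegative integer counts
#'   (rows = groups, columns = categories). The p-value is asymptotic;
#'   small expected counts are not flagged.
#' @return an \code{r1_test} record with fields \code{statistic}, \code{p},
#'   \code{df}, \code{method}.
#' @examples
#' chi_square_2x2(matrix(c(52, 29, 12, 23), 2, byrow = TRUE))
#' @export
chi_square_2x2 <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2L, 2L)))
    stop("`counts` must be a 2x2 matrix")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("`counts` must contain nonnegative integers")
  if (sum(counts) < 1) stop("contingency table is empty")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("chi-square undefined: a marginal total is zero")
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  test_result(ht$statistic, ht$p.value, ht$parameter,
              "Pearson chi-square (2x2, no continuity correction)")
}

#' Kruskal-Wallis rank-sum test across groups
#'
#' Tie-corrected H statistic with a chi-square reference distribution on
#' k - 1 degrees of freedom. A degenerate input where every observation is
#' identical returns H = 0, p = 1 rather than an error.
#'
#' @param samples list of numeric vectors, one per group (each nonempty).
#' @return an \code{r1_test} record.
#' @export
kruskal_wallis <- function(samples) {
  if (!is.list(samples) || length(samples) < 2)
    stop("`samples` must be a list of >= 2 groups")
  if (any(!vapply(samples, length, 1L)))
    stop("every group must be nonempty")
  x <- unlist(samples, use.names = FALSE)
  g <- factor(rep(seq_along(samples), lengths(samples)))
  if (length(unique(x)) == 1L)
    return(test_result(0, 1, length(samples) - 1L,
                       "Kruskal-Wallis rank sum test"))
  ht <- stats::kruskal.test(x, g)
  test_result(ht$statistic, ht$p.value, ht$parameter,
              "Kruskal-Wallis rank sum test")
}

#' Two-sample t test
#'
#' Pooled-variance (Student) test by default; Welch's unequal-variance
#' variant with \code{welch = TRUE}.
#'
#' @param x,y numeric samples of length >= 2.
#' @param welch use the Welch correction instead of pooled variance.
#' @return an \code{r1_test} record.
#' @export
two_sample_t <- function(x, y, welch = FALSE) {
  if (length(x) < 2 || length(y) < 2)
    stop("both samples need >= 2 observations")
  if (stats::var(x) == 0 && stats::var(y) == 0)
    stop("zero variance in both samples")
  ht <- stats::t.test(x, y, var.equal = !welch)
  test_result(ht$statistic, ht$p.value, ht$parameter,
              if (welch) "Welch two-sample t test" else "Two-sample t test (pooled variance)")
}

#' ANCOVA F for a group factor adjusting for covariates
#'
#' Least-squares fit of \code{y ~ covariates + group} compared against the
#' covariates-only model by extra sum of squares; the reported F and p are
#' for the group term.
#'
#' @param y numeric response.
#' @param group group labels (coerced to factor; >= 2 levels).
#' @param covariates optional numeric matrix/data.frame of covariates
#'   (e.g. age and 0/1-coded sex), one row per observation.
#' @return an \code{r1_test} record; \code{df} is \code{c(df1, df2)}.
#' @export
ancova_group_F <- function(y, group, covariates = NULL) {
  y <- as.numeric(y)
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2) stop("`group` must have >= 2 levels")
  n <- length(y)
  if (length(group) != n) stop("`y` and `group` lengths differ")
  Xr <- matrix(1, n, 1)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n) stop("covariate rows do not match `y`")
    if (!all(is.finite(covariates))) stop("covariates must be finite; check the covariate columns")
    Xr <- cbind(Xr, covariates)
  }
  G <- stats::model.matrix(~group)[, -1, drop = FALSE]
  Xf <- cbind(Xr, G)
  if (qr(Xf)$rank < ncol(Xf))
    stop("design is rank deficient (group or a covariate such as sex is confounded/constant)")
  rss <- function(X) sum(stats::lm.fit(X, y)$residuals^2)
  rss_r <- rss(Xr)
  rss_f <- rss(Xf)
  df1 <- ncol(Xf) - ncol(Xr)
  df2 <- n - ncol(Xf)
  if (df2 < 1) stop("not enough residual degrees of freedom")
  Fstat <- ((rss_r - rss_f) / df1) / (rss_f / df2)
  p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  test_result(Fstat, p, c(df1, df2), "ANCOVA group F (extra sum of squares)")
}

#' Pearson correlation with a two-sided p-value
#'
#' @param x,y numeric vectors, length >= 3, nonzero variance.
#' @return an \code{r1_test} record; \code{statistic} is r.
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` lengths differ")
  if (length(x) < 3) stop("need n >= 3")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance input to Pearson correlation")
  ht <- stats::cor.test(x, y, method = "pearson")
  test_result(ht$estimate, ht$p.value, ht$parameter, "Pearson correlation")
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, clipped to 1, returned in the
#' input order.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return vector of q-values, same length and order as \code{pvals}.
#' @export
bh_fdr <- function(pvals) {
  pvals <- as.numeric(pvals)
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}
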