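#' Bland-Altman summary of paired percent differences
#'
#' Sample mean and SD (n-1 denominator) of the differences and the 95%
#' limits of agreement `LOA = mean +/- 1.96 * SD`.
#'
#' @param differences numeric vector of (percent) differences, length >= 2.
#' @return List with `mean`, `sd`, `loa_low`, `loa_high`, `n`.
#' @export
bland_altman <- function(differences) {
  differences <- as.numeric(differences)
  if (length(differences) < 2L) stop("need at least two differences")
  if (any(!is.finite(differences))) stop("differences must be finite")
  m <- mean(differences)
  s <- stats::sd(differences)
  list(mean = m, sd = s, loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
       n = length(differences))
}

#' Single-measure intraclass correlation, absolute agreement
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC (McGraw &
#' Wong's ICC(A,1)) computed from the two-way ANOVA mean squares, with the
#' 95% confidence interval from the F-based interval with Satterthwaite
#' degrees of freedom.
#'
#' @param ratings numeric `n x k` matrix: one row per subject, one column
#'   per rater/technique; `n >= 3`, `k >= 2`.
#' @param conf_level confidence level (default 0.95).
#' @return List with `icc`, `ci_low`, `ci_high` and the ANOVA mean squares.
#' @export
icc_single <- function(ratings, conf_level = 0.95) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 3L) stop("need at least 3 subjects")
  if (k < 2L) stop("need at least 2 columns")
  if (any(!is.finite(ratings))) stop("ratings must be finite")
  grand <- mean(ratings)
  sst <- sum((ratings - grand)^2)
  if (sst == 0) stop("zero total variance: ICC undefined")
  rm_ <- rowMeans(ratings); cm_ <- colMeans(ratings)
  ssr <- k * sum((rm_ - grand)^2)
  ssc <- n * sum((cm_ - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))

  alpha <- 1 - conf_level
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  ci_low <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  ci_high <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  list(icc = icc, ci_low = ci_low, ci_high = ci_high,
       msr = msr, msc = msc, mse = mse, n = n, k = k)
}

#' Cronbach's alpha
#'
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(row sums))`.
#'
#' @param ratings numeric `n x k` matrix, `k >= 2`.
#' @export
cronbach_alpha <- function(ratings) {
  ratings <- as.matrix(ratings)
  k <- ncol(ratings)
  if (k < 2L) stop("need at least 2 columns")
  if (any(!is.finite(ratings))) stop("ratings must be finite")
  total_var <- stats::var(rowSums(ratings))
  if (total_var == 0) stop("zero total-score variance: alpha undefined")
  item_var <- sum(apply(ratings, 2, stats::var))
  k / (k - 1) * (1 - item_var / total_var)
}

#' Paired t test
#'
#' Two-sided paired t test on the differences, df = n - 1. Identical inputs
#' give `t = 0, p = 1`; zero-variance differences with nonzero mean are a
#' degenerate input and raise an error.
#'
#' @param x,y equal-length numeric vectors, n >= 2.
#' @return List with `t`, `df`, `p`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 2L) stop("need at least two pairs")
  d <- x - y
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) return(list(t = 0, df = n - 1, p = 1))
    stop("differences are constant and nonzero: t statistic undefined")
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Pearson correlation with two-sided p value
#'
#' @param x,y equal-length numeric vectors, n >= 3, each with nonzero
#'   variance.
#' @return List with `r` and `p`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least three pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance input: correlation undefined")
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), p = ht$p.value)
}

#' Significance reclassification between two techniques
#'
#' Classifies each subject's uptake as significant (percent difference vs
#' the normal reference strictly above `threshold`) under technique A and
#' technique B, and counts class changes. Percentages are rounded to the
#' nearest integer, matching clinical-table convention.
#'
#' @param tbr_a,tbr_b per-subject TBRmax under the two techniques.
#' @param diff_a,diff_b per-subject percent differences vs the normal-aorta
#'   reference under the two techniques.
#' @param threshold significance threshold in percent (default 25).
#' @return List with counts `insig_to_sig`, `sig_to_insig`, `unchanged`,
#'   per-technique significant counts and integer percentages, and `n`.
#' @export
reclassification_table <- function(tbr_a, tbr_b, diff_a, diff_b,
                                   threshold = 25) {
  n <- length(diff_a)
  if (length(diff_b) != n || length(tbr_a) != n || length(tbr_b) != n)
    stop("input lengths differ")
  sig_a <- classify_significant(diff_a, threshold)
  sig_b <- classify_significant(diff_b, threshold)
  list(n = n,
       insig_to_sig = sum(!sig_a & sig_b),
       sig_to_insig = sum(sig_a & !sig_b),
       unchanged = sum(sig_a == sig_b),
       n_sig_a = sum(sig_a), n_sig_b = sum(sig_b),
       pct_sig_a = as.integer(round(100 * sum(sig_a) / n)),
       pct_sig_b = as.integer(round(100 * sum(sig_b) / n)),
       mean_tbr_a = mean(tbr_a), mean_tbr_b = mean(tbr_b))
}
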