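#' Bland-Altman agreement analysis
#'
#' @param x,y paired measurements (equal length >= 2). Differences are
#'   `y - x`.
#' @return list with `bias` (mean difference), `sd` (SD of differences,
#'   denominator n-1), `lower` and `upper` 95% limits of agreement
#'   (`bias -+ 1.96 * sd`), and `n`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need at least 2 pairs")
  d <- y - x
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, sd = s, lower = bias - 1.96 * s,
       upper = bias + 1.96 * s, n = length(d))
}

#' Coefficient of determination (squared Pearson correlation)
#'
#' @param x,y numeric vectors, >= 3 pairs, neither constant.
#' @return r-squared in \[0, 1\].
#' @export
r_squared <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input: correlation undefined")
  }
  stats::cor(x, y)^2
}

#' Two-sample Wilcoxon rank-sum test
#'
#' For combined sample size at most `exact_max_n`, the two-sided p-value is
#' computed by full enumeration of all rank assignments (midranks under
#' ties): p = min(1, 2 * min(P(W <= w), P(W >= w))) where W is the rank sum
#' of the first sample. For larger samples the normal approximation with
#' tie correction and continuity correction is used.
#'
#' @param a,b numeric samples (non-empty).
#' @param exact_max_n combined-size cutoff for exact enumeration.
#' @return list with `p_value`, `statistic` (rank sum of `a`) and `method`.
#' @export
wilcoxon_rank_sum <- function(a, b, exact_max_n = 12) {
  if (length(a) == 0 || length(b) == 0) stop("samples must be non-empty")
  na <- length(a); nb <- length(b); N <- na + nb
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1) {
    warning("all values tied across both samples; p = 1")
    return(list(p_value = 1, statistic = sum(rank(pooled)[seq_len(na)]),
                method = "degenerate"))
  }
  r <- rank(pooled)
  w <- sum(r[seq_len(na)])
  if (N <= exact_max_n) {
    cmb <- utils::combn(N, na)
    sums <- colSums(matrix(r[cmb], nrow = na))
    eps <- 1e-9
    p_le <- mean(sums <= w + eps)
    p_ge <- mean(sums >= w - eps)
    p <- min(1, 2 * min(p_le, p_ge))
    return(list(p_value = p, statistic = w, method = "exact enumeration"))
  }
  mu <- na * (N + 1) / 2
  ties <- table(r)
  sigma2 <- na * nb / 12 *
    ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  z_num <- w - mu
  z <- (z_num - sign(z_num) * 0.5) / sqrt(sigma2)
  list(p_value = min(1, 2 * stats::pnorm(-abs(z))), statistic = w,
       method = "normal approximation (tie-corrected)")
}

#' Bonferroni significance flags
#'
#' Flags p-values significant at family level `alpha` over `m`
#' simultaneous comparisons: flag i is `p[i] <= alpha / m`.
#'
#' @param p_values numeric vector of p-values.
#' @param alpha family-wise significance level.
#' @param m number of simultaneous comparisons (>= length(p_values), > 0).
#' @return logical vector.
#' @export
bonferroni_flags <- function(p_values, alpha = 0.05,
                             m = length(p_values)) {
  if (m == 0) stop("number of comparisons must be positive")
  if (m < length(p_values)) {
    stop("m must be at least the number of p-values")
  }
  p_values <= alpha / m
}

#' Median and interquartile range summary
#'
#' @param x numeric vector.
#' @return named numeric `c(median, q1, q3)` (type-7 quantiles).
#' @export
median_iqr <- function(x) {
  q <- stats::quantile(x, c(0.5, 0.25, 0.75), names = FALSE)
  c(median = q[1], q1 = q[2], q3 = q[3])
}
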