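#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the transformed skewness statistic (D'Agostino 1970) and the
#' transformed kurtosis statistic (Anscombe-Glynn 1983) into
#' `K^2 = Z1^2 + Z2^2`, referred to a chi-squared distribution with 2 df.
#' Requires `n >= 8` (the kurtosis transform is undefined below that).
#'
#' @param x numeric sample, `n >= 8`.
#' @return list with `statistic` (K^2), `p_value`, `z_skewness`, `z_kurtosis`
#'   and `n`.
#' @export
normality_test <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8L)
    abort_input(sprintf(
      "D'Agostino-Pearson test needs n >= 8 observations, got %d", n))
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  if (m2 == 0) abort_input("sample is constant; normality test undefined")

  ## skewness component (D'Agostino 1970)
  b1 <- m3 / m2^1.5
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * asinh(y / alpha)

  ## kurtosis component (Anscombe-Glynn 1983)
  b2 <- m4 / m2^2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sqrtb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqrtb1 * (2 / sqrtb1 + sqrt(1 + 4 / sqrtb1^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z1^2 + z2^2
  list(statistic = k2, p_value = pchisq(k2, 2, lower.tail = FALSE),
       z_skewness = z1, z_kurtosis = z2, n = n)
}

#' Compare two groups with the normality-gated decision tree
#'
#' The statistical routing rule of the study: test each group for normality
#' (D'Agostino-Pearson); if both pass, check variance equality (F test) and
#' run a pooled or Welch t-test accordingly; if either fails, run a
#' Mann-Whitney test. All tests are two-sided. Groups smaller than 8 (where
#' the normality test is undefined) are routed to Mann-Whitney with a warning.
#' Group summaries are reported as median and IQR, the study's convention.
#'
#' @param a,b numeric samples (each `n >= 2`).
#' @param alpha_normality significance level of the normality gate
#'   (default 0.05).
#' @param alpha_variance significance level of the variance-equality gate
#'   (default 0.05).
#' @return a `GroupComparison`: list with `test_used` (`"t"`, `"t_welch"` or
#'   `"mann_whitney"`), `p_value`, `normality_p_A`, `normality_p_B`,
#'   `variance_equal`, and `summary` (median and IQR per group).
#' @export
compare_two_groups <- function(a, b, alpha_normality = 0.05,
                               alpha_variance = 0.05) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L)
    abort_input("each group needs at least 2 finite values")
  small <- length(a) < 8L || length(b) < 8L
  np_a <- np_b <- NA_real_
  if (sd(a) == 0 || sd(b) == 0) {
    ## constant data: the normality gate is undefined; degenerate samples go
    ## down the nonparametric route
    route <- "mann_whitney"
    var_eq <- NA
  } else if (small) {
    warning("group below n = 8: normality gate undefined, using Mann-Whitney")
    route <- "mann_whitney"
    var_eq <- NA
  } else {
    np_a <- normality_test(a)$p_value
    np_b <- normality_test(b)$p_value
    if (np_a > alpha_normality && np_b > alpha_normality) {
      var_eq <- var.test(a, b)$p.value > alpha_variance
      route <- if (var_eq) "t" else "t_welch"
    } else {
      route <- "mann_whitney"
      var_eq <- NA
    }
  }
  p <- switch(route,
    t = t.test(a, b, var.equal = TRUE)$p.value,
    t_welch = t.test(a, b, var.equal = FALSE)$p.value,
    mann_whitney = suppressWarnings(wilcox.test(a, b, exact = NULL)$p.value))
  summ <- data.frame(
    group = c("A", "B"),
    n = c(length(a), length(b)),
    median = c(median(a), median(b)),
    iqr_low = c(quantile(a, 0.25), quantile(b, 0.25)),
    iqr_high = c(quantile(a, 0.75), quantile(b, 0.75)))
  structure(list(test_used = route, p_value = p,
                 normality_p_A = np_a, normality_p_B = np_b,
                 variance_equal = var_eq, summary = summ),
            class = "GroupComparison")
}

#' @export
print.GroupComparison <- function(x, ...) {
  cat(sprintf("<GroupComparison> %s, p = %.4g\n", x$test_used, x$p_value))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D = sup |ECDF_A - ECDF_B|` with its two-sided p-value (exact for small
#' untied samples, asymptotic otherwise; delegated to [stats::ks.test()]).
#'
#' @param a,b numeric samples, each `n >= 2`.
#' @return list with `D` and `p_value`.
#' @export
ks_two_sample <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L)
    abort_input("each sample needs at least 2 finite values")
  res <- suppressWarnings(ks.test(a, b))
  list(D = unname(res$statistic), p_value = res$p.value)
}

#' Fisher's exact test for a 2x2 table
#'
#' Conditional exact test: with all margins fixed, the two-sided p-value is
#' the total hypergeometric probability of all tables at least as extreme as
#' (i.e. with point probability not exceeding) the observed one.
#'
#' @param table 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @return list with `odds_ratio` (sample odds ratio `ad/bc`) and `p_value`.
#' @export
fisher_exact <- function(table) {
  tb <- as.matrix(table)
  if (!all(dim(tb) == c(2L, 2L))) abort_input("`table` must be 2x2")
  if (any(tb < 0) || any(tb != round(tb))) abort_input("counts must be non-negative integers")
  if (any(rowSums(tb) == 0) || any(colSums(tb) == 0))
    abort_input("all margins must be positive")
  m <- sum(tb[1, ]); n <- sum(tb[2, ]); k <- sum(tb[, 1])
  support <- max(0L, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(tb[1, 1], m, n, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  or <- (tb[1, 1] * tb[2, 2]) / (tb[1, 2] * tb[2, 1])
  list(odds_ratio = or, p_value = min(1, p))
}

#' Bonferroni adjustment
#'
#' @param p numeric p-values in `[0, 1]`.
#' @param m number of comparisons (defaults to `length(p)`, must be >= that).
#' @return adjusted p-values `min(1, p * m)`.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    abort_input("p-values must lie in [0, 1]")
  if (m < length(p)) abort_input("`m` must be >= number of p-values")
  pmin(1, p * m)
}
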