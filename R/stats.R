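#' Median and interquartile range
#'
#' Quartiles use the linear-interpolation convention between order
#' statistics (type 7), stated here because IQR bounds differ across
#' conventions.
#'
#' @param values numeric vector, length >= 1.
#' @return named vector `c(median, q1, q3)`.
#' @export
median_iqr <- function(values) {
  if (length(values) < 1) stop("median_iqr: empty input")
  q <- quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(median = q[2], q1 = q[1], q3 = q[3])
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided test on paired differences `x - y`. Absolute differences are
#' ranked with midranks for ties and the statistic is `W = min(W+, W-)`.
#' When `n_effective <= 25` and there are no ties among the nonzero
#' absolute differences, the p-value is exact: the fraction of the `2^n`
#' equiprobable sign assignments whose `min(W+, W-)` is at most the
#' observed value (computed by shift convolution, identical to full
#' enumeration). Otherwise a normal approximation with continuity and tie
#' correction is used. Zero differences are dropped by default
#' (`zero_policy = "wilcoxon"`) or kept in the ranking then removed from
#' the statistic (`"pratt"`).
#'
#' @param x,y paired numeric vectors (or `y` missing: `x` = differences).
#' @param zero_policy `"wilcoxon"` (drop zeros, classical default) or
#'   `"pratt"`.
#' @param alpha significance threshold stored in the result (e.g. a
#'   Bonferroni-corrected level).
#' @return object of class `signed_rank_test`: `statistic` (W), `p_value`,
#'   `n_effective`, `method` (`"exact"` / `"normal_approx"`),
#'   `significant_at`, `degenerate`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL,
                                 zero_policy = c("wilcoxon", "pratt"),
                                 alpha = 0.05) {
  zero_policy <- match.arg(zero_policy)
  d <- if (is.null(y)) as.numeric(x) else as.numeric(x) - as.numeric(y)
  d <- d[!is.na(d)]
  nonzero <- d != 0
  if (!any(nonzero)) {
    return(structure(list(statistic = 0, p_value = 1, n_effective = 0L,
                          method = "degenerate", significant_at = alpha,
                          degenerate = TRUE),
                     class = "signed_rank_test"))
  }

  if (zero_policy == "wilcoxon") {
    dd <- d[nonzero]
    r <- rank(abs(dd))
  } else {
    r_all <- rank(abs(d))
    dd <- d[nonzero]
    r <- r_all[nonzero]
  }
  n_eff <- length(dd)
  w_plus <- sum(r[dd > 0])
  w_minus <- sum(r[dd < 0])
  W <- min(w_plus, w_minus)
  ties <- anyDuplicated(abs(dd)) > 0 || (zero_policy == "pratt" && any(!nonzero))

  if (n_eff <= 25 && !ties) {
    # exact distribution of W+ over all 2^n sign assignments
    cnt <- signrank_counts(n_eff)  # counts for W+ = 0..n(n+1)/2
    tot <- 2^n_eff
    # two-sided: P(min(W+, W-) <= W_obs); by symmetry of the null
    # distribution this is P(W+ <= W) + P(W+ >= n(n+1)/2 - W)
    m <- n_eff * (n_eff + 1) / 2
    p <- (sum(cnt[seq_len(W + 1)]) + sum(cnt[(m - W + 1):(m + 1)])) / tot
    p <- min(1, p)
    method <- "exact"
  } else {
    mu <- n_eff * (n_eff + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n_eff * (n_eff + 1) * (2 * n_eff + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (w_plus - mu - sign(w_plus - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal_approx"
  }
  structure(list(statistic = W, p_value = p, n_effective = n_eff,
                 method = method, significant_at = alpha,
                 degenerate = FALSE),
            class = "signed_rank_test")
}

# number of sign assignments with each value of W+ (0..n(n+1)/2),
# untied ranks 1..n; classic shift convolution
signrank_counts <- function(n) {
  m <- n * (n + 1) / 2
  cnt <- numeric(m + 1)
  cnt[1] <- 1
  for (k in seq_len(n)) {
    shifted <- c(numeric(k), cnt[seq_len(m + 1 - k)])
    cnt <- cnt + shifted
  }
  cnt
}

#' @export
print.signed_rank_test <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank: W = %g, n = %d, p = %.4g (%s)%s\n",
              x$statistic, x$n_effective, x$p_value, x$method,
              if (x$p_value < x$significant_at)
                sprintf(" significant at %.4g", x$significant_at) else ""))
  invisible(x)
}

#' Bonferroni-corrected significance threshold
#'
#' @param family_alpha family-wise level (e.g. 0.05).
#' @param m number of comparisons (>= 1).
#' @return `family_alpha / m` (unrounded; the reporting layer prints 3
#'   decimals, e.g. 0.05/6 prints as .008).
#' @export
bonferroni_alpha <- function(family_alpha = 0.05, m = 1) {
  stopifnot(m >= 1, family_alpha > 0)
  family_alpha / m
}

#' Single-measures intraclass correlation, two-way absolute agreement
#'
#' ICC(A,1) in the McGraw & Wong nomenclature: a two-way model with
#' absolute agreement on single measures, computed from the two-way ANOVA
#' mean squares, with the standard F-based 95% confidence interval.
#' Absolute agreement (rather than consistency) is the appropriate form
#' when the question is whether two measurement methods agree, not merely
#' co-vary.
#'
#' @param x,y paired measurements (one rater/method per vector), n >= 5.
#' @param conf_level confidence level for the interval.
#' @return object of class `icc_result`: `estimate`, `ci` (lower, upper),
#'   `model` (descriptor string), `n`, `degenerate` (zero between-subject
#'   variance).
#' @export
icc_single <- function(x, y, conf_level = 0.95) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5) stop("icc_single needs at least 5 complete pairs")
  k <- 2
  M <- cbind(x, y)
  grand <- mean(M)
  row_m <- rowMeans(M)
  col_m <- colMeans(M)
  MSR <- k * sum((row_m - grand)^2) / (n - 1)          # rows (subjects)
  MSC <- n * sum((col_m - grand)^2) / (k - 1)          # columns (methods)
  resid <- M - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + grand
  MSE <- sum(resid^2) / ((n - 1) * (k - 1))

  degenerate <- MSR <= MSE
  denom <- MSR + (k - 1) * MSE + k * (MSC - MSE) / n
  est <- if (denom <= 0) 0 else (MSR - MSE) / denom
  if (degenerate && est < 0) est <- max(est, -1)

  # McGraw & Wong (1996) CI for ICC(A,1)
  alpha <- 1 - conf_level
  a <- k * est / (n * (1 - est))
  b <- 1 + k * est * (n - 1) / (n * (1 - est))
  v <- (a * MSC + b * MSE)^2 /
    ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
  FL <- qf(1 - alpha / 2, n - 1, v)
  FU <- qf(1 - alpha / 2, v, n - 1)
  lower <- n * (MSR - FL * MSE) /
    (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  upper <- n * (FU * MSR - MSE) /
    (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
  # perfect agreement (MSE ~ 0) collapses the F-based interval
  if (!is.finite(lower) || !is.finite(upper)) {
    lower <- upper <- est
  }
  lower <- max(-1, min(lower, est))
  upper <- min(1, max(upper, est))

  structure(list(estimate = est, ci = c(lower = lower, upper = upper),
                 model = "two-way, absolute agreement, single measures (ICC(A,1))",
                 n = n, degenerate = degenerate),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(A,1) = %.3f (95%% CI %.3f-%.3f), n = %d%s\n",
              x$estimate, x$ci[1], x$ci[2], x$n,
              if (x$degenerate) " [degenerate: no between-subject variance]" else ""))
  invisible(x)
}

#' A-priori sample size for detecting a correlation
#'
#' Smallest n whose power for the two-sided test of rho = 0 against a
#' bivariate-normal correlation `rho` reaches `power`. Power is computed
#' from the bias-corrected Fisher z distribution of the sample correlation
#' (mean `atanh(rho) + rho / (2 (n - 1))`, sd `1 / sqrt(n - 3)`) against
#' the t-based critical r. With rho = 0.4, alpha = 0.05, power = 0.95 this
#' returns 75 pairs.
#'
#' @param rho assumed population correlation, 0 < rho < 1.
#' @param alpha two-sided (or one-sided) significance level.
#' @param power target power, 0 < power < 1.
#' @param two_tailed logical.
#' @param n_max search cap (error if power is unattainable below it).
#' @return integer sample size.
#' @export
sample_size_for_correlation <- function(rho, alpha = 0.05, power = 0.95,
                                        two_tailed = TRUE, n_max = 100000) {
  stopifnot(rho > 0, rho < 1, alpha > 0, alpha < 1, power > 0, power < 1)
  for (n in 5:n_max) {
    if (correlation_power(n, rho, alpha, two_tailed) >= power) return(n)
  }
  stop("sample_size_for_correlation: target power unattainable below n_max")
}

#' @rdname sample_size_for_correlation
#' @param n sample size (>= 5).
#' @export
correlation_power <- function(n, rho, alpha = 0.05, two_tailed = TRUE) {
  df <- n - 2
  tail_alpha <- if (two_tailed) alpha / 2 else alpha
  tcrit <- qt(1 - tail_alpha, df)
  rcrit <- tcrit / sqrt(df + tcrit^2)
  mu <- atanh(rho) + rho / (2 * (n - 1))
  s <- 1 / sqrt(n - 3)
  p <- pnorm(atanh(rcrit), mu, s, lower.tail = FALSE)
  if (two_tailed) p <- p + pnorm(atanh(-rcrit), mu, s)
  p
}
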