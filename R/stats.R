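#' Kruskal-Wallis rank-sum test across groups
#'
#' Rank-based k-group comparison with midrank tie handling and the
#' standard tie correction; the H statistic is referred to a chi-square
#' distribution with k-1 degrees of freedom. Per-group mean ranks are
#' reported (they are what the cohort summary tables print).
#'
#' @param groups list of numeric vectors, one per group (>= 2 groups,
#'   each non-empty).
#' @param exact if TRUE, compute the p-value by exhaustive enumeration of
#'   all assignments of the pooled values to groups (only feasible for
#'   tiny samples); otherwise use the chi-square approximation.
#' @return list with `H`, `df`, `p_value`, `mean_ranks`, `n`.
#' @examples
#' kruskal_wallis(list(c(1, 2), c(3, 4)))
#' @export
kruskal_wallis <- function(groups, exact = FALSE) {
  if (!is.list(groups) || length(groups) < 2 || any(lengths(groups) < 1)) {
    stop_invalid("groups must be a list of >= 2 non-empty numeric vectors")
  }
  k <- length(groups)
  ns <- lengths(groups)
  N <- sum(ns)
  g <- rep(seq_len(k), ns)
  x <- unlist(groups, use.names = FALSE)
  H <- kw_statistic(x, g, k, ns, N)
  mean_ranks <- tapply(rank(x), g, mean)
  if (exact) {
    p <- kw_exact_p(x, ns, H)
  } else {
    p <- if (is.nan(H)) 1 else stats::pchisq(H, df = k - 1, lower.tail = FALSE)
  }
  if (is.nan(H)) H <- 0  # all pooled values identical: no evidence, p = 1
  list(H = H, df = k - 1L, p_value = p,
       mean_ranks = as.numeric(mean_ranks), n = as.integer(ns))
}

kw_statistic <- function(x, g, k, ns, N) {
  r <- rank(x)  # midranks
  Rbar <- tapply(r, g, mean)
  H <- 12 / (N * (N + 1)) * sum(ns * (Rbar - (N + 1) / 2)^2)
  ties <- table(x)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H / corr  # NaN when all values tie (corr 0); caller maps to H=0, p=1
}

# Exact permutation p: enumerate all distinct assignments of pooled
# values into groups of the given sizes.
kw_exact_p <- function(x, ns, H_obs) {
  N <- length(x)
  k <- length(ns)
  idx_all <- seq_len(N)
  stats <- numeric(0)
  recurse <- function(remaining, sizes) {
    if (length(sizes) == 1) return(list(list(remaining)))
    first <- utils::combn(remaining, sizes[1], simplify = FALSE)
    out <- list()
    for (f in first) {
      rest <- recurse(setdiff(remaining, f), sizes[-1])
      for (r in rest) out[[length(out) + 1]] <- c(list(f), r)
    }
    out
  }
  parts <- recurse(idx_all, ns)
  stats <- vapply(parts, function(p) {
    g <- integer(N)
    for (i in seq_len(k)) g[p[[i]]] <- i
    kw_statistic(x, g, k, ns, N)
  }, numeric(1))
  if (is.nan(H_obs)) return(1)
  mean(stats >= H_obs - 1e-12)
}

#' Pearson product-moment correlation with two-tailed p-value
#'
#' @param x,y numeric vectors of equal length `n >= 3` with nonzero
#'   variance.
#' @return list with `r`, `p_value` (two-tailed, t transform with n-2
#'   df), `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop_invalid("x and y must have equal length >= 3")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop(errorCondition("correlation undefined: zero variance",
                        class = c("perioFD_undefined_correlation", "error")))
  }
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  p <- if (abs(r) >= 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  list(r = r, p_value = p, n = n)
}

#' Chi-square test of independence for a contingency table
#'
#' Expected counts from the margins; `chi2 = sum((O - E)^2 / E)` with
#' `df = (r - 1)(c - 1)`. No continuity correction (matching the usual
#' r x c cross-tabulation output).
#'
#' @param tab matrix of non-negative counts, >= 2 rows and columns.
#' @return list with `chi2`, `df`, `p_value`, `expected`.
#' @export
chi_square_independence <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2 || any(tab < 0)) {
    stop_invalid("table must be >= 2x2 with non-negative counts")
  }
  rs <- rowSums(tab); cs <- colSums(tab); N <- sum(tab)
  if (any(rs == 0) || any(cs == 0)) {
    stop(errorCondition("degenerate table: zero row or column margin",
                        class = c("perioFD_degenerate_table", "error")))
  }
  E <- outer(rs, cs) / N
  chi2 <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(chi2 = chi2, df = df,
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
       expected = E)
}

#' Power of the chi-square test at a given effect size and sample size
#'
#' A priori power computation for chi-square goodness-of-fit /
#' contingency tests: the noncentrality parameter is `lambda = n * w^2`
#' (Cohen's effect size `w`), the critical value is the `1 - alpha`
#' quantile of the central chi-square, and the power is the upper-tail
#' probability of the noncentral chi-square beyond it.
#'
#' @param w effect size (> 0).
#' @param n_total total sample size (>= 1).
#' @param df degrees of freedom of the test.
#' @param alpha significance level.
#' @return list with `w`, `n_total`, `df`, `alpha`, `lambda`,
#'   `critical_chi2`, `power`.
#' @examples
#' chi_square_power(0.5, 70, 12, 0.05)
#' @export
chi_square_power <- function(w, n_total, df, alpha = 0.05) {
  if (w <= 0 || n_total < 1 || df < 1 || alpha <= 0 || alpha >= 1) {
    stop_invalid("require w > 0, n_total >= 1, df >= 1, alpha in (0, 1)")
  }
  lambda <- n_total * w^2
  crit <- stats::qchisq(1 - alpha, df)
  power <- stats::pchisq(crit, df, ncp = lambda, lower.tail = FALSE)
  list(w = w, n_total = as.integer(n_total), df = as.integer(df),
       alpha = alpha, lambda = lambda, critical_chi2 = crit, power = power)
}

#' Smallest sample size reaching a target chi-square power
#'
#' @param w effect size.
#' @param df degrees of freedom.
#' @param alpha significance level.
#' @param target_power required power, in `(alpha, 1)`.
#' @return the smallest integer `n` with power >= `target_power`.
#' @examples
#' required_sample_size(0.5, 12, 0.05, 0.80)
#' @export
required_sample_size <- function(w, df, alpha = 0.05, target_power = 0.80) {
  if (target_power <= alpha || target_power >= 1) {
    stop_invalid("target_power must lie in (alpha, 1)")
  }
  lo <- 1L; hi <- 2L
  while (chi_square_power(w, hi, df, alpha)$power < target_power) {
    lo <- hi
    hi <- hi * 2L
    if (hi > 1e7) stop_invalid("sample size search exceeded 1e7")
  }
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (chi_square_power(w, mid, df, alpha)$power >= target_power) hi <- mid else lo <- mid + 1L
  }
  hi
}

#' Shapiro-Wilk normality test
#'
#' Contract wrapper over the vetted standard routine (the W statistic's
#' coefficient tables are not re-derived here).
#'
#' @param x numeric vector, 3 <= n <= 5000, non-constant.
#' @return list with `W` (in (0, 1\]) and `p_value`.
#' @export
shapiro_wilk <- function(x) {
  if (length(x) < 3 || length(x) > 5000) stop_invalid("require 3 <= n <= 5000")
  if (stats::sd(x) == 0) {
    stop(errorCondition("Shapiro-Wilk undefined for a constant sample",
                        class = c("perioFD_invalid_argument", "error")))
  }
  sw <- stats::shapiro.test(x)
  list(W = unname(sw$statistic), p_value = sw$p.value)
}

#' Pool per-group means and SDs into an overall mean and SD
#'
#' The identity used to reproduce "Total" rows of group summary tables:
#' pooled mean is the n-weighted mean; pooled variance combines
#' within-group variance and between-group spread,
#' `[sum((n_i - 1) s_i^2) + sum(n_i (m_i - m)^2)] / (sum(n_i) - 1)`.
#'
#' @param means,sds,ns equal-length vectors of per-group means, SDs and
#'   sizes (each `n_i >= 2`).
#' @return list with `mean`, `sd`, `n`.
#' @examples
#' pooled_summary(c(12.1, 25.4, 57.9, 77.0), c(2.6, 4.7, 6.1, 10.3), rep(15, 4))
#' @export
pooled_summary <- function(means, sds, ns) {
  if (length(means) != length(sds) || length(means) != length(ns)) {
    stop_invalid("means, sds, ns must have equal length")
  }
  if (any(ns < 2)) stop_invalid("all group sizes must be >= 2")
  N <- sum(ns)
  m <- sum(ns * means) / N
  v <- (sum((ns - 1) * sds^2) + sum(ns * (means - m)^2)) / (N - 1)
  list(mean = m, sd = sqrt(v), n = as.integer(N))
}
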