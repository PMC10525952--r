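# cohort_statistics module

test_that("Kruskal-Wallis handles identical groups, ties, and reports mean ranks", {
  res <- kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_equal(res$H, 0)
  expect_equal(res$p_value, 1)
  # weighted mean of mean ranks is (N+1)/2
  expect_equal(sum(res$n * res$mean_ranks), sum(res$n) * (sum(res$n) + 1) / 2)

  # all pooled values identical: defined as H = 0, p = 1
  res0 <- kruskal_wallis(list(c(5, 5), c(5, 5, 5)))
  expect_equal(res0$H, 0)
  expect_equal(res0$p_value, 1)
  expect_error(kruskal_wallis(list(1:3)), class = "perioFD_invalid_argument")
})

test_that("exact permutation p-value matches the enumerated distribution for {1,2} vs {3,4}", {
  # Enumerating all 4!/(2!2!) = 6 assignments of ranks {1,2,3,4} into two
  # pairs gives H in {2.4, 0.6, 0} with probabilities 2/6 each, so
  # P(H >= 2.4) = 1/3 for the observed split {1,2} | {3,4}.
  res <- kruskal_wallis(list(c(1, 2), c(3, 4)), exact = TRUE)
  expect_equal(res$H, 2.4)
  expect_equal(res$p_value, 1 / 3)
})

test_that("Kruskal-Wallis agrees with the reference implementation and is monotone-invariant", {
  set.seed(41)
  for (i in 1:20) {
    g <- lapply(sample(3:6, 3, replace = TRUE), function(n) round(rnorm(n, sd = 2), 1))
    mine <- kruskal_wallis(g)
    ref <- stats::kruskal.test(g)
    expect_equal(mine$H, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
    # strictly monotone transform of pooled data leaves H unchanged
    tr <- kruskal_wallis(lapply(g, function(v) exp(v / 3) + 1))
    expect_equal(tr$H, mine$H, tolerance = 1e-12)
  }
})

test_that("Pearson correlation matches closed forms and the reference implementation", {
  x <- c(1, 2, 4, 7, 11)
  res <- pearson_correlation(x, -2 * x + 5)
  expect_equal(res$r, -1.0, tolerance = 1e-12)
  expect_equal(res$p_value, 0)

  set.seed(8)
  for (i in 1:20) {
    a <- rnorm(15); b <- 0.4 * a + rnorm(15)
    mine <- pearson_correlation(a, b)
    ref <- stats::cor.test(a, b)
    expect_equal(mine$r, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  }
  expect_error(pearson_correlation(rep(1, 5), rnorm(5)),
               class = "perioFD_undefined_correlation")
})

test_that("correlation p-values are uniform under the null (calibration, 1000 reps)", {
  set.seed(1234)
  pv <- replicate(1000, {
    x <- rnorm(20)
    pearson_correlation(x, rnorm(20))$p_value
  })
  ks <- suppressWarnings(stats::ks.test(pv, "punif"))
  expect_gt(ks$p.value, 0.001)
  expect_lt(abs(mean(pv < 0.05) - 0.05), 0.025)
})

test_that("chi-square independence matches the direct formula", {
  even <- matrix(10, 2, 2)
  res <- chi_square_independence(even)
  expect_equal(res$chi2, 0)
  expect_equal(res$p_value, 1)

  perfect <- matrix(c(20, 0, 0, 20), 2, 2)
  res2 <- chi_square_independence(perfect)
  expect_equal(res2$chi2, 40)
  expect_equal(res2$df, 1L)

  set.seed(21)
  for (i in 1:10) {
    tab <- matrix(rpois(20, 8) + 1, 5, 4)
    mine <- chi_square_independence(tab)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(mine$chi2, sum((tab - E)^2 / E), tolerance = 1e-12)
    expect_equal(mine$df, 12L)
  }
  expect_error(chi_square_independence(matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE)),
               class = "perioFD_degenerate_table")
})

test_that("chi-square power analysis reproduces the published a priori block", {
  res <- chi_square_power(0.5, 70, 12, 0.05)
  expect_equal(res$lambda, 17.5)
  expect_equal(res$critical_chi2, 21.0260698, tolerance = 1e-7)
  expect_equal(res$power, 0.8046698, tolerance = 1e-7)

  # w -> 0: power -> alpha
  expect_equal(chi_square_power(1e-8, 70, 12, 0.05)$power, 0.05, tolerance = 1e-6)
  # power strictly increases with n
  expect_gt(chi_square_power(0.5, 140, 12, 0.05)$power, res$power)
})

test_that("power matches a Monte-Carlo estimate at the alternative (w = 0.5, n = 70, df = 12)", {
  # Alternative multinomial with 13 cells and Cohen's w exactly 0.5
  k <- 13
  p0 <- rep(1 / k, k)
  a <- sqrt(0.25 / (2 * 6 * k))
  p1 <- p0 + c(rep(a, 6), rep(-a, 6), 0)
  expect_equal(sqrt(sum((p1 - p0)^2 / p0)), 0.5, tolerance = 1e-12)
  crit <- qchisq(0.95, k - 1)
  set.seed(99)
  nrep <- 10000
  rej <- replicate(nrep, {
    o <- as.vector(rmultinom(1, 70, p1))
    sum((o - 70 * p0)^2 / (70 * p0)) > crit
  })
  target <- chi_square_power(0.5, 70, 12, 0.05)$power
  mc_se <- sqrt(target * (1 - target) / nrep)
  expect_lt(abs(mean(rej) - target), 3 * mc_se + 0.01) # small chi-square-approx slack
})

test_that("required sample size reproduces N = 70 and is monotone", {
  expect_equal(required_sample_size(0.5, 12, 0.05, 0.80), 70L)
  expect_lte(required_sample_size(0.5, 12, 0.05, 0.051), 5L)
  expect_gte(required_sample_size(0.5, 12, 0.05, 0.95),
             required_sample_size(0.5, 12, 0.05, 0.80))
})

test_that("Shapiro-Wilk contract: W bounded, bimodal rejected, null calibrated", {
  set.seed(7)
  x <- rnorm(50)
  res <- shapiro_wilk(x)
  expect_lte(res$W, 1)
  expect_gt(res$W, 0)

  bimodal <- c(rnorm(25, 0, 0.5), rnorm(25, 100, 0.5))
  expect_lt(shapiro_wilk(bimodal)$p_value, 0.01)

  pv <- replicate(1000, shapiro_wilk(rnorm(50))$p_value)
  ks <- suppressWarnings(stats::ks.test(pv, "punif"))
  expect_gt(ks$p.value, 0.001)
  expect_error(shapiro_wilk(rep(2, 10)), class = "perioFD_invalid_argument")
})

test_that("pooled summary reproduces the published Total rows and degenerate cases", {
  bl <- pooled_summary(c(12.1, 25.4, 57.9, 77.0), c(2.6, 4.7, 6.1, 10.3), rep(15, 4))
  expect_equal(round(bl$mean, 1), 43.1)
  expect_equal(round(bl$sd, 1), 26.7)
  expect_equal(bl$n, 60L)

  fd <- pooled_summary(c(1.21, 1.21, 1.19, 1.11, 1.02),
                       c(0.07, 0.06, 0.05, 0.05, 0.11), rep(15, 5))
  expect_equal(round(fd$mean, 2), 1.15)
  expect_equal(round(fd$sd, 2), 0.10)
  expect_equal(fd$n, 75L)

  one <- pooled_summary(5.5, 1.2, 10)
  expect_equal(one$mean, 5.5)
  expect_equal(one$sd, 1.2)
  # equal groups with zero between-group spread: pooled variance is the
  # within variance shrunk by (N - k)/(N - 1) under the N - 1 denominator
  # (approaches the common SD as n grows; exact only for a single group)
  eq <- pooled_summary(c(3, 3, 3), c(0.8, 0.8, 0.8), c(7, 7, 7))
  expect_equal(eq$sd, 0.8 * sqrt((21 - 3) / (21 - 1)), tolerance = 1e-12)
  big <- pooled_summary(c(3, 3, 3), c(0.8, 0.8, 0.8), c(5000, 5000, 5000))
  expect_equal(big$sd, 0.8, tolerance = 1e-4)
})
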