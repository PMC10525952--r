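# roc_staging module

test_that("empirical ROC endpoints, separation, and tie handling", {
  # perfectly separated: positives strictly below negatives (direction <=)
  sc <- c(1.0, 1.1, 1.2, 1.4, 1.5, 1.6)
  lb <- c(1, 1, 1, 0, 0, 0)
  curve <- empirical_roc(sc, lb)
  expect_equal(curve$fpr[1], 0)
  expect_equal(curve$tpr[1], 0)
  expect_equal(curve$fpr[nrow(curve)], 1)
  expect_equal(curve$tpr[nrow(curve)], 1)
  expect_true(any(curve$fpr == 0 & curve$tpr == 1))
  expect_true(all(diff(curve$fpr) >= 0) && all(diff(curve$tpr) >= 0))

  # labels independent of scores: curve hugs the diagonal
  set.seed(3)
  s2 <- rnorm(2000); l2 <- rbinom(2000, 1, 0.5)
  c2 <- empirical_roc(s2, l2)
  expect_lt(max(abs(c2$tpr - c2$fpr)), 0.1)
  expect_error(empirical_roc(1:5, rep(1, 5)), class = "perioFD_invalid_argument")
})

test_that("ROC points agree with a brute-force threshold sweep", {
  set.seed(10)
  for (i in 1:20) {
    n <- sample(6:18, 1)
    sc <- round(rnorm(n), 1)  # force ties
    lb <- c(1, 0, rbinom(n - 2, 1, 0.5))
    curve <- empirical_roc(sc, lb)
    for (t in sort(unique(sc))) {
      row <- curve[curve$threshold == t, ]
      expect_equal(row$tpr, mean(sc[lb == 1] <= t))
      expect_equal(row$fpr, mean(sc[lb == 0] <= t))
    }
  }
})

test_that("AUC equals the all-pairs Mann-Whitney oracle on 100 random instances", {
  set.seed(55)
  for (i in 1:100) {
    n <- sample(4:20, 1)
    sc <- round(rnorm(n), sample(0:2, 1))  # varied tie intensity
    lb <- c(1, 0, rbinom(n - 2, 1, 0.5))
    expect_equal(roc_auc(sc, lb)$auc, oracle_auc(sc, lb), tolerance = 1e-12)
  }
})

test_that("AUC trivials, label flip, and monotone-transform invariance", {
  expect_equal(roc_auc(c(1, 2, 10, 20), c(1, 1, 0, 0))$auc, 1.0)
  allties <- roc_auc(rep(3.3, 10), rep(c(0, 1), 5))
  expect_equal(allties$auc, 0.5)
  expect_equal(allties$p_vs_half, 1)

  set.seed(17)
  for (i in 1:10) {
    sc <- rnorm(15); lb <- c(1, 0, rbinom(13, 1, 0.4))
    a <- roc_auc(sc, lb)$auc
    expect_equal(roc_auc(sc, 1 - lb)$auc, 1 - a, tolerance = 1e-12)
    expect_equal(roc_auc(exp(sc), lb)$auc, a, tolerance = 1e-12)  # strictly increasing transform
  }
  r <- roc_auc(c(1.0, 1.1, 1.3, 1.4), c(1, 1, 0, 0))
  expect_true(r$ci[1] <= r$auc && r$auc <= r$ci[2])
})

test_that("Youden criterion matches exhaustive enumeration; ties break toward sensitivity", {
  # single positive below single negative
  cv <- empirical_roc(c(1, 2), c(1, 0))
  yc <- youden_criterion(cv)
  expect_equal(yc$criterion, 1)
  expect_equal(yc$sensitivity, 100)
  expect_equal(yc$specificity, 100)
  expect_equal(yc$J, 1)

  # perfectly separated: criterion is the largest positive score
  cv2 <- empirical_roc(c(1.0, 1.1, 1.2, 1.5, 1.6), c(1, 1, 1, 0, 0))
  expect_equal(youden_criterion(cv2)$criterion, 1.2)

  set.seed(66)
  for (i in 1:30) {
    n <- sample(5:20, 1)
    sc <- round(runif(n, 0, 4), 1)
    lb <- c(1, 0, rbinom(n - 2, 1, 0.5))
    yc <- youden_criterion(empirical_roc(sc, lb))
    expect_equal(yc$J, oracle_youden_J(sc, lb), tolerance = 1e-12)
  }
})

test_that("Clopper-Pearson interval reproduces printed bounds and degenerate ends", {
  ci <- clopper_pearson(15, 15)
  expect_equal(round(ci[1], 1), 78.2)
  expect_equal(ci[2], 100)
  expect_equal(clopper_pearson(0, 10)[1], 0)
  ci5 <- clopper_pearson(5, 10)
  expect_true(ci5[1] < 50 && 50 < ci5[2])
})

test_that("Clopper-Pearson achieves at least nominal coverage (p = 0.7, n = 15)", {
  set.seed(202)
  nrep <- 10000
  x <- rbinom(nrep, 15, 0.7)
  covered <- vapply(x, function(s) {
    ci <- clopper_pearson(s, 15)
    ci[1] <= 70 && 70 <= ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.95)
})

test_that("run_situation assembles the right cohorts and rejects bad specs", {
  coh <- simulate_cohort(seed = 4)
  r1 <- run_situation(coh, default_situations()[[1]])
  expect_equal(r1$n, 75)
  expect_equal(r1$n_positive, 60)
  r3 <- run_situation(coh, default_situations()[[3]])
  expect_equal(r3$n, 60)
  r5 <- run_situation(coh, default_situations()[[5]])
  expect_equal(r5$n, 45)
  expect_true(r1$auc_ci[1] <= r1$auc && r1$auc <= r1$auc_ci[2])
  expect_true(all(c(r1$sensitivity, r1$specificity) >= 0) &&
              all(c(r1$sensitivity, r1$specificity) <= 100))

  expect_error(situation_spec("#x", c("I", "II"), c("II", "Control")),
               class = "perioFD_invalid_argument")
  tiny <- coh[coh$stage %in% c("I", "II"), ]
  expect_error(run_situation(tiny, default_situations()[[1]]),
               class = "perioFD_invalid_argument")
})

test_that("staging classifier follows the published cutoffs and is monotone", {
  expect_equal(classify_stage(1.20), "Healthy")
  expect_equal(classify_stage(1.17), "Stage I/II")
  expect_equal(classify_stage(1.12), "Stage III")
  expect_equal(classify_stage(1.05), "Stage IV")
  # boundaries closed on the disease side
  expect_equal(classify_stage(1.188), "Stage I/II")
  expect_equal(classify_stage(1.158), "Stage III")
  expect_equal(classify_stage(1.102), "Stage IV")

  # monotone step function: lower fd never maps to a less severe band
  sev <- c(Healthy = 0, `Stage I/II` = 1, `Stage III` = 2, `Stage IV` = 3)
  grid <- seq(2, 0.01, by = -0.007)
  ranks <- sev[classify_stage(grid)]
  expect_true(all(diff(ranks) >= 0))
  expect_error(classify_stage(-0.1), class = "perioFD_invalid_argument")
  expect_error(staging_rule(1.1, 1.15, 1.2), class = "perioFD_invalid_argument")
})
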