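test_that("ROC handles perfect separation and uninformative scores", {
  s <- c(1, 2, 3, 10, 11, 12)
  lab <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  r <- empirical_roc(s, lab)
  expect_equal(r$auc, 1)
  expect_equal(r$youden_j, 1)
  expect_true(r$optimal_cutoff > 3 && r$optimal_cutoff <= 10)

  tied <- empirical_roc(rep(5, 10), rep(c(TRUE, FALSE), 5))
  expect_equal(tied$auc, 0.5)
  expect_error(empirical_roc(1:5, rep(TRUE, 5)), "degenerate")
})

test_that("AUC equals brute-force pair counting on a toy set with ties", {
  s <- c(10, 12, 12, 15, 20, 22, 25, 12, 30, 31, 15, 40)
  lab <- c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE,
           FALSE, FALSE)
  expect_equal(empirical_roc(s, lab)$auc, auc_paircount(s, lab))
})

test_that("AUC and Youden cutoff match oracles on random instances", {
  set.seed(13)
  for (i in 1:60) {
    n <- sample(6:50, 1)
    npos <- sample(2:(n - 2), 1)
    s <- round(stats::rnorm(n, 30, 15), sample(0:1, 1)) # rounding forces ties
    lab <- c(rep(TRUE, npos), rep(FALSE, n - npos))
    r <- empirical_roc(s, lab)
    expect_equal(r$auc, auc_paircount(s, lab))
    ye <- youden_exhaustive(s, lab)
    expect_equal(r$youden_j, ye$j)
    expect_equal(r$optimal_cutoff, ye$cutoff)
    expect_true(all(r$sensitivity >= 0 & r$sensitivity <= 1))
    expect_true(all(r$specificity >= 0 & r$specificity <= 1))
    expect_true(r$auc >= 0 && r$auc <= 1)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(14)
  s <- stats::rnorm(40, 30, 10)
  lab <- stats::runif(40) < 0.4
  lab[1:2] <- c(TRUE, FALSE)
  a0 <- empirical_roc(s, lab)$auc
  expect_equal(empirical_roc(exp(s / 10), lab)$auc, a0)
  expect_equal(empirical_roc(3 * s - 7, lab)$auc, a0)
  # reversing the scale with the opposite direction gives the same AUC
  expect_equal(empirical_roc(-s, lab, direction = "higher_is_positive")$auc, a0)
})

test_that("DeLong AUC confidence interval agrees with pROC", {
  skip_if_not_installed("pROC")
  set.seed(15)
  for (i in 1:10) {
    s <- c(stats::rnorm(20, 25, 10), stats::rnorm(25, 45, 12))
    lab <- rep(c(TRUE, FALSE), c(20, 25))
    r <- empirical_roc(s, lab)
    pr <- pROC::roc(response = lab, predictor = s, direction = ">",
                    levels = c(FALSE, TRUE), quiet = TRUE)
    expect_equal(r$auc, as.numeric(pROC::auc(pr)))
    ci <- as.numeric(pROC::ci.auc(pr, method = "delong"))
    expect_equal(r$auc_ci[1], max(0, ci[1]), tolerance = 1e-8)
    expect_equal(r$auc_ci[2], min(1, ci[3]), tolerance = 1e-8)
  }
})

test_that("Hanley-McNeil CI is available and brackets the AUC", {
  set.seed(16)
  s <- c(stats::rnorm(20, 25, 10), stats::rnorm(25, 45, 12))
  lab <- rep(c(TRUE, FALSE), c(20, 25))
  r <- empirical_roc(s, lab, ci_method = "hanley")
  expect_true(r$auc_ci[1] <= r$auc && r$auc <= r$auc_ci[2])
  expect_equal(r$ci_method, "hanley")
})

test_that("diagnostic performance counts and proportions are consistent", {
  s <- c(1, 2, 3, 10, 11, 12)
  lab <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  p <- diagnostic_performance(s, lab, 5)
  expect_equal(p$sensitivity$estimate, 1)
  expect_equal(p$specificity$estimate, 1)
  expect_equal(p$accuracy$estimate, 1)

  p2 <- diagnostic_performance(s, lab, 0.5) # below every score
  expect_equal(p2$sensitivity$estimate, 0)
  expect_equal(p2$specificity$estimate, 1)

  set.seed(17)
  for (i in 1:20) {
    sc <- stats::rnorm(30, 30, 15)
    lb <- stats::runif(30) < 0.5
    lb[1:2] <- c(TRUE, FALSE)
    cut <- stats::runif(1, 10, 50)
    pp <- diagnostic_performance(sc, lb, cut)
    expect_equal(unname(pp$counts["TP"] + pp$counts["FN"]), sum(lb))
    expect_equal(unname(pp$counts["TN"] + pp$counts["FP"]), sum(!lb))
    expect_true(pp$sensitivity$ci_lower <= pp$sensitivity$estimate)
    expect_true(pp$sensitivity$ci_upper >= pp$sensitivity$estimate)
  }
})

test_that("cohort accuracy at the reference cut-off equals confusion-matrix enumeration", {
  sc <- scored_default_cohort()
  p <- diagnostic_performance(sc$ccar_pct, sc$do_status, 36.4)
  pred <- predict_do(sc$ccar_pct, 36.4)
  acc_oracle <- sum(pred == sc$do_status) / nrow(sc)
  expect_equal(p$accuracy$estimate, acc_oracle)
  expect_equal(sum(p$counts), nrow(sc))
})
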