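test_that("OCAR and SCAR are calibrated percent ratios with zero-division guards", {
  expect_equal(ocar(50, 200), 25)
  expect_equal(ocar(0, 200), 0)
  expect_equal(ocar(200, 200), 100)
  expect_error(ocar(10, 0), "division")
  expect_equal(scar(60, 240), 25)
  expect_equal(scar(0, 240), 0)
  expect_equal(scar(240, 240), 100)
  expect_error(scar(10, 0), "division")
  expect_error(ocar(-5, 100), "non-negative")
})

test_that("CCAR completes the identity and flags out-of-range values unclipped", {
  expect_equal(ccar(25, 25), 50)
  expect_equal(ccar(0, 0), 100)
  expect_warning(v <- ccar(60, 50), "outside")
  expect_equal(v, -10)
  expect_true(ccar_out_of_range(v))
  expect_false(ccar_out_of_range(50))
})

test_that("OCAR + SCAR + CCAR = 100 exactly on random inputs", {
  set.seed(3)
  n <- 1e4
  canal <- stats::runif(n, 100, 400)
  mass <- stats::runif(n, 0, 0.7) * canal
  dural <- stats::runif(n, 100, 400)
  cord <- stats::runif(n, 0, 0.6) * dural
  o <- ocar(mass, canal)
  s <- scar(cord, dural)
  cc <- suppressWarnings(ccar(o, s))
  expect_equal(o + s + cc, rep(100, n))
})

test_that("recovery rate follows the mJOA formula and is undefined at pre = 11", {
  expect_equal(recovery_rate(5, 11), 100)
  expect_equal(recovery_rate(5, 5), 0)
  expect_equal(recovery_rate(4, 9), 500 / 7) # 71.43%
  expect_true(is.na(recovery_rate(11, 11)))
  expect_error(recovery_rate(12, 5), "\\[0, 11\\]")
  expect_error(recovery_rate(5, 5.5), "\\[0, 11\\]")
  expect_error(recovery_rate(-1, 5), "\\[0, 11\\]")
})

test_that("recovery rate is monotone in follow-up and 100 at full recovery", {
  for (pre in 0:10) {
    rr <- recovery_rate(rep(pre, 12 - pre), pre:11)
    expect_true(all(diff(rr) > 0))
    expect_equal(rr[length(rr)], 100)
  }
})

test_that("RR grading uses the printed interval edges and maps deterioration to poor", {
  expect_equal(as.character(grade_rr(75)), "excellent")
  expect_equal(as.character(grade_rr(100)), "excellent")
  expect_equal(as.character(grade_rr(74.99)), "good")
  expect_equal(as.character(grade_rr(50)), "good")
  expect_equal(as.character(grade_rr(49.9)), "fair")
  expect_equal(as.character(grade_rr(25)), "fair")
  expect_equal(as.character(grade_rr(24.9)), "poor")
  expect_equal(as.character(grade_rr(0)), "poor")
  expect_equal(as.character(grade_rr(-10)), "poor")
  expect_true(is.na(grade_rr(NA_real_)))
  # the grade intervals partition the line: every finite rr gets one grade
  set.seed(4)
  rr <- stats::runif(1000, -150, 150)
  expect_false(anyNA(grade_rr(rr)))
})

test_that("CCAR zones use closed outer boundaries and are monotone in CCAR", {
  expect_equal(as.character(ccar_zone(14.3)), "do_zone")
  expect_equal(as.character(ccar_zone(44.5)), "non_do_zone")
  expect_equal(as.character(ccar_zone(30)), "gray_zone")
  expect_equal(as.character(ccar_zone(14.300001)), "gray_zone")
  z <- as.integer(ccar_zone(sort(stats::runif(500, -10, 110))))
  expect_true(all(diff(z) >= 0))
})

test_that("DO prediction is strict at the cut-off", {
  expect_true(predict_do(22.2))
  expect_false(predict_do(50.0))
  expect_false(predict_do(36.4)) # boundary value classifies as non-DO
  expect_true(predict_do(36.4, cutoff = 40))
})

test_that("outcome zones follow the reference edges", {
  expect_equal(as.character(outcome_zone(10)), "poor_or_fair")
  expect_equal(as.character(outcome_zone(14.3)), "poor_or_fair")
  expect_equal(as.character(outcome_zone(45.2)), "good_or_excellent")
  expect_equal(as.character(outcome_zone(30)), "indeterminate")
})

test_that("score_cohort reproduces the latent truth exactly under noiseless observers", {
  params <- cohort_params(observer_cv = 0)
  cohort <- generate_cohort(params, seed = 5)
  truth <- attr(cohort, "truth")
  scored <- score_cohort(cohort)
  expect_equal(scored$ocar_pct, truth$ocar_true)
  expect_equal(scored$scar_pct, truth$scar_true)
  expect_equal(scored$ccar_pct, truth$ccar_true)
  expect_equal(scored$ocar_pct + scored$scar_pct + scored$ccar_pct,
               rep(100, nrow(scored)))
  expect_equal(scored$rr_pct,
               100 * (scored$mjoa_fu - scored$mjoa_pre) / (11 - scored$mjoa_pre))
})
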