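test_that("default cohort has the reference composition and is seed-deterministic", {
  co <- generate_cohort(seed = 21)
  expect_equal(nrow(co), 52)
  expect_equal(sum(co$do_status), 27)
  expect_equal(sum(!co$do_status), 25)
  expect_true(all(cohort_columns() %in% names(co)))
  co2 <- generate_cohort(seed = 21)
  expect_identical(co, co2)
  co3 <- generate_cohort(seed = 22)
  expect_false(identical(attr(co, "truth")$ccar_true,
                         attr(co3, "truth")$ccar_true))
})

test_that("generated latent scores satisfy the exact identity and mJOA bounds", {
  for (seed in c(1, 33)) {
    co <- generate_cohort(seed = seed)
    tr <- attr(co, "truth")
    expect_equal(tr$ocar_true + tr$scar_true + tr$ccar_true,
                 rep(100, nrow(co)))
    expect_true(all(co$mjoa_fu >= 0 & co$mjoa_fu <= 11))
    expect_true(all(co$mjoa_pre >= 0 & co$mjoa_pre <= 10))
    # realized integer follow-up never implies RR above 100
    rr <- recovery_rate(co$mjoa_pre, co$mjoa_fu)
    expect_true(all(rr <= 100, na.rm = TRUE))
    expect_true(all(tr$ccar_true >= 0 & tr$ccar_true <= 100))
    expect_true(all(as.matrix(co[, area_columns()]) >= 0))
  }
})

test_that("observer simulation is exact at cv 0 and bias drives ICC down", {
  truth <- c(200, 60, 210, 190, 50)
  m0 <- simulate_observers(truth, cv = 0, bias_per_observer = c(0, 0))
  for (rep_id in names(m0)) expect_equal(m0[[rep_id]], truth)

  # large inter-observer bias with tiny subject spread: absolute-agreement
  # ICC collapses even though rankings are preserved
  set.seed(23)
  subj <- stats::rnorm(100, 200, 2)
  meas <- simulate_observers(subj, cv = 0.01, bias_per_observer = c(0, 0.05),
                             seed = 24)
  per_obs <- cbind((meas$o1r1 + meas$o1r2) / 2, (meas$o2r1 + meas$o2r2) / 2)
  expect_lt(icc_interobserver(per_obs)$icc, 0.5)
})

test_that("3% observer noise keeps inter-observer ICC of derived CCAR above 0.9", {
  params <- cohort_params(n_do = 100, n_nondo = 100, observer_cv = 0.03)
  co <- generate_cohort(params, seed = 25)
  r <- run_full_analysis(score_cohort(co))
  expect_gte(r$icc$icc, 0.9)
})

test_that("cohort calibration: generated group CCAR means track the reference values", {
  # Monte-Carlo over independent cohorts; grand group means must sit within
  # +/- 1.5 percentage points of the generator targets 22.2 / 50.0
  means_do <- means_nondo <- numeric(40)
  for (i in seq_len(40)) {
    co <- generate_cohort(seed = 1000 + i)
    tr <- attr(co, "truth")
    means_do[i] <- mean(tr$ccar_true[co$do_status])
    means_nondo[i] <- mean(tr$ccar_true[!co$do_status])
  }
  expect_lt(abs(mean(means_do) - 22.2), 1.5)
  expect_lt(abs(mean(means_nondo) - 50.0), 1.5)
})

test_that("scoring a generated cohort recovers the generator means within the 95% CI", {
  hits_do <- hits_nondo <- 0L
  n_rep <- 30L
  for (i in seq_len(n_rep)) {
    sc <- score_cohort(generate_cohort(seed = 2000 + i))
    ci_do <- mean_ci(sc$ccar_pct[sc$do_status])
    ci_nd <- mean_ci(sc$ccar_pct[!sc$do_status])
    # truncation to [0, 100] barely moves these group means, so the CI of the
    # sample mean should usually cover the nominal generator mean
    hits_do <- hits_do + (ci_do$ci_lower <= 22.2 && 22.2 <= ci_do$ci_upper)
    hits_nondo <- hits_nondo + (ci_nd$ci_lower <= 50.0 && 50.0 <= ci_nd$ci_upper)
  }
  expect_gte(hits_do / n_rep, 0.8)
  expect_gte(hits_nondo / n_rep, 0.8)
})

test_that("phantom ground truth follows the analytic shape formulas", {
  ph <- generate_phantom(canal_radius_mm = 10, mass_fraction = 0,
                         cord_semiaxes_mm = c(4, 4))
  expect_equal(ph$truth$ccar, 84) # 100 - 0 - 100 * (pi 16)/(pi 100)
  ph2 <- generate_phantom(canal_radius_mm = 10, mass_fraction = 0.5,
                          cord_semiaxes_mm = c(5, 5))
  expect_equal(ph2$truth$ocar, 50)
  expect_equal(ph2$truth$scar, 25)
  expect_equal(ph2$truth$ccar, 25)
})

test_that("phantom masks respect containment and rasterize within 1% of truth", {
  ph <- generate_phantom() # default canal spans 320 px at 0.05 mm/px
  m <- ph$masks
  expect_true(all(m$mass <= m$canal))           # mass inside the canal
  expect_true(all(m$cord <= m$dural_sac))       # cord inside the dural sac
  chk <- phantom_check(ph)
  expect_true(all(chk$areas$rel_error < 0.01))
  expect_lt(abs(chk$ccar["measured"] - chk$ccar["truth"]), 0.5)
})

test_that("phantoms reject geometry that cannot fit", {
  expect_error(generate_phantom(canal_radius_mm = 8, mass_fraction = 0.9,
                                cord_semiaxes_mm = c(4, 4)),
               "mass-free region")
  expect_error(generate_phantom(size_px = 50), "raster")
  expect_error(generate_phantom(mass_fraction = 1), "mass_fraction")
})

test_that("phantom PNG + JSON round trip preserves masks and truth", {
  dir <- withr::local_tempdir()
  ph <- generate_phantom(canal_radius_mm = 5, cal = calibration(0.1))
  write_phantom(ph, dir)
  ph2 <- read_phantom(dir)
  expect_identical(ph2$masks$canal, ph$masks$canal)
  expect_identical(ph2$masks$cord, ph$masks$cord)
  expect_equal(ph2$truth$ccar, ph$truth$ccar)
  expect_equal(ph2$calibration$mm_per_pixel, 0.1)
  chk <- phantom_check(dir)
  expect_true(all(chk$areas$rel_error < 0.01))
})
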