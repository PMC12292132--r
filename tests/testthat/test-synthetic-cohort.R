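test_that("noise calibration inverts the population R^2 relation", {
  coefs <- c(1, 0.2, 0.01)
  expect_equal(calibrate_noise_sd(coefs, c(80, 294), 1), 0)

  # at R^2 = 0.5, noise variance equals curve variance
  sd_half <- calibrate_noise_sd(coefs, c(80, 294), 0.5)
  days <- 80:294
  f <- oracle_poly(coefs, days)
  expect_equal(sd_half^2, mean((f - mean(f))^2), tolerance = 1e-12)

  # closed-form arithmetic: Var = 19, R^2 = 0.95 -> sigma = 1
  # a linear curve on two days {0, 1} with slope s has Var = s^2/4
  sd_one <- calibrate_noise_sd(c(0, sqrt(19 * 4)), c(0, 1), 0.95)
  expect_equal(sd_one, 1, tolerance = 1e-12)

  expect_error(calibrate_noise_sd(coefs, c(80, 294), 0),
               class = "growthref_invalid_parameter")
  expect_error(calibrate_noise_sd(coefs, c(80, 294), 1.2),
               class = "growthref_invalid_parameter")
})

test_that("cohort generation is deterministic and shaped by its spec", {
  spec <- cohort_spec(n_subjects = 120, seed = 77)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a, b)

  # per-parameter totals hit the spec targets exactly
  counts <- table(a$parameter)
  defaults <- fetal_curve_defaults()
  expect_equal(as.integer(counts[defaults$parameter]), defaults$n_records)

  # ages stay inside each parameter's range
  for (i in seq_len(nrow(defaults))) {
    sub <- a[a$parameter == defaults$parameter[i], ]
    expect_true(all(sub$ga_days >= defaults$ga_min[i] &
                      sub$ga_days <= defaults$ga_max[i]))
  }
  expect_true(all(a$value > 0))
  expect_true(all(a$condition %in% condition_levels()))

  # a different seed gives different draws
  expect_false(identical(a$value,
                         generate_cohort(cohort_spec(n_subjects = 120,
                                                     seed = 78))$value))
})

test_that("zero-noise cohorts lie exactly on the generating curves", {
  spec <- single_param_spec("AC", n_records = 300, noise_sd = 0, seed = 4)
  cohort <- generate_cohort(spec)
  truth <- oracle_poly(
    fetal_curve_defaults()$coefficients[[1]], cohort$ga_days)
  expect_equal(cohort$value, truth, tolerance = 1e-12)
})

test_that("empirical R^2 of the generating curve matches the calibration target", {
  # criterion: |empirical (1 - SSnoise/SStot) - target| <= 0.01 at n >= 5000
  spec <- single_param_spec("AC", n_records = 8000, target_r2 = 0.965,
                            seed = 12)
  cohort <- generate_cohort(spec)
  truth <- oracle_poly(fetal_curve_defaults()$coefficients[[1]],
                       cohort$ga_days)
  emp_r2 <- 1 - sum((cohort$value - truth)^2) /
    sum((cohort$value - mean(cohort$value))^2)
  expect_lt(abs(emp_r2 - 0.965), 0.01)

  # EFW at the documented target, n ~ 850 per the Monte-Carlo contract
  spec_efw <- single_param_spec("EFW", n_records = 850, target_r2 = 0.954,
                                seed = 8)
  efw <- generate_cohort(spec_efw)
  truth_efw <- oracle_poly(
    fetal_curve_defaults()$coefficients[[
      which(fetal_curve_defaults()$parameter == "EFW")]], efw$ga_days)
  emp <- 1 - sum((efw$value - truth_efw)^2) /
    sum((efw$value - mean(efw$value))^2)
  expect_gt(emp, 0.94)
  expect_lt(emp, 0.965)
})

test_that("condition effects order the fetal-weight residual means", {
  spec <- cohort_spec(n_subjects = 600, gdm_prevalence = 0.3,
                      pe_prevalence = 0.3, seed = 21)
  cohort <- generate_cohort(spec)
  efw <- cohort[cohort$parameter == "EFW", ]
  truth <- oracle_poly(
    fetal_curve_defaults()$coefficients[[
      which(fetal_curve_defaults()$parameter == "EFW")]], efw$ga_days)
  resid <- efw$value - truth
  means <- tapply(resid, efw$condition, mean)
  sizes <- tapply(resid, efw$condition, length)
  expect_true(all(sizes >= 200))
  expect_gt(means[["GDM"]], means[["none"]])
  expect_gt(means[["none"]], means[["PE"]])

  # condition shifts only touch EFW: AC values are condition-free
  ac <- cohort[cohort$parameter == "AC", ]
  truth_ac <- oracle_poly(fetal_curve_defaults()$coefficients[[1]],
                          ac$ga_days)
  means_ac <- tapply(ac$value - truth_ac, ac$condition, mean)
  expect_lt(max(abs(means_ac)), 0.5)
})

test_that("a quadratic fit recovers the generating curve from a calibrated cohort", {
  spec <- single_param_spec("AC", n_records = 20000, seed = 31)
  cohort <- generate_cohort(spec)
  fit <- fit_growth_curve(cohort, "AC")
  days <- 80:294
  truth <- oracle_poly(fetal_curve_defaults()$coefficients[[1]], days)
  rel_dev <- abs(predict(fit, days) - truth) / abs(truth)
  expect_lt(max(rel_dev), 0.02)
})

test_that("subject intercepts shift all of a subject's records together", {
  spec <- single_param_spec("HC", n_records = 2000, noise_sd = 0,
                            seed = 14, subject_effect_sd = 3)
  cohort <- generate_cohort(spec)
  hc_row <- which(fetal_curve_defaults()$parameter == "HC")
  truth <- oracle_poly(fetal_curve_defaults()$coefficients[[hc_row]],
                       cohort$ga_days)
  offsets <- cohort$value - truth
  per_subject_spread <- tapply(offsets, cohort$subject_id,
                               function(v) diff(range(v)))
  expect_lt(max(per_subject_spread), 1e-9)
  expect_gt(stats::sd(tapply(offsets, cohort$subject_id, mean)), 1)
})

test_that("invalid cohort specifications are rejected", {
  expect_error(cohort_spec(n_subjects = 0),
               class = "growthref_invalid_parameter")
  expect_error(cohort_spec(gdm_prevalence = 0.7, pe_prevalence = 0.5),
               class = "growthref_invalid_parameter")
  bad <- fetal_curve_defaults()
  bad$noise_sd <- 1  # both noise_sd and target_r2 set
  expect_error(cohort_spec(parameters = bad),
               class = "growthref_invalid_parameter")
  bad2 <- fetal_curve_defaults()
  bad2$ga_min <- bad2$ga_max
  expect_error(cohort_spec(parameters = bad2),
               class = "growthref_invalid_parameter")
  expect_error(cohort_spec(gdm_effect = -5),
               class = "growthref_invalid_parameter")
})
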