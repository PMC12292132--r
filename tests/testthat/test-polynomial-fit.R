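test_that("design matrix expands the polynomial basis exactly", {
  dm <- build_design_matrix(c(2, 3), degree = 2)
  expect_equal(unname(dm[, ]), rbind(c(1, 2, 4), c(1, 3, 9)),
               ignore_attr = TRUE)
  expect_equal(unname(build_design_matrix(5, 0)[, , drop = FALSE])[1, 1], 1)
  dm1 <- build_design_matrix(c(0, 1, 2), degree = 1)
  expect_equal(unname(dm1[, ]), rbind(c(1, 0), c(1, 1), c(1, 2)),
               ignore_attr = TRUE)
  expect_error(build_design_matrix(c(1, 2), -1),
               class = "growthref_invalid_parameter")
  expect_error(build_design_matrix(numeric(0), 2),
               class = "growthref_invalid_parameter")
})

test_that("OLS solves the normal equations (hand-worked cases)", {
  # exact interpolation of y = 1 + x^2
  fit <- fit_ols(c(0, 1, 2), c(1, 2, 5), degree = 2)
  expect_equal(fit$coefficients, c(1, 0, 1), tolerance = 1e-12)
  expect_equal(fit$residuals, rep(0, 3), tolerance = 1e-12)

  # hand-solved 2x2 normal equations
  fit2 <- fit_ols(c(0, 1, 2), c(0, 1, 1), degree = 1)
  expect_equal(fit2$coefficients, c(1 / 6, 1 / 2), tolerance = 1e-12)

  # duplicate single age cannot support a slope (also warns: ill conditioned)
  expect_error(suppressWarnings(fit_ols(c(5, 5, 5), c(1, 2, 3), degree = 1)),
               class = "growthref_singular_error")
  expect_error(suppressWarnings(fit_ols(c(5, 5, 5), c(1, 2, 3), degree = 1)),
               regexp = "ridge")
})

test_that("noiseless polynomial data are recovered to machine precision", {
  set.seed(71)
  for (d in 1:3) {
    true_theta <- round(stats::runif(d + 1, -2, 2), 3)
    true_theta[true_theta == 0] <- 0.5
    x <- stats::runif(20 + d, 0, 50)
    y <- oracle_poly(true_theta, x)
    fit <- fit_ols(x, y, degree = d)
    expect_lt(max(abs(fit$coefficients - true_theta) / abs(true_theta)),
              1e-9)
    expect_equal(fit$r2, 1, tolerance = 1e-12)
    expect_lt(fit$rmse, 1e-9 * max(abs(y)))
  }
})

test_that("ridge closed form matches hand calculation and reduces to OLS", {
  # degree 0, n = 2, y = (2, 4), lambda = 1: theta = 6 / (2 + 1) = 2
  fit <- fit_ridge(c(1, 2), c(2, 4), degree = 0, lambda = 1)
  expect_equal(fit$coefficients, 2, tolerance = 1e-12)

  x <- c(1, 3, 4, 7, 9)
  y <- c(2.2, 4.0, 5.1, 8.3, 9.9)
  expect_equal(fit_ridge(x, y, 2, lambda = 0)$coefficients,
               fit_ols(x, y, 2)$coefficients, tolerance = 1e-10)

  # overwhelming penalty shrinks everything to zero
  big <- fit_ridge(x, y, 1, lambda = 1e12)
  expect_lt(max(abs(big$coefficients)), 1e-6)

  expect_error(fit_ridge(x, y, 1, lambda = -0.1),
               class = "growthref_invalid_parameter")
})

test_that("closed-form ridge matches an independent numerical minimizer", {
  set.seed(2024)
  lambdas <- c(0, 0.01, 0.1, 1, 10)
  n_cases <- 0
  for (rep in 1:12) {
    d <- sample(1:3, 1)
    n <- sample((d + 2):50, 1)
    x <- stats::runif(n)  # ages rescaled to [0, 1] for oracle conditioning
    y <- stats::rnorm(n, oracle_poly(stats::runif(d + 1, -3, 3), x), 0.3)
    for (lam in lambdas) {
      theta <- fit_ridge(x, y, degree = d, lambda = lam)$coefficients
      oracle <- oracle_ridge_minimize(build_design_matrix(x, d), y, lam)
      expect_lt(max(abs(theta - oracle)), 1e-6)
      n_cases <- n_cases + 1
    }
  }
  expect_gte(n_cases, 50)
})

test_that("training R^2 never increases with lambda, and never decreases with degree", {
  set.seed(9)
  for (rep in 1:5) {
    x <- stats::runif(40, 0, 10)
    y <- stats::rnorm(40, 1 + 0.5 * x - 0.05 * x^2, 0.5)
    r2_lam <- vapply(c(0, 0.01, 0.1, 1, 10, 100),
                     function(l) fit_ridge(x, y, 2, lambda = l)$r2,
                     numeric(1))
    expect_true(all(diff(r2_lam) <= 1e-12))
    r2_deg <- vapply(0:3, function(d) fit_ols(x, y, d)$r2, numeric(1))
    expect_true(all(diff(r2_deg) >= -1e-12))
  }
})

test_that("predictions evaluate the published quadratic equations", {
  defaults <- fetal_curve_defaults()
  efw <- defaults$coefficients[[which(defaults$parameter == "EFW")]]
  ac <- defaults$coefficients[[which(defaults$parameter == "AC")]]
  expect_equal(oracle_poly(efw, 280), 3390.61, tolerance = 5e-3)
  expect_equal(oracle_poly(ac, 280), 33.73, tolerance = 5e-3)

  # predict() agrees with direct evaluation and refuses out-of-range ages
  fit <- fit_ols(c(80, 150, 294), oracle_poly(efw, c(80, 150, 294)), 2)
  expect_equal(predict(fit, 280), oracle_poly(efw, 280), tolerance = 1e-6)
  expect_error(predict(fit, 300), class = "growthref_range_error")
  expect_error(predict(fit, 300), regexp = "294")
  expect_equal(predict(fit, 300, extrapolate = TRUE),
               oracle_poly(efw, 300), tolerance = 1e-6)

  zero <- fit_ols(c(1, 2, 3), c(0, 0, 0), 1)
  expect_equal(predict(zero, c(1, 2.5)), c(0, 0))
})

test_that("coefficient standard errors match hand and brute-force covariance", {
  # hand case: s^2 = 1/6, (X'X)^-1 = [[5,-3],[-3,3]]/6
  fit <- fit_ols(c(0, 1, 2), c(0, 1, 1), degree = 1)
  expect_equal(coef_standard_errors(fit),
               c(sqrt(5 / 36), sqrt(1 / 12)), tolerance = 1e-12)

  # zero residuals give zero SEs
  exact <- fit_ols(c(0, 1, 2, 3), oracle_poly(c(1, 2), c(0, 1, 2, 3)), 1)
  expect_equal(coef_standard_errors(exact), c(0, 0), tolerance = 1e-7)

  # brute-force analytic oracle on random small instances
  set.seed(33)
  for (rep in 1:20) {
    d <- sample(1:3, 1)
    n <- sample((d + 3):30, 1)
    x <- stats::runif(n, 0, 5)
    y <- stats::rnorm(n)
    fit <- fit_ols(x, y, d)
    expect_equal(coef_standard_errors(fit),
                 oracle_ols_se(build_design_matrix(x, d), y),
                 tolerance = 1e-8)
  }

  # saturated fit has no residual degrees of freedom
  sat <- fit_ols(c(0, 1), c(1, 2), degree = 1)
  expect_error(coef_standard_errors(sat),
               class = "growthref_undefined_statistic")
})

test_that("ridge standard errors use the sandwich form and reduce to OLS at lambda 0", {
  set.seed(5)
  x <- stats::runif(25, 0, 3)
  y <- stats::rnorm(25, 1 + x, 0.4)
  X <- build_design_matrix(x, 2)
  lam <- 0.5
  fit <- fit_ridge(x, y, 2, lambda = lam)
  # independent sandwich computation
  gram <- t(X) %*% X
  shrink <- solve(gram + lam * diag(3))
  beta <- shrink %*% t(X) %*% y
  s2 <- sum((y - X %*% beta)^2) / (25 - 3)
  expect_equal(coef_standard_errors(fit),
               unname(sqrt(diag(s2 * shrink %*% gram %*% shrink))),
               tolerance = 1e-10)
  expect_equal(coef_standard_errors(fit_ridge(x, y, 2, lambda = 0)),
               coef_standard_errors(fit_ols(x, y, 2)), tolerance = 1e-12)
})

test_that("ill-conditioned designs raise the condition-number warning", {
  # cubic basis on a far-from-origin age scale: huge but full-rank design
  x <- c(1, 1.5, 2, 2.5, 3) * 1e5
  expect_warning(fit_ols(x, c(1, 2, 3, 4, 5), degree = 3),
                 class = "growthref_condition_warning")
  # routine quadratic day-scale fits stay quiet
  expect_no_warning(fit_ols(80:294, oracle_poly(c(1, 0.1, 0.01), 80:294), 2))
})

test_that("degree selection favours the smallest adequate degree", {
  expect_identical(select_degree(c(`1` = 0.9132, `2` = 0.9539, `3` = 0.9551)),
                   2L)
  expect_identical(select_degree(c(`1` = 0.9640, `2` = 0.9732, `3` = 0.9732)),
                   2L)
  expect_identical(select_degree(c(`1` = 0.99, `2` = 0.99, `3` = 0.99),
                                 epsilon = 0), 1L)
  expect_error(select_degree(c(`1` = 0.9, `2` = 0.95)),
               class = "growthref_invalid_parameter")
  expect_error(select_degree(c(`1` = 0.9, `2` = 0.95, `3` = 0.96),
                             epsilon = -1),
               class = "growthref_invalid_parameter")
})

test_that("metrics match their definitions", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(r_squared(c(1, 2, 3), c(2, 2, 2)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5)
  expect_error(r_squared(c(2, 2, 2), c(1, 2, 3)),
               class = "growthref_undefined_statistic")

  expect_equal(rmse(c(1, 2), c(1, 2)), 0)
  expect_equal(rmse(c(3, 4), c(0, 0)), sqrt(12.5))
  expect_equal(rmse(rep(7, 5), rep(7, 5) - 2.5), 2.5)
  expect_error(rmse(numeric(0), numeric(0)),
               class = "growthref_invalid_parameter")
})
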