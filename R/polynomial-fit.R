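#' Polynomial design matrix in gestational age
#'
#' Expands a vector of ages into the polynomial basis
#' \eqn{[1, x, x^2, \dots, x^d]}: row i of the result is the basis
#' evaluated at `ages[i]`. Ages are used raw (days, no centering or
#' scaling) so fitted coefficients are directly interpretable on the
#' day scale.
#'
#' @param ages Numeric vector of gestational ages (days).
#' @param degree Polynomial degree, a single integer >= 0.
#' @return Numeric matrix with `length(ages)` rows and `degree + 1`
#'   columns, with the ages attached as attribute `"ages"` and the degree
#'   as `"degree"`.
#' @export
#' @examples
#' build_design_matrix(c(2, 3), degree = 2)
build_design_matrix <- function(ages, degree) {
  if (length(degree) != 1 || !is.finite(degree) || degree < 0 ||
      degree != round(degree)) {
    abort("degree must be a single non-negative integer",
          class = "growthref_invalid_parameter")
  }
  if (length(ages) == 0 || !all(is.finite(ages))) {
    abort("ages must be a nonempty vector of finite values",
          class = "growthref_invalid_parameter")
  }
  dm <- outer(as.numeric(ages), 0:degree, `^`)
  colnames(dm) <- paste0("x^", 0:degree)
  attr(dm, "ages") <- as.numeric(ages)
  attr(dm, "degree") <- as.integer(degree)
  dm
}

# shared solver: least squares (lambda = 0) or ridge with the full identity
# penalty via the augmented-rows QR factorisation, equivalent to
# (Phi'Phi + lambda I)^-1 Phi'y but without forming the inverse.
# penalize_intercept = FALSE exempts the first column from the penalty.
solve_penalized <- function(dm, y, lambda, penalize_intercept = TRUE) {
  p <- ncol(dm)
  if (lambda == 0) {
    qr_fit <- qr(dm)
    if (qr_fit$rank < p) {
      abort(paste0(
        "design matrix is rank deficient (e.g. too few distinct ages for ",
        "this degree); consider ridge regression with lambda > 0"
      ), class = "growthref_singular_error")
    }
    return(qr.coef(qr_fit, y))
  }
  penalty <- sqrt(lambda) * diag(p)
  if (!penalize_intercept) {
    penalty[1, 1] <- 0
  }
  aug_x <- rbind(dm, penalty)
  aug_y <- c(y, rep(0, p))
  qr_fit <- qr(aug_x)
  if (qr_fit$rank < p) {
    abort("penalized system is rank deficient",
          class = "growthref_singular_error")
  }
  qr.coef(qr_fit, aug_y)
}

# analytic coefficient standard errors; NULL when residual df <= 0
compute_coef_se <- function(dm, y, theta, lambda, penalize_intercept = TRUE) {
  n <- nrow(dm)
  p <- ncol(dm)
  if (n <= p) {
    return(NULL)
  }
  residuals <- y - drop(dm %*% theta)
  s2 <- sum(residuals^2) / (n - p)
  gram <- crossprod(dm)
  cov_theta <- tryCatch({
    if (lambda == 0) {
      s2 * solve(gram)
    } else {
      penalty <- lambda * diag(p)
      if (!penalize_intercept) penalty[1, 1] <- 0
      shrink_inv <- solve(gram + penalty)
      s2 * shrink_inv %*% gram %*% shrink_inv
    }
  }, error = function(cnd) NULL)  # numerically singular Gram matrix
  if (is.null(cov_theta)) {
    return(NULL)
  }
  unname(sqrt(pmax(diag(cov_theta), 0)))
}

new_growth_fit <- function(dm, y, theta, lambda, parameter, units,
                           penalize_intercept) {
  ages <- attr(dm, "ages")
  degree <- attr(dm, "degree")
  fitted <- drop(dm %*% theta)
  residuals <- y - fitted
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum(residuals^2) / sst else NA_real_
  structure(
    list(
      parameter = parameter,
      units = units,
      degree = degree,
      coefficients = unname(theta),
      lambda = lambda,
      penalize_intercept = penalize_intercept,
      coefficient_se = compute_coef_se(dm, y, theta, lambda,
                                       penalize_intercept),
      r2 = r2,
      rmse = sqrt(mean(residuals^2)),
      n = length(y),
      residuals = unname(residuals),
      fitted = unname(fitted),
      ages = ages,
      ga_range = c(min(ages), max(ages))
    ),
    class = "growth_fit"
  )
}

#' Ordinary least-squares polynomial fit
#'
#' Solves the normal equations \eqn{\theta = (\Phi'\Phi)^{-1}\Phi'y} for a
#' polynomial of the given degree, using a QR factorisation of the design
#' matrix rather than an explicit inverse. A warning is raised when the
#' design matrix condition number exceeds 1e10.
#'
#' @param ages Gestational ages (days).
#' @param y Measured values, same length as `ages`.
#' @param degree Polynomial degree (default 2, the quadratic growth model).
#' @param parameter Optional biometric code recorded on the fit.
#' @param units Measurement units recorded on the fit.
#' @return A `growth_fit` object: ascending coefficients, lambda (0 here),
#'   coefficient standard errors (when residual degrees of freedom remain),
#'   R-squared, RMSE, residuals and the training age range. Methods:
#'   [predict.growth_fit()], [tidy.growth_fit()], [glance.growth_fit()].
#' @seealso [fit_ridge()], [fit_growth_curve()]
#' @export
#' @examples
#' fit <- fit_ols(c(0, 1, 2), c(1, 2, 5), degree = 2)
#' coef(fit)  # recovers y = 1 + x^2
fit_ols <- function(ages, y, degree = 2, parameter = NA_character_,
                    units = NA_character_) {
  fit_ridge(ages, y, degree = degree, lambda = 0, parameter = parameter,
            units = units)
}

#' Ridge-regularised polynomial fit
#'
#' Closed-form ridge regression
#' \eqn{\theta = (\Phi'\Phi + \lambda I)^{-1}\Phi'y} with the full
#' identity penalty: the intercept is penalised along with the other
#' coefficients by default. Set `penalize_intercept = FALSE` for the
#' conventional variant that exempts the intercept. `lambda = 0`
#' reproduces [fit_ols()] exactly.
#'
#' @inheritParams fit_ols
#' @param lambda Ridge penalty, a single number >= 0.
#' @param penalize_intercept Include the intercept in the L2 penalty
#'   (default TRUE).
#' @return A `growth_fit` object; see [fit_ols()].
#' @export
#' @examples
#' fit_ridge(c(1, 2), c(2, 4), degree = 0, lambda = 1)$coefficients  # 2
fit_ridge <- function(ages, y, degree = 2, lambda = 0,
                      parameter = NA_character_, units = NA_character_,
                      penalize_intercept = TRUE) {
  if (length(lambda) != 1 || !is.finite(lambda) || lambda < 0) {
    abort("lambda must be a single finite number >= 0",
          class = "growthref_invalid_parameter")
  }
  if (length(y) != length(ages)) {
    abort("ages and y must have equal length",
          class = "growthref_invalid_parameter")
  }
  dm <- build_design_matrix(ages, degree)
  if (nrow(dm) < ncol(dm)) {
    abort(sprintf("need at least degree + 1 = %d observations, got %d",
                  ncol(dm), nrow(dm)),
          class = "growthref_invalid_parameter")
  }
  cond <- kappa(dm, exact = FALSE)
  if (is.finite(cond) && cond > 1e10) {
    warn(sprintf(
      "design matrix is ill conditioned (condition number %.2e); consider ridge regularisation",
      cond
    ), class = "growthref_condition_warning")
  }
  theta <- solve_penalized(dm, y, lambda, penalize_intercept)
  new_growth_fit(dm, y, theta, lambda, parameter, units, penalize_intercept)
}

#' Fit a growth curve to a records table
#'
#' Data-frame-first wrapper around [fit_ridge()]: takes a records tibble
#' (columns `ga_days`, `value`, and `parameter` when more than one code is
#' present), selects one biometric parameter, and fits a polynomial of the
#' requested degree.
#'
#' @param data Records data frame (see [read_records()] for the column
#'   contract).
#' @param parameter Biometric code to fit; may be omitted when `data`
#'   contains a single code.
#' @param degree Polynomial degree (default 2).
#' @param lambda Ridge penalty (default 0 = ordinary least squares).
#' @param penalize_intercept Passed to [fit_ridge()].
#' @return A `growth_fit` object.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_subjects = 50, seed = 1))
#' fit_growth_curve(cohort, "EFW")
fit_growth_curve <- function(data, parameter = NULL, degree = 2, lambda = 0,
                             penalize_intercept = TRUE) {
  data <- validate_records(data)
  if (is.null(parameter)) {
    codes <- unique(data$parameter)
    if (length(codes) != 1) {
      abort("data contains several parameters; supply `parameter`",
            class = "growthref_invalid_parameter")
    }
    parameter <- codes
  }
  sub <- dplyr::filter(data, .data$parameter == !!parameter)
  if (nrow(sub) == 0) {
    abort(sprintf("no records with parameter '%s'", parameter),
          class = "growthref_invalid_parameter")
  }
  units <- if (parameter == "EFW") "g" else "cm"
  fit_ridge(sub$ga_days, sub$value, degree = degree, lambda = lambda,
            parameter = parameter, units = units,
            penalize_intercept = penalize_intercept)
}

#' @export
coef.growth_fit <- function(object, ...) {
  setNames(object$coefficients, paste0("x^", 0:object$degree))
}

#' Evaluate a fitted growth curve at new gestational ages
#'
#' Computes \eqn{\sum_k \theta_k x^k}. Ages outside the training range are
#' refused unless `extrapolate = TRUE`, since a polynomial growth curve has
#' no clinical meaning beyond the ages it was fitted on.
#'
#' @param object A `growth_fit`.
#' @param ages Gestational ages (days) to predict at.
#' @param extrapolate Allow ages outside the training range (default FALSE).
#' @param ... Unused.
#' @return Numeric vector of predicted values.
#' @export
predict.growth_fit <- function(object, ages, extrapolate = FALSE, ...) {
  if (!extrapolate) {
    out <- ages < object$ga_range[1] | ages > object$ga_range[2]
    if (any(out)) {
      abort(sprintf(
        "age %s outside the fitted range [%s, %s]; set extrapolate = TRUE to override",
        format(ages[which(out)[1]]), format(object$ga_range[1]),
        format(object$ga_range[2])
      ), class = "growthref_range_error")
    }
  }
  evaluate_polynomial(object$coefficients, ages)
}

# Horner evaluation of an ascending coefficient vector
evaluate_polynomial <- function(coefficients, x) {
  out <- rep(0, length(x))
  for (k in rev(seq_along(coefficients))) {
    out <- out * x + coefficients[k]
  }
  out
}

#' Coefficient standard errors of a fitted growth curve
#'
#' For an unpenalised fit, the classical OLS standard errors
#' \eqn{\sqrt{s^2 \,\mathrm{diag}[(\Phi'\Phi)^{-1}]}} with
#' \eqn{s^2 = SSE/(n - d - 1)}; for a ridge fit, the sandwich form
#' \eqn{s^2 (\Phi'\Phi+\lambda I)^{-1}\Phi'\Phi(\Phi'\Phi+\lambda I)^{-1}},
#' which reduces to the OLS form at \eqn{\lambda = 0}.
#'
#' @param fit A `growth_fit`.
#' @return Numeric vector of per-coefficient standard errors.
#' @export
coef_standard_errors <- function(fit) {
  stopifnot(inherits(fit, "growth_fit"))
  if (is.null(fit$coefficient_se)) {
    abort(paste0(
      "standard errors undefined: no residual degrees of freedom ",
      "(n must exceed degree + 1)"
    ), class = "growthref_undefined_statistic")
  }
  fit$coefficient_se
}

#' @export
print.growth_fit <- function(x, ...) {
  label <- if (is.na(x$parameter)) "polynomial" else x$parameter
  cat(sprintf("<growth_fit> %s, degree %d, lambda %g\n",
              label, x$degree, x$lambda))
  cat("  coefficients (ascending):",
      paste(signif(x$coefficients, 6), collapse = ", "), "\n")
  cat(sprintf("  n = %d, R^2 = %.4f, RMSE = %.4g, GA range [%g, %g] days\n",
              x$n, x$r2, x$rmse, x$ga_range[1], x$ga_range[2]))
  invisible(x)
}
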