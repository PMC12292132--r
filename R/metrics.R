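#' Coefficient of determination
#'
#' \eqn{R^2 = 1 - \sum_i (y_i-\hat y_i)^2 / \sum_i (y_i-\bar y)^2}.
#' Can be negative when predictions are worse than the mean; undefined
#' (error) when `y` is constant.
#'
#' @param y Observed values.
#' @param y_hat Predicted values, same length.
#' @return A single number, at most 1.
#' @export
#' @examples
#' r_squared(c(1, 2, 3), c(1, 2, 4))  # 0.5
r_squared <- function(y, y_hat) {
  if (length(y) != length(y_hat)) {
    abort("y and y_hat must have equal length",
          class = "growthref_invalid_parameter")
  }
  if (length(y) < 2) {
    abort("need at least two observations",
          class = "growthref_invalid_parameter")
  }
  sst <- sum((y - mean(y))^2)
  if (sst == 0) {
    abort("R^2 undefined: y is constant (zero total sum of squares)",
          class = "growthref_undefined_statistic")
  }
  1 - sum((y - y_hat)^2) / sst
}

#' Root mean squared error
#'
#' \eqn{\sqrt{\frac{1}{n}\sum_i (y_i - \hat y_i)^2}} (divisor n, not
#' n - p).
#'
#' @inheritParams r_squared
#' @return A single non-negative number.
#' @export
#' @examples
#' rmse(c(3, 4), c(0, 0))  # sqrt(12.5)
rmse <- function(y, y_hat) {
  if (length(y) == 0 || length(y) != length(y_hat)) {
    abort("y and y_hat must be nonempty vectors of equal length",
          class = "growthref_invalid_parameter")
  }
  sqrt(mean((y - y_hat)^2))
}

#' Choose a polynomial degree from per-degree R-squared values
#'
#' Formalises the parsimony rule used to settle on the quadratic model:
#' among candidate degrees, return the smallest whose R-squared is within
#' `epsilon` of the best. Ties therefore favour the simpler model.
#'
#' @param r2_by_degree Named numeric vector or list mapping degree to
#'   (training or cross-validated) R-squared; degrees 1-3 must be present.
#' @param epsilon Tolerated R-squared shortfall relative to the best
#'   degree (default 0.005).
#' @return The selected degree as an integer.
#' @export
#' @examples
#' select_degree(c(`1` = 0.9132, `2` = 0.9539, `3` = 0.9551))  # 2
select_degree <- function(r2_by_degree, epsilon = 0.005) {
  r2 <- unlist(r2_by_degree)
  if (is.null(names(r2)) || any(names(r2) == "")) {
    abort("r2_by_degree must be named by degree",
          class = "growthref_invalid_parameter")
  }
  degrees <- as.integer(names(r2))
  if (!all(1:3 %in% degrees)) {
    abort("degrees 1, 2 and 3 must all be present",
          class = "growthref_invalid_parameter")
  }
  if (length(epsilon) != 1 || !is.finite(epsilon) || epsilon < 0) {
    abort("epsilon must be a single number >= 0",
          class = "growthref_invalid_parameter")
  }
  ord <- order(degrees)
  degrees <- degrees[ord]
  r2 <- r2[ord]
  best <- max(r2)
  degrees[which(best - r2 <= epsilon)[1]]
}

# residual moments used by the diagnostics module
moment_skewness <- function(x) {
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) return(0)
  mean((x - m)^3) / s^3
}

moment_excess_kurtosis <- function(x) {
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 == 0) return(0)
  mean((x - m)^4) / s2^2 - 3
}
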