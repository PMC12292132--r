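#' @importFrom broom tidy
#' @export
broom::tidy

#' @importFrom broom glance
#' @export
broom::glance

#' Tidy a fitted growth curve
#'
#' One row per polynomial coefficient, ascending (term `x^0` is the
#' intercept), with the analytic standard error when defined.
#'
#' @param x A `growth_fit`.
#' @param ... Unused.
#' @return Tibble with columns `term`, `estimate`, `std.error`.
#' @export
tidy.growth_fit <- function(x, ...) {
  tibble::tibble(
    term = paste0("x^", 0:x$degree),
    estimate = x$coefficients,
    std.error = if (is.null(x$coefficient_se)) NA_real_ else x$coefficient_se
  )
}

#' One-row summary of a fitted growth curve
#' @param x A `growth_fit`.
#' @param ... Unused.
#' @return Tibble with `parameter`, `degree`, `lambda`, `r.squared`,
#'   `rmse`, `nobs`, `ga_min`, `ga_max`.
#' @export
glance.growth_fit <- function(x, ...) {
  tibble::tibble(
    parameter = x$parameter,
    degree = x$degree,
    lambda = x$lambda,
    r.squared = x$r2,
    rmse = x$rmse,
    nobs = x$n,
    ga_min = x$ga_range[1],
    ga_max = x$ga_range[2]
  )
}

#' Tidy a cross-validation result (one row per fold)
#' @param x A `growth_cv`.
#' @param ... Unused.
#' @return Tibble with `fold`, `n_test`, `r.squared`.
#' @export
tidy.growth_cv <- function(x, ...) {
  tibble::tibble(fold = x$folds$fold, n_test = x$folds$n_test,
                 r.squared = x$folds$r2)
}

#' One-row summary of a cross-validation result
#' @param x A `growth_cv`.
#' @param ... Unused.
#' @return Tibble with `parameter`, `k`, `degree`, `lambda`,
#'   `mean_r.squared`, `sd_r.squared`, `nobs`.
#' @export
glance.growth_cv <- function(x, ...) {
  tibble::tibble(
    parameter = x$parameter,
    k = x$k,
    degree = x$degree,
    lambda = x$lambda,
    mean_r.squared = x$mean_r2,
    sd_r.squared = x$sd_r2,
    nobs = x$n
  )
}

#' Tidy a condition-group comparison (Dunn pairwise table)
#' @param x A `group_test`.
#' @param ... Unused.
#' @return Tibble with `group1`, `group2`, `z`, `p.value`,
#'   `p.value.adjusted`.
#' @export
tidy.group_test <- function(x, ...) {
  tibble::tibble(
    group1 = x$pairwise$group1,
    group2 = x$pairwise$group2,
    z = x$pairwise$z,
    p.value = x$pairwise$p_raw,
    p.value.adjusted = x$pairwise$p_adj
  )
}

#' One-row summary of a condition-group comparison
#' @param x A `group_test`.
#' @param ... Unused.
#' @return Tibble with `statistic` (Kruskal-Wallis H), `df`, `p.value`,
#'   `n_groups`, `nobs`.
#' @export
glance.group_test <- function(x, ...) {
  tibble::tibble(
    statistic = x$H,
    df = x$df,
    p.value = x$p_value,
    n_groups = nrow(x$groups),
    nobs = sum(x$groups$n)
  )
}
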