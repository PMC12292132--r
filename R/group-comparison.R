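#' Residuals from a fitted curve, labelled by maternal condition
#'
#' Computes residual = value - predicted mean for each record and groups
#' them by condition label. Records without a condition label count as
#' controls (`"none"`). Empty groups are dropped with a warning; at least
#' two nonempty groups must remain.
#'
#' @param data Records data frame, same parameter as `fit`.
#' @param fit A `growth_fit` for that parameter.
#' @return Tibble with columns `subject_id`, `ga_days`, `condition`,
#'   `residual`.
#' @export
residuals_by_group <- function(data, fit) {
  stopifnot(inherits(fit, "growth_fit"))
  data <- validate_records(data)
  if (!is.na(fit$parameter) && any(data$parameter != fit$parameter)) {
    abort(sprintf("records contain parameters other than the fitted '%s'",
                  fit$parameter),
          class = "growthref_invalid_parameter")
  }
  pred <- predict(fit, data$ga_days, extrapolate = TRUE)
  out <- tibble::tibble(
    subject_id = data$subject_id,
    ga_days = data$ga_days,
    condition = data$condition,
    residual = data$value - pred
  )
  present <- unique(out$condition)
  missing <- setdiff(condition_levels(), present)
  if (length(missing) > 0) {
    warn(sprintf("condition group(s) with no records dropped: %s",
                 paste(missing, collapse = ", ")))
  }
  if (length(present) < 2) {
    abort("fewer than 2 nonempty condition groups; nothing to compare",
          class = "growthref_invalid_state")
  }
  out
}

# mid-ranks, per-group sizes and rank means, and the tie term sum(t^3 - t)
rank_summaries <- function(x, g) {
  r <- rank(x)  # mid-ranks
  tie_sizes <- table(x)
  list(
    n = length(x),
    group_n = tapply(r, g, length),
    group_rank_mean = tapply(r, g, mean),
    tie_term = sum(tie_sizes^3 - tie_sizes)
  )
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected Kruskal-Wallis H over two or more labelled groups:
#' mid-ranks are assigned over the pooled values,
#' \eqn{H = \frac{12}{N(N+1)} \sum_i n_i (\bar R_i - \frac{N+1}{2})^2}
#' divided by the tie correction \eqn{1 - \sum (t^3 - t)/(N^3 - N)}, and
#' the p-value is the chi-square upper tail with groups - 1 degrees of
#' freedom.
#'
#' @param x Numeric values.
#' @param g Group labels, same length as `x`.
#' @return List with `H`, `df`, `p_value`, and a tibble `groups` of sizes
#'   and mean ranks.
#' @export
#' @examples
#' kruskal_wallis(c(1, 2, 3, 4), c("a", "a", "b", "b"))$H  # 2.4
kruskal_wallis <- function(x, g) {
  if (length(x) != length(g)) {
    abort("x and g must have equal length",
          class = "growthref_invalid_parameter")
  }
  g <- as.character(g)
  counts <- table(g)
  if (length(counts) < 2 || length(x) < 3) {
    abort("need at least two nonempty groups and N >= 3",
          class = "growthref_invalid_parameter")
  }
  rs <- rank_summaries(x, g)
  n_total <- rs$n
  tie_correction <- 1 - rs$tie_term / (n_total^3 - n_total)
  if (tie_correction == 0) {
    abort("all pooled values are identical; H is undefined",
          class = "growthref_undefined_statistic")
  }
  h_raw <- 12 / (n_total * (n_total + 1)) *
    sum(rs$group_n * (rs$group_rank_mean - (n_total + 1) / 2)^2)
  h <- h_raw / tie_correction
  df <- length(counts) - 1L
  list(
    H = h,
    df = df,
    p_value = pchisq(h, df, lower.tail = FALSE),
    groups = tibble::tibble(
      group = names(rs$group_n),
      n = as.integer(rs$group_n),
      mean_rank = as.numeric(rs$group_rank_mean)
    )
  )
}

#' Dunn's pairwise post-hoc rank comparisons
#'
#' For every unordered pair of groups, the Dunn z statistic
#' \eqn{z_{ij} = (\bar R_i - \bar R_j) / \sqrt{\left[\frac{N(N+1)}{12} -
#' \frac{\sum (t^3 - t)}{12(N-1)}\right]\left(\frac{1}{n_i} +
#' \frac{1}{n_j}\right)}}
#' with mid-ranks over the pooled sample and the standard tie correction
#' in the variance, two-sided normal p-values, and a multiplicity
#' adjustment (Holm by default).
#'
#' @inheritParams kruskal_wallis
#' @param adjust Multiplicity adjustment: `"holm"` (default),
#'   `"bonferroni"`, or `"none"`.
#' @return Tibble with columns `group1`, `group2`, `z`, `p_raw`, `p_adj`.
#' @export
#' @examples
#' dunn_test(c(1, 2, 3, 4), c("a", "a", "b", "b"))
dunn_test <- function(x, g, adjust = c("holm", "bonferroni", "none")) {
  adjust <- match.arg(adjust)
  g <- as.character(g)
  if (length(x) != length(g) || length(unique(g)) < 2 || length(x) < 3) {
    abort("need at least two nonempty groups and N >= 3",
          class = "growthref_invalid_parameter")
  }
  rs <- rank_summaries(x, g)
  n_total <- rs$n
  var_term <- n_total * (n_total + 1) / 12 -
    rs$tie_term / (12 * (n_total - 1))
  if (var_term <= 0) {
    abort("all pooled values are identical; Dunn z is undefined",
          class = "growthref_undefined_statistic")
  }
  labels <- names(rs$group_n)
  pairs <- utils::combn(labels, 2, simplify = FALSE)
  out <- purrr::map_dfr(pairs, function(pr) {
    i <- pr[1]
    j <- pr[2]
    se <- sqrt(var_term * (1 / rs$group_n[[i]] + 1 / rs$group_n[[j]]))
    z <- (rs$group_rank_mean[[i]] - rs$group_rank_mean[[j]]) / se
    tibble::tibble(group1 = i, group2 = j, z = z,
                   p_raw = 2 * pnorm(-abs(z)))
  })
  out$p_adj <- p.adjust(out$p_raw, method = adjust)
  out
}

#' Compare condition-group residuals around a fitted growth curve
#'
#' End-to-end group analysis: residuals from the fitted mean curve are
#' grouped by maternal condition, an overall Kruskal-Wallis test is run,
#' and Dunn's pairwise z tests with multiplicity adjustment follow. The
#' scientific question is whether fetal-weight residuals shift with
#' maternal condition — gestational diabetes towards heavier fetuses,
#' preeclampsia towards lighter ones.
#'
#' @inheritParams residuals_by_group
#' @param adjust Multiplicity adjustment for the pairwise table (default
#'   `"holm"`).
#' @return A `group_test` object: `groups` (sizes, mean rank, mean
#'   residual), `H`, `df`, `p_value`, `pairwise` tibble. Methods:
#'   [tidy.group_test()], [glance.group_test()].
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_subjects = 300, seed = 11))
#' efw <- dplyr::filter(cohort, parameter == "EFW")
#' fit <- fit_growth_curve(efw)
#' compare_residual_groups(efw, fit)
compare_residual_groups <- function(data, fit,
                                    adjust = c("holm", "bonferroni", "none")) {
  adjust <- match.arg(adjust)
  grouped <- residuals_by_group(data, fit)
  kw <- kruskal_wallis(grouped$residual, grouped$condition)
  pairwise <- dunn_test(grouped$residual, grouped$condition, adjust = adjust)
  group_means <- grouped |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(mean_residual = mean(.data$residual), .groups = "drop")
  groups <- dplyr::left_join(kw$groups, group_means,
                             by = c(group = "condition"))
  structure(
    list(
      parameter = fit$parameter,
      groups = groups,
      H = kw$H,
      df = kw$df,
      p_value = kw$p_value,
      pairwise = pairwise,
      adjust = adjust
    ),
    class = "group_test"
  )
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("<group_test> Kruskal-Wallis H = %.3f, df = %d, p = %.3g\n",
              x$H, x$df, x$p_value))
  print(x$groups)
  cat(sprintf("Dunn pairwise (%s-adjusted):\n", x$adjust))
  print(x$pairwise)
  invisible(x)
}
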