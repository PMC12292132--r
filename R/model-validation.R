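#' Seeded 70:30-style train/test split
#'
#' Uniformly random permutation of the indices 1..n (seeded); the first
#' `floor(ratio * n)` go to the training set and the remainder to the test
#' set. The floor rule is the one consistent with published split tables
#' (e.g. 985 records at ratio 0.7 give 689 training, 296 test).
#'
#' @param n Number of records (>= 2).
#' @param ratio Training fraction, strictly between 0 and 1 (default 0.7).
#' @param seed RNG seed.
#' @return List with integer vectors `train` and `test` (disjoint, jointly
#'   covering 1..n) and the `ratio`.
#' @export
#' @examples
#' split <- train_test_split(985, ratio = 0.7, seed = 1)
#' lengths(split[c("train", "test")])  # 689, 296
train_test_split <- function(n, ratio = 0.7, seed = 1L) {
  if (length(n) != 1 || n < 2 || n != round(n)) {
    abort("n must be a single integer >= 2",
          class = "growthref_invalid_parameter")
  }
  if (ratio <= 0 || ratio >= 1) {
    abort("ratio must be strictly between 0 and 1",
          class = "growthref_invalid_parameter")
  }
  perm <- withr::with_seed(seed, sample.int(n))
  n_train <- floor(ratio * n)
  list(train = sort(perm[seq_len(n_train)]),
       test = sort(perm[seq.int(n_train + 1, n)]),
       ratio = ratio)
}

#' Split a records table into training and test rows
#'
#' Data-frame front end to [train_test_split()]: appends a `split` column
#' with values `"train"` / `"test"`.
#'
#' @param data Records data frame.
#' @inheritParams train_test_split
#' @return The input tibble with a `split` column.
#' @export
split_records <- function(data, ratio = 0.7, seed = 1L) {
  data <- validate_records(data)
  s <- train_test_split(nrow(data), ratio, seed)
  data$split <- "test"
  data$split[s$train] <- "train"
  data
}

# deal shuffled indices into k folds with sizes differing by at most 1:
# the first (n mod k) folds take one extra
make_folds <- function(n, k, seed) {
  perm <- withr::with_seed(seed, sample.int(n))
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  split(perm, rep(seq_len(k), times = sizes))
}

#' k-fold cross-validation of a polynomial growth curve
#'
#' Shuffles the records (seeded) and deals them into k folds whose sizes
#' differ by at most one; each fold in turn is held out, the curve is
#' refitted on the remaining folds, and the held-out R-squared is
#' recorded. A fold whose held-out values are constant has no defined
#' R-squared; it is excluded with a warning.
#'
#' @param data Records data frame for a single biometric parameter.
#' @param degree Polynomial degree (default 2).
#' @param lambda Ridge penalty (default 0).
#' @param k Number of folds (default 10).
#' @param seed RNG seed for the shuffle.
#' @return A `growth_cv` object: tibble `folds` (fold, n_test, r2),
#'   `mean_r2`, `sd_r2`, and the fitting settings. Methods:
#'   [tidy.growth_cv()], [glance.growth_cv()].
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_subjects = 200, seed = 3))
#' cross_validate(dplyr::filter(cohort, parameter == "FL"), k = 10, seed = 3)
cross_validate <- function(data, degree = 2, lambda = 0, k = 10, seed = 1L) {
  data <- validate_records(data)
  if (length(unique(data$parameter)) != 1) {
    abort("cross_validate expects records of a single parameter",
          class = "growthref_invalid_parameter")
  }
  n <- nrow(data)
  if (k < 2 || n < k) {
    abort(sprintf("need n >= k >= 2 (got n = %d, k = %d)", n, k),
          class = "growthref_invalid_parameter")
  }
  folds <- make_folds(n, k, seed)
  per_fold <- purrr::imap(folds, function(test_idx, fold_name) {
    train <- data[-test_idx, ]
    test <- data[test_idx, ]
    fit <- fit_ridge(train$ga_days, train$value, degree = degree,
                     lambda = lambda)
    pred <- predict(fit, test$ga_days, extrapolate = TRUE)
    # single-record or constant held-out folds have no defined R^2
    r2 <- tryCatch(r_squared(test$value, pred),
                   growthref_undefined_statistic = function(cnd) NA_real_,
                   growthref_invalid_parameter = function(cnd) NA_real_)
    tibble::tibble(fold = as.integer(fold_name),
                   n_test = nrow(test), r2 = r2)
  })
  folds_tbl <- dplyr::bind_rows(per_fold)
  if (anyNA(folds_tbl$r2)) {
    warn(sprintf(
      "%d fold(s) had constant held-out values; their R^2 is undefined and excluded",
      sum(is.na(folds_tbl$r2))
    ))
  }
  ok <- folds_tbl$r2[!is.na(folds_tbl$r2)]
  structure(
    list(
      parameter = unique(data$parameter),
      folds = folds_tbl,
      mean_r2 = mean(ok),
      sd_r2 = if (length(ok) > 1) stats::sd(ok) else 0,
      k = as.integer(k),
      degree = as.integer(degree),
      lambda = lambda,
      n = n,
      seed = as.integer(seed)
    ),
    class = "growth_cv"
  )
}

#' @export
print.growth_cv <- function(x, ...) {
  cat(sprintf(
    "<growth_cv> %s: %d-fold CV, degree %d, lambda %g, n = %d\n",
    x$parameter, x$k, x$degree, x$lambda, x$n))
  cat(sprintf("  per-fold R^2: %s\n",
              paste(sprintf("%.2f", x$folds$r2), collapse = " ")))
  cat(sprintf("  mean R^2 = %.4f (SD %.4f)\n", x$mean_r2, x$sd_r2))
  invisible(x)
}

#' Residual diagnostics for a fitted growth curve
#'
#' Checks the two regression assumptions the reference-band construction
#' relies on. Normality is screened by residual moments: the verdict
#' `normal_ok` holds when |skewness| and |excess kurtosis| are below the
#' configured thresholds. Homoscedasticity is screened by the Spearman
#' rank correlation between |residual| and gestational age — a monotone
#' spread trend shows up as a nonzero rank correlation — with
#' `homosced_ok` holding when its two-sided p-value is at or above
#' `alpha`.
#'
#' @param fit A `growth_fit` (its stored training residuals and ages are
#'   used).
#' @param skew_threshold Maximum |skewness| for the normality verdict
#'   (default 0.5).
#' @param kurtosis_threshold Maximum |excess kurtosis| (default 1).
#' @param alpha Significance level for the heteroscedasticity screen
#'   (default 0.05).
#' @return A `residual_diag` object: `mean_residual`, `skewness`,
#'   `excess_kurtosis`, `hetero_rank_corr`, `hetero_p`, verdicts
#'   `normal_ok` and `homosced_ok`, and the thresholds used.
#' @export
residual_diagnostics <- function(fit, skew_threshold = 0.5,
                                 kurtosis_threshold = 1, alpha = 0.05) {
  stopifnot(inherits(fit, "growth_fit"))
  res <- fit$residuals
  if (length(res) < 10) {
    abort("need at least 10 residuals for diagnostics",
          class = "growthref_insufficient_data")
  }
  skewness <- moment_skewness(res)
  kurtosis <- moment_excess_kurtosis(res)
  scale <- max(1, max(abs(fit$fitted)))
  if (diff(range(abs(res))) < .Machine$double.eps^0.5 * scale) {
    # zero (or constant-magnitude) residuals: spread carries no age trend
    warn("residual spread is degenerate; heteroscedasticity correlation defined as 0")
    rho <- 0
    p <- 1
  } else {
    ct <- suppressWarnings(
      cor.test(abs(res), fit$ages, method = "spearman", exact = FALSE)
    )
    rho <- unname(ct$estimate)
    p <- ct$p.value
  }
  structure(
    list(
      mean_residual = mean(res),
      skewness = skewness,
      excess_kurtosis = kurtosis,
      hetero_rank_corr = rho,
      hetero_p = p,
      normal_ok = abs(skewness) < skew_threshold &&
        abs(kurtosis) < kurtosis_threshold,
      homosced_ok = p >= alpha,
      thresholds = list(skew = skew_threshold, kurtosis = kurtosis_threshold,
                        alpha = alpha),
      n = length(res)
    ),
    class = "residual_diag"
  )
}

#' @export
print.residual_diag <- function(x, ...) {
  cat("<residual_diag>\n")
  cat(sprintf("  mean residual %.4g, skewness %.3f, excess kurtosis %.3f\n",
              x$mean_residual, x$skewness, x$excess_kurtosis))
  cat(sprintf("  |residual| vs age Spearman rho = %.3f (p = %.3g)\n",
              x$hetero_rank_corr, x$hetero_p))
  cat(sprintf("  normality %s, homoscedasticity %s\n",
              if (x$normal_ok) "OK" else "SUSPECT",
              if (x$homosced_ok) "OK" else "SUSPECT"))
  invisible(x)
}
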