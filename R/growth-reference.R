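new_growth_reference <- function(parameter, units, mean_coeffs, upper_coeffs,
                                 lower_coeffs, ga_range, band_mode) {
  structure(
    list(
      parameter = parameter,
      units = units,
      mean_coeffs = unname(mean_coeffs),
      upper_coeffs = unname(upper_coeffs),
      lower_coeffs = unname(lower_coeffs),
      ga_range = ga_range,
      band_mode = band_mode
    ),
    class = "growth_reference"
  )
}

#' Build a +/-2 SD reference band from a fitted growth curve
#'
#' The default band follows the coefficient-wise construction used in the
#' published reference charts: the upper and lower curves are the mean
#' polynomial with 2 coefficient standard deviations added to, and
#' subtracted from, every coefficient. Because all standard errors are
#' non-negative, the band ordering lower <= mean <= upper holds at every
#' non-negative age.
#'
#' `mode = "rmse"` instead offsets the mean curve by +/- 2 residual RMSE
#' (a conventional pointwise envelope for individual measurements); this
#' alternative is provided for comparison and is not the published
#' construction.
#'
#' @param fit A `growth_fit` with coefficient standard errors populated
#'   (i.e. fitted with n > degree + 1).
#' @param mode `"coefficient"` (default) or `"rmse"`.
#' @return A `growth_reference`: ascending mean/upper/lower coefficient
#'   vectors, the fitted age range, parameter code and units.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_subjects = 100, seed = 7))
#' ref <- build_bands(fit_growth_curve(cohort, "AC"))
#' evaluate_bands(ref, c(100, 200, 280))
build_bands <- function(fit, mode = c("coefficient", "rmse")) {
  stopifnot(inherits(fit, "growth_fit"))
  mode <- match.arg(mode)
  if (mode == "coefficient") {
    se <- coef_standard_errors(fit)
    upper <- fit$coefficients + 2 * se
    lower <- fit$coefficients - 2 * se
  } else {
    offset <- 2 * fit$rmse
    upper <- fit$coefficients
    lower <- fit$coefficients
    upper[1] <- upper[1] + offset
    lower[1] <- lower[1] - offset
  }
  new_growth_reference(fit$parameter, fit$units, fit$coefficients,
                       upper, lower, fit$ga_range, mode)
}

#' Build a reference directly from published coefficients
#'
#' Constructs a `growth_reference` from a mean-curve coefficient vector
#' and per-coefficient standard deviations, without refitting — the route
#' used when transcribing a published reference equation table.
#'
#' @param parameter Biometric code.
#' @param coefficients Ascending mean-curve coefficients.
#' @param coef_se Per-coefficient standard deviations (all >= 0), same
#'   length.
#' @param ga_range Length-2 day range of validity.
#' @param units Measurement units (`"cm"` or `"g"`; default by parameter).
#' @return A `growth_reference`.
#' @export
#' @examples
#' ac <- subset(fetal_curve_defaults(), parameter == "AC")
#' ref <- reference_from_coefficients("AC", ac$coefficients[[1]],
#'                                    ac$coef_se[[1]], c(80, 294))
#' evaluate_bands(ref, 280)
reference_from_coefficients <- function(parameter, coefficients, coef_se,
                                        ga_range, units = NULL) {
  if (length(coefficients) != length(coef_se) || any(coef_se < 0)) {
    abort("coef_se must be non-negative and match coefficients in length",
          class = "growthref_invalid_parameter")
  }
  units <- units %||% if (identical(parameter, "EFW")) "g" else "cm"
  new_growth_reference(parameter, units, coefficients,
                       coefficients + 2 * coef_se,
                       coefficients - 2 * coef_se,
                       as.numeric(ga_range), "coefficient")
}

#' Default reference bands for all six biometric parameters
#'
#' Convenience constructor: one `growth_reference` per parameter, built
#' from the package's default curve table ([fetal_curve_defaults()]).
#'
#' @return Named list of `growth_reference` objects.
#' @export
default_references <- function() {
  defaults <- fetal_curve_defaults()
  refs <- purrr::pmap(defaults, function(parameter, units, ga_min, ga_max,
                                         coefficients, coef_se, ...) {
    reference_from_coefficients(parameter, coefficients, coef_se,
                                c(ga_min, ga_max), units)
  })
  setNames(refs, defaults$parameter)
}

#' Evaluate a reference band at gestational ages
#'
#' @param ref A `growth_reference`.
#' @param ages Gestational ages (days) within the reference's range.
#' @return Tibble with columns `ga_days`, `mean`, `lower`, `upper`.
#' @export
evaluate_bands <- function(ref, ages) {
  stopifnot(inherits(ref, "growth_reference"))
  out <- ages < ref$ga_range[1] | ages > ref$ga_range[2]
  if (any(out)) {
    abort(sprintf("age %s outside the reference range [%s, %s]",
                  format(ages[which(out)[1]]), format(ref$ga_range[1]),
                  format(ref$ga_range[2])),
          class = "growthref_range_error")
  }
  tibble::tibble(
    ga_days = ages,
    mean = evaluate_polynomial(ref$mean_coeffs, ages),
    lower = evaluate_polynomial(ref$lower_coeffs, ages),
    upper = evaluate_polynomial(ref$upper_coeffs, ages)
  )
}

#' Flag measurements against a reference band
#'
#' Classifies each record of one biometric parameter against the band:
#' `"normal"` when lower <= value <= upper (boundaries count as normal),
#' `"above_upper"` / `"below_lower"` on strict exceedance. This is the
#' real-time anomaly rule the reference charts are built for.
#'
#' @param data Records data frame (single parameter matching `ref`, ages
#'   within the reference range).
#' @param ref A `growth_reference`.
#' @return The input tibble with columns `predicted_mean`, `lower`,
#'   `upper`, `status` appended.
#' @export
#' @examples
#' ref <- default_references()$AC
#' flag_anomalies(
#'   tibble::tibble(subject_id = "S1", ga_days = 280L,
#'                  parameter = "AC", value = 40),
#'   ref
#' )
flag_anomalies <- function(data, ref) {
  stopifnot(inherits(ref, "growth_reference"))
  data <- validate_records(data)
  if (any(data$parameter != ref$parameter)) {
    bad <- which(data$parameter != ref$parameter)[1]
    abort(sprintf("row %d: parameter '%s' does not match reference '%s'",
                  bad, data$parameter[bad], ref$parameter),
          class = "growthref_invalid_parameter")
  }
  bands <- evaluate_bands(ref, data$ga_days)
  dplyr::mutate(
    data,
    predicted_mean = bands$mean,
    lower = bands$lower,
    upper = bands$upper,
    status = dplyr::case_when(
      .data$value > .data$upper ~ "above_upper",
      .data$value < .data$lower ~ "below_lower",
      TRUE ~ "normal"
    )
  )
}

#' Per-day empirical summaries of one biometric parameter
#'
#' For each distinct gestational day present in the data: the count, the
#' arithmetic mean, the sample SD (denominator n - 1, defined as 0 on
#' singleton days so every observed day stays plottable) and the mean
#' +/- 2 SD envelope. This is the raw-data view plotted alongside fitted
#' reference curves.
#'
#' @param data Records data frame containing a single biometric parameter.
#' @return Tibble with columns `ga_days`, `n`, `mean`, `sd`, `lower`,
#'   `upper`, one row per observed day, sorted by day.
#' @export
daily_summary <- function(data) {
  data <- validate_records(data)
  if (nrow(data) == 0) {
    abort("no records supplied", class = "growthref_invalid_parameter")
  }
  if (length(unique(data$parameter)) != 1) {
    abort("daily_summary expects records of a single parameter",
          class = "growthref_invalid_parameter")
  }
  data |>
    dplyr::group_by(.data$ga_days) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      sd = if (dplyr::n() > 1) stats::sd(.data$value) else 0,
      .groups = "drop"
    ) |>
    dplyr::mutate(lower = .data$mean - 2 * .data$sd,
                  upper = .data$mean + 2 * .data$sd) |>
    dplyr::arrange(.data$ga_days)
}

#' @export
print.growth_reference <- function(x, ...) {
  cat(sprintf("<growth_reference> %s (%s), %s band, GA [%g, %g] days\n",
              x$parameter, x$units, x$band_mode,
              x$ga_range[1], x$ga_range[2]))
  cat("  mean coefficients:",
      paste(signif(x$mean_coeffs, 6), collapse = ", "), "\n")
  invisible(x)
}
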