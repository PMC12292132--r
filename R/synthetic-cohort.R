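#' Calibrate measurement-noise SD to a target population R-squared
#'
#' For values generated as \eqn{y = f(x) + \epsilon} with x uniform on the
#' integer days of `ga_range` and homoscedastic Gaussian noise, the
#' population coefficient of determination is
#' \eqn{R^2 = Var[f(X)] / (Var[f(X)] + \sigma^2)}. Inverting gives the
#' noise SD that realises a requested R-squared:
#' \eqn{\sigma = \sqrt{Var[f(X)] (1 - R^2) / R^2}}, with the curve
#' variance computed exactly by enumerating the integer days.
#'
#' @param coefficients Ascending polynomial coefficients of the true mean
#'   curve.
#' @param ga_range Length-2 integer vector, inclusive day range.
#' @param target_r2 Desired population R-squared, in (0, 1].
#' @return The noise standard deviation (same units as the curve).
#' @export
#' @examples
#' calibrate_noise_sd(c(445.374781, -11.971466, 0.080322),
#'                    c(80, 294), target_r2 = 0.954)
calibrate_noise_sd <- function(coefficients, ga_range, target_r2) {
  if (length(target_r2) != 1 || !is.finite(target_r2) ||
      target_r2 <= 0 || target_r2 > 1) {
    abort("target_r2 must be a single value in (0, 1]",
          class = "growthref_invalid_parameter")
  }
  days <- seq.int(ga_range[1], ga_range[2])
  if (length(days) < 1) {
    abort("ga_range must be a nonempty day interval",
          class = "growthref_invalid_parameter")
  }
  f <- evaluate_polynomial(coefficients, days)
  var_curve <- mean((f - mean(f))^2)  # population variance under uniform X
  sqrt(var_curve * (1 - target_r2) / target_r2)
}

#' Specify a synthetic prenatal cohort
#'
#' Bundles everything [generate_cohort()] needs into a validated spec:
#' cohort size, per-parameter true growth curves and day ranges, noise
#' levels (given directly or calibrated to a target R-squared), a shared
#' per-subject intercept SD, maternal-condition prevalences and the
#' additive fetal-weight shifts they induce, and the RNG seed. The same
#' spec and seed always reproduce the identical cohort.
#'
#' Defaults emulate the cohort the reference curves are designed for:
#' 980 subjects, per-parameter record totals of a few hundred to a few
#' thousand visits (see [fetal_curve_defaults()]), quadratic mean growth,
#' homoscedastic Gaussian noise calibrated to each parameter's published
#' R-squared level, 8% gestational diabetes (GDM) and 4% preeclampsia (PE)
#' prevalence, and EFW shifts of +0.5 and -0.5 noise SDs for GDM and PE
#' respectively.
#'
#' @param n_subjects Number of subjects (default 980).
#' @param parameters Curve table in the format of [fetal_curve_defaults()];
#'   subset rows or edit list columns to customise. A `noise_sd` column
#'   may replace `target_r2` (exactly one of the two per row).
#' @param subject_effect_sd SD of the per-subject additive intercept
#'   (default 0: independent visits, matching pooled curve fitting).
#' @param gdm_prevalence,pe_prevalence Condition fractions; must be >= 0
#'   and sum to at most 1.
#' @param gdm_effect,pe_effect Additive EFW shifts in grams (GDM positive,
#'   PE negative). Default `NULL` means +/- 0.5 x the EFW noise SD.
#' @param noise_sd_slope Optional linear-in-age multiplier on the noise SD
#'   (0 = homoscedastic, the default); at slope s the SD at age x is
#'   `sd * (1 + s * (x - ga_min) / (ga_max - ga_min))`. For robustness
#'   experiments only.
#' @param seed RNG seed (integer).
#' @return A `cohort_spec` object.
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(n_subjects = 980,
                        parameters = fetal_curve_defaults(),
                        subject_effect_sd = 0,
                        gdm_prevalence = 0.08,
                        pe_prevalence = 0.04,
                        gdm_effect = NULL,
                        pe_effect = NULL,
                        noise_sd_slope = 0,
                        seed = 1L) {
  if (n_subjects < 1) {
    abort("n_subjects must be at least 1",
          class = "growthref_invalid_parameter")
  }
  if (gdm_prevalence < 0 || pe_prevalence < 0 ||
      gdm_prevalence + pe_prevalence > 1) {
    abort("prevalences must be >= 0 and sum to at most 1",
          class = "growthref_invalid_parameter")
  }
  if (subject_effect_sd < 0) {
    abort("subject_effect_sd must be >= 0",
          class = "growthref_invalid_parameter")
  }
  parameters <- tibble::as_tibble(parameters)
  has_sd <- "noise_sd" %in% names(parameters)
  has_r2 <- "target_r2" %in% names(parameters)
  if (has_sd && has_r2 &&
      any(!is.na(parameters$noise_sd) & !is.na(parameters$target_r2))) {
    abort("give noise_sd or target_r2 per parameter, not both",
          class = "growthref_invalid_parameter")
  }
  if (!has_sd && !has_r2) {
    abort("parameters must carry a noise_sd or target_r2 column",
          class = "growthref_invalid_parameter")
  }
  if (any(parameters$ga_min >= parameters$ga_max)) {
    abort("each ga_range must satisfy min < max",
          class = "growthref_invalid_parameter")
  }
  # resolve every row to an explicit noise SD now, so the spec is complete
  parameters$noise_sd <- purrr::pmap_dbl(
    list(parameters$coefficients,
         parameters$ga_min, parameters$ga_max,
         if (has_r2) parameters$target_r2 else rep(NA_real_, nrow(parameters)),
         if (has_sd) parameters$noise_sd else rep(NA_real_, nrow(parameters))),
    function(coefs, lo, hi, r2, sd_given) {
      if (!is.na(sd_given)) {
        if (sd_given < 0) abort("noise_sd must be >= 0",
                                class = "growthref_invalid_parameter")
        return(sd_given)
      }
      calibrate_noise_sd(coefs, c(lo, hi), r2)
    }
  )
  efw_sd <- parameters$noise_sd[parameters$parameter == "EFW"]
  if (is.null(gdm_effect)) {
    gdm_effect <- if (length(efw_sd) == 1) 0.5 * efw_sd else 0
  }
  if (is.null(pe_effect)) {
    pe_effect <- if (length(efw_sd) == 1) -0.5 * efw_sd else 0
  }
  if (gdm_effect < 0 || pe_effect > 0) {
    abort("gdm_effect must be >= 0 and pe_effect <= 0 (heavier / lighter)",
          class = "growthref_invalid_parameter")
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      parameters = parameters,
      subject_effect_sd = subject_effect_sd,
      gdm_prevalence = gdm_prevalence,
      pe_prevalence = pe_prevalence,
      gdm_effect = gdm_effect,
      pe_effect = pe_effect,
      noise_sd_slope = noise_sd_slope,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "<cohort_spec> %d subjects, %d parameters, %d records; seed %d\n",
    x$n_subjects, nrow(x$parameters), sum(x$parameters$n_records), x$seed))
  cat(sprintf("  GDM %.0f%% (+%.1f g EFW), PE %.0f%% (%.1f g EFW)\n",
              100 * x$gdm_prevalence, x$gdm_effect,
              100 * x$pe_prevalence, x$pe_effect))
  invisible(x)
}

#' Generate a synthetic prenatal-visit cohort
#'
#' Draws one record table from a [cohort_spec()]: each subject receives a
#' condition label by prevalence and a shared Gaussian intercept; each
#' parameter's target record total is allocated multinomially over
#' subjects; visit ages are uniform over the parameter's integer-day
#' range; values are the true curve plus subject intercept plus Gaussian
#' measurement noise, with the condition effect added to EFW records only.
#' Draws that land at or below zero are resampled (fresh noise, same age)
#' up to 100 times, keeping the noise distribution near-Gaussian without
#' truncation artefacts.
#'
#' @param spec A `cohort_spec`.
#' @return Tibble of records: `subject_id`, `ga_days`, `parameter`,
#'   `value`, `condition`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_subjects = 100, seed = 42))
#' dplyr::count(cohort, parameter)
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, generate_cohort_impl(spec))
}

generate_cohort_impl <- function(spec) {
  n_sub <- spec$n_subjects
  ids <- sprintf("S%04d", seq_len(n_sub))
  condition <- sample(
    condition_levels()[c(2, 3, 1)], n_sub, replace = TRUE,
    prob = c(spec$gdm_prevalence, spec$pe_prevalence,
             1 - spec$gdm_prevalence - spec$pe_prevalence)
  )
  intercept <- if (spec$subject_effect_sd > 0) {
    rnorm(n_sub, 0, spec$subject_effect_sd)
  } else {
    rep(0, n_sub)
  }

  per_parameter <- purrr::pmap(spec$parameters, function(parameter, units,
                                                         ga_min, ga_max,
                                                         n_records, noise_sd,
                                                         coefficients, ...) {
    subj <- sample.int(n_sub, n_records, replace = TRUE)
    ages <- sample.int(ga_max - ga_min + 1L, n_records, replace = TRUE) +
      ga_min - 1L
    mean_val <- evaluate_polynomial(coefficients, ages) + intercept[subj]
    if (parameter == "EFW") {
      mean_val <- mean_val +
        ifelse(condition[subj] == "GDM", spec$gdm_effect,
               ifelse(condition[subj] == "PE", spec$pe_effect, 0))
    }
    sd_at_age <- noise_sd
    if (spec$noise_sd_slope != 0) {
      sd_at_age <- noise_sd *
        (1 + spec$noise_sd_slope * (ages - ga_min) / (ga_max - ga_min))
    }
    value <- mean_val + rnorm(n_records, 0, sd_at_age)
    # positivity by resampling the noise draw, bounded retries
    for (try in seq_len(100)) {
      bad <- which(value <= 0)
      if (length(bad) == 0) break
      sd_bad <- if (length(sd_at_age) == 1) sd_at_age else sd_at_age[bad]
      value[bad] <- mean_val[bad] + rnorm(length(bad), 0, sd_bad)
    }
    if (any(value <= 0)) {
      bad <- which(value <= 0)[1]
      abort(sprintf(
        "could not generate a positive %s value at day %d after 100 retries",
        parameter, ages[bad]
      ), class = "growthref_generation_error")
    }
    tibble::tibble(
      subject_id = ids[subj],
      ga_days = as.integer(ages),
      parameter = parameter,
      value = value,
      condition = condition[subj]
    )
  })
  dplyr::arrange(dplyr::bind_rows(per_parameter),
                 .data$parameter, .data$subject_id, .data$ga_days)
}

#' Write a cohort bundle: records CSV, spec JSON and provenance
#'
#' Generates the cohort and writes three files under `dir`: `cohort.csv`
#' (the records), `spec.json` (the full generative description, schema at
#' `inst/schema/cohort_spec.schema.json`) and `provenance.json` (seed and
#' record count), so any cohort can be regenerated exactly.
#'
#' @param spec A `cohort_spec`.
#' @param dir Output directory (created if needed).
#' @return The generated records tibble, invisibly.
#' @export
write_cohort <- function(spec, dir) {
  stopifnot(inherits(spec, "cohort_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  records <- generate_cohort(spec)
  write_records(records, file.path(dir, "cohort.csv"))
  spec_json <- list(
    n_subjects = spec$n_subjects,
    parameters = spec$parameters[, c("parameter", "units", "ga_min",
                                     "ga_max", "n_records", "noise_sd")],
    subject_effect_sd = spec$subject_effect_sd,
    gdm_prevalence = spec$gdm_prevalence,
    pe_prevalence = spec$pe_prevalence,
    gdm_effect = spec$gdm_effect,
    pe_effect = spec$pe_effect,
    noise_sd_slope = spec$noise_sd_slope,
    seed = spec$seed,
    coefficients = setNames(spec$parameters$coefficients,
                            spec$parameters$parameter)
  )
  jsonlite::write_json(spec_json, file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(
    list(seed = spec$seed, n_records = nrow(records),
         n_subjects = spec$n_subjects),
    file.path(dir, "provenance.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(records)
}
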