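#' Read a prenatal-visit records CSV
#'
#' The records format is a UTF-8 CSV with header columns `subject_id`,
#' `ga_days`, `parameter`, `value` and optionally `condition` (blank or
#' absent means `"none"`). `ga_days` must parse as a positive integer,
#' `value` as a finite decimal, `parameter` as one of the six biometric
#' codes. Parse errors cite the offending data row.
#'
#' @param path Path to the CSV file.
#' @return Records tibble.
#' @seealso [write_records()]
#' @export
read_records <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("records file not found: %s", path),
          class = "growthref_io_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  needed <- c("subject_id", "ga_days", "parameter", "value")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("missing column(s) in %s: %s", path,
                  paste(missing_cols, collapse = ", ")),
          class = "growthref_parse_error")
  }
  ga <- suppressWarnings(as.numeric(raw$ga_days))
  bad <- which(is.na(ga))
  if (length(bad) > 0) {
    abort(sprintf("row %d: ga_days '%s' is not numeric",
                  bad[1], raw$ga_days[bad[1]]),
          class = "growthref_parse_error")
  }
  val <- suppressWarnings(as.numeric(raw$value))
  bad <- which(is.na(val))
  if (length(bad) > 0) {
    abort(sprintf("row %d: value '%s' is not numeric",
                  bad[1], raw$value[bad[1]]),
          class = "growthref_parse_error")
  }
  validate_records(tibble::tibble(
    subject_id = raw$subject_id,
    ga_days = ga,
    parameter = raw$parameter,
    value = val,
    condition = if ("condition" %in% names(raw)) raw$condition else "none"
  ))
}

#' Write records to CSV
#'
#' Full-precision counterpart of [read_records()]; a write followed by a
#' read restores the records exactly.
#'
#' @param data Records data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_records <- function(data, path) {
  data <- validate_records(data)
  readr::write_csv(
    data[, c("subject_id", "ga_days", "parameter", "value", "condition")],
    path)
  invisible(path)
}

# --- model / reference JSON serialisation --------------------------------

#' Serialise a fitted growth curve to JSON
#'
#' Coefficients are written at full double precision (no decimal
#' truncation), so a write/read round trip preserves the model exactly.
#'
#' @param fit A `growth_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(fit, path) {
  stopifnot(inherits(fit, "growth_fit"))
  payload <- list(
    type = "growth_fit",
    parameter = fit$parameter,
    units = fit$units,
    degree = fit$degree,
    coefficients = fit$coefficients,
    lambda = fit$lambda,
    penalize_intercept = fit$penalize_intercept,
    coefficient_se = fit$coefficient_se,
    r2 = fit$r2,
    rmse = fit$rmse,
    n = fit$n,
    ga_range = fit$ga_range
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE,
                       digits = I(17), null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a growth-curve JSON written by [write_model_json()]
#'
#' The returned object evaluates and serialises exactly like the original;
#' training residuals and fitted values are not stored in JSON and are
#' absent.
#'
#' @param path JSON path.
#' @return A `growth_fit` (without residual vectors).
#' @export
read_model_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$type, "growth_fit")) {
    abort(sprintf("%s is not a growth_fit JSON document", path),
          class = "growthref_parse_error")
  }
  structure(
    list(
      parameter = payload$parameter,
      units = payload$units,
      degree = as.integer(payload$degree),
      coefficients = as.numeric(payload$coefficients),
      lambda = payload$lambda,
      penalize_intercept = isTRUE(payload$penalize_intercept),
      coefficient_se = if (is.null(payload$coefficient_se)) NULL else
        as.numeric(payload$coefficient_se),
      r2 = payload$r2,
      rmse = payload$rmse,
      n = as.integer(payload$n),
      residuals = NULL,
      fitted = NULL,
      ages = NULL,
      ga_range = as.numeric(payload$ga_range)
    ),
    class = "growth_fit"
  )
}

#' Serialise a reference band to JSON
#' @param ref A `growth_reference`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference_json <- function(ref, path) {
  stopifnot(inherits(ref, "growth_reference"))
  payload <- list(
    type = "growth_reference",
    parameter = ref$parameter,
    units = ref$units,
    band_mode = ref$band_mode,
    mean_coeffs = ref$mean_coeffs,
    upper_coeffs = ref$upper_coeffs,
    lower_coeffs = ref$lower_coeffs,
    ga_range = ref$ga_range
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE)
  invisible(path)
}

#' Read a reference-band JSON written by [write_reference_json()]
#' @param path JSON path.
#' @return A `growth_reference`.
#' @export
read_reference_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$type, "growth_reference")) {
    abort(sprintf("%s is not a growth_reference JSON document", path),
          class = "growthref_parse_error")
  }
  new_growth_reference(payload$parameter, payload$units,
                       as.numeric(payload$mean_coeffs),
                       as.numeric(payload$upper_coeffs),
                       as.numeric(payload$lower_coeffs),
                       as.numeric(payload$ga_range),
                       payload$band_mode)
}

# --- run configuration ----------------------------------------------------

run_config_defaults <- function() {
  list(
    input = NULL,            # records CSV; NULL = generate a synthetic cohort
    parameters = biometric_parameters(),
    degree_policy = "fixed", # "fixed" or "auto" (pick by training R^2)
    degree = 2L,
    lambda_policy = "fixed", # "fixed" or "grid" (CV-RMSE over the grid)
    lambda = 0.1,
    lambda_grid = c(0.01, 0.1, 1, 10),
    split_ratio = 0.7,
    k_folds = 10L,
    band_mode = "coefficient",
    degree_epsilon = 0.005,
    seed = 1L,
    n_subjects = 980L
  )
}

#' Validate (and complete) a pipeline run configuration
#'
#' Fills defaults and rejects unknown keys and out-of-range values. The
#' JSON shape is documented by the schema shipped at
#' `system.file("schema", "run_config.schema.json", package = "growthref")`.
#'
#' @param config Named list (e.g. parsed from JSON); missing entries take
#'   defaults.
#' @return Completed configuration list.
#' @export
validate_run_config <- function(config = list()) {
  defaults <- run_config_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
          class = "growthref_config_error")
  }
  cfg <- utils::modifyList(defaults, config)
  if (!all(cfg$parameters %in% biometric_parameters())) {
    abort("config parameters must be among the six biometric codes",
          class = "growthref_config_error")
  }
  if (!cfg$degree_policy %in% c("fixed", "auto") ||
      !cfg$lambda_policy %in% c("fixed", "grid") ||
      !cfg$band_mode %in% c("coefficient", "rmse")) {
    abort("invalid policy value in config", class = "growthref_config_error")
  }
  if (cfg$split_ratio <= 0 || cfg$split_ratio >= 1) {
    abort("split_ratio must be in (0, 1)", class = "growthref_config_error")
  }
  if (cfg$k_folds < 2) {
    abort("k_folds must be at least 2", class = "growthref_config_error")
  }
  if (cfg$lambda < 0) {
    abort("lambda must be >= 0", class = "growthref_config_error")
  }
  cfg
}

#' Read a pipeline run configuration from JSON
#' @param path JSON path.
#' @return Completed configuration list (see [validate_run_config()]).
#' @export
read_run_config <- function(path) {
  validate_run_config(jsonlite::read_json(path, simplifyVector = TRUE))
}
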