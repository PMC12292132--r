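#' Default growth-curve parameters for the six biometric measures
#'
#' Quadratic mean-growth curves, coefficient standard errors and population
#' R-squared levels used as package defaults: by the synthetic cohort
#' generator as its generating truth, and by [reference_from_coefficients()]
#' to build published-style reference bands without refitting. Coefficients
#' are stored ascending (intercept, linear, quadratic), ages in days;
#' lengths in cm, EFW in grams.
#'
#' Gestational-age ranges reflect clinical usage: CRL is a first-trimester
#' dating measurement (days 45-100); the other parameters span routine
#' second/third-trimester scans through term (days 80-294). The EFW mean
#' curve turns positive shortly before day 80, so the range starts there.
#'
#' @return A tibble with one row per parameter: `parameter`, `units`,
#'   `ga_min`, `ga_max`, `n_records` (default cohort size), `target_r2`
#'   (population coefficient of determination of the generative model),
#'   `coefficients` and `coef_se` (list columns of ascending numeric
#'   triples).
#' @export
#' @examples
#' fetal_curve_defaults()
fetal_curve_defaults <- function() {
  tibble::tibble(
    parameter = c("AC", "CRL", "EFW", "HC", "BPD", "FL"),
    units = c("cm", "cm", "g", "cm", "cm", "cm"),
    ga_min = c(80L, 45L, 80L, 80L, 80L, 80L),
    ga_max = c(294L, 100L, 294L, 294L, 294L, 294L),
    n_records = c(4594L, 985L, 5639L, 4495L, 4573L, 4531L),
    target_r2 = c(0.9650, 0.7876, 0.9539, 0.9676, 0.9682, 0.9732),
    coefficients = list(
      c(-10.973933, 0.209781, -0.000179),
      c(-4.886816, 0.097966, 0.000306),
      c(445.374781, -11.971466, 0.080322),
      c(-15.160118, 0.289683, -0.000413),
      c(-3.928534, 0.076084, -0.000100),
      c(-3.968641, 0.061229, -0.000073)
    ),
    coef_se = list(
      c(0.364211, 0.003891, 0.000010),
      c(0.626545, 0.015851, 0.000097),
      c(51.521103, 0.547088, 0.001388),
      c(0.334808, 0.003567, 0.000009),
      c(0.096205, 0.001029, 0.000003),
      c(0.078762, 0.000841, 0.000002)
    )
  )
}

# row of fetal_curve_defaults() for one parameter code
default_curve_row <- function(parameter) {
  defaults <- fetal_curve_defaults()
  row <- defaults[defaults$parameter == parameter, ]
  if (nrow(row) != 1) {
    abort(sprintf("unknown biometric parameter '%s'", parameter),
          class = "growthref_invalid_parameter")
  }
  row
}
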