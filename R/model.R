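#' Coefficients of the urine-output prediction formula
#'
#' The model predicts `Qu`, the total urine volume (mL) over the first 32
#' post-operative hours, as
#' \deqn{Q_u = c_0 \left[\frac{aW + b}{W + d}\, F\, (1 - Hct)\right]^{e_v}
#'       \frac{pH^{e_{pH}}}{CPB^{e_{CPB}}\, VIS^{e_{VIS}}\, CVP^{e_{CVP}}}}
#' with `W` the weight in kg, `Hct` the hematocrit as a decimal fraction,
#' `pH` the first post-operative arterial pH, `CPB` the bypass duration in
#' minutes, `VIS` the vasoactive-inotropic score and `CVP` the central
#' venous pressure in mmHg. The defaults are the published constants
#' (`c0 = 6.06`, `F = 558`, `a = 4`, `b = 7`, `d = 90`, exponents
#' 1.01, 0.07, 0.01, 0.08, 0.04). The bracketed product — including the
#' `(1 - Hct)` factor — is raised to `volume_exponent` as a whole.
#'
#' @param leading_constant Multiplicative constant `c0`.
#' @param flow_constant Flow scale `F` inside the bracket.
#' @param numerator_linear Length-2 numeric `c(a, b)` for the weight term
#'   `a*W + b`.
#' @param denominator_offset Offset `d` in the weight term denominator.
#' @param volume_exponent Exponent applied to the bracketed product.
#' @param ph_exponent,cpb_exponent,vis_exponent,cvp_exponent Exponents of
#'   the pH numerator and the CPB/VIS/CVP denominator factors.
#'
#' @return A list of class `uop_coefficients`.
#' @examples
#' uop_coefficients()
#' @export
uop_coefficients <- function(leading_constant = 6.06,
                             flow_constant = 558,
                             numerator_linear = c(4, 7),
                             denominator_offset = 90,
                             volume_exponent = 1.01,
                             ph_exponent = 0.07,
                             cpb_exponent = 0.01,
                             vis_exponent = 0.08,
                             cvp_exponent = 0.04) {
  co <- list(
    leading_constant = leading_constant,
    flow_constant = flow_constant,
    numerator_linear = numerator_linear,
    denominator_offset = denominator_offset,
    volume_exponent = volume_exponent,
    ph_exponent = ph_exponent,
    cpb_exponent = cpb_exponent,
    vis_exponent = vis_exponent,
    cvp_exponent = cvp_exponent
  )
  vals <- unlist(co)
  if (!all(is.finite(vals))) {
    stop("all model coefficients must be finite", call. = FALSE)
  }
  if (leading_constant <= 0 || flow_constant <= 0) {
    stop("leading_constant and flow_constant must be > 0", call. = FALSE)
  }
  if (length(numerator_linear) != 2) {
    stop("numerator_linear must have exactly two elements", call. = FALSE)
  }
  structure(co, class = "uop_coefficients")
}

#' @export
print.uop_coefficients <- function(x, ...) {
  cat("Urine-output model coefficients\n")
  cat(sprintf(
    "  Qu = %g * [((%g*W + %g)/(W + %g)) * %g * (1 - Hct)]^%g * pH^%g / (CPB^%g * VIS^%g * CVP^%g)\n",
    x$leading_constant, x$numerator_linear[1], x$numerator_linear[2],
    x$denominator_offset, x$flow_constant, x$volume_exponent,
    x$ph_exponent, x$cpb_exponent, x$vis_exponent, x$cvp_exponent
  ))
  invisible(x)
}

#' Construct a table of patient covariates
#'
#' One row per surgical encounter, holding the six model inputs in internal
#' units. Hematocrit is stored as a decimal fraction; files and tables in
#' this field report percent, so convert exactly once at ingest with
#' [hct_percent_to_fraction()].
#'
#' @param weight_kg Weight at surgery, kg (> 0).
#' @param hct_fraction First post-operative hematocrit, fraction in (0, 1).
#' @param ph First post-operative arterial serum pH (> 0).
#' @param cpb_minutes Cardiopulmonary bypass duration, minutes (> 0).
#' @param vis First post-operative vasoactive-inotropic score (> 0; the
#'   model is undefined at 0).
#' @param cvp_mmhg First central venous pressure, mmHg (> 0).
#' @param check If `TRUE` (default), reject invalid covariates with an
#'   error listing every violation.
#'
#' @return A tibble with the six covariate columns.
#' @examples
#' patient_covariates(6.1, 0.43, 7.32, 95, 7, 10)
#' @export
patient_covariates <- function(weight_kg, hct_fraction, ph, cpb_minutes,
                               vis, cvp_mmhg, check = TRUE) {
  cov <- tibble::tibble(
    weight_kg = as.numeric(weight_kg),
    hct_fraction = as.numeric(hct_fraction),
    ph = as.numeric(ph),
    cpb_minutes = as.numeric(cpb_minutes),
    vis = as.numeric(vis),
    cvp_mmhg = as.numeric(cvp_mmhg)
  )
  if (check) {
    viol <- validate_covariates(cov)
    if (length(viol) > 0) {
      stop("invalid covariates:\n  ", paste(viol, collapse = "\n  "),
           call. = FALSE)
    }
  }
  cov
}

# field -> c(lower, upper); NA upper means unbounded. Declaration order fixes
# the order in which violations are reported.
.covariate_ranges <- list(
  weight_kg = c(0, NA),
  hct_fraction = c(0, 1),
  ph = c(0, NA),
  cpb_minutes = c(0, NA),
  vis = c(0, NA),
  cvp_mmhg = c(0, NA)
)

#' List covariate invariant violations
#'
#' Reports, never raises: returns one message per violated invariant, in
#' field declaration order (weight, hematocrit, pH, CPB, VIS, CVP), naming
#' the field, the offending value and the allowed range. An empty character
#' vector means every row is valid. A hematocrit of 43 is flagged against
#' the open interval (0, 1) — the usual symptom of passing percent where a
#' fraction is required.
#'
#' @param cov A covariate table as from [patient_covariates()].
#' @return Character vector of violation descriptions (empty when valid).
#' @examples
#' validate_covariates(patient_covariates(6.1, 0.43, 7.32, 95, 7, 10))
#' validate_covariates(patient_covariates(6.1, 43, 7.32, 95, 0, 10, check = FALSE))
#' @export
validate_covariates <- function(cov) {
  missing_cols <- setdiff(names(.covariate_ranges), names(cov))
  if (length(missing_cols) > 0) {
    stop("covariate table lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  n <- nrow(cov)
  out <- character(0)
  for (field in names(.covariate_ranges)) {
    rng <- .covariate_ranges[[field]]
    x <- cov[[field]]
    allowed <- if (is.na(rng[2])) {
      sprintf("> %g", rng[1])
    } else {
      sprintf("in (%g, %g)", rng[1], rng[2])
    }
    bad <- !is.finite(x) | x <= rng[1] | (!is.na(rng[2]) & x >= rng[2])
    for (i in which(bad)) {
      where <- if (n > 1) sprintf(" (row %d)", i) else ""
      out <- c(out, sprintf("%s must be %s, got %s%s",
                            field, allowed, format(x[i]), where))
    }
  }
  out
}

#' Convert hematocrit percent to fraction
#'
#' The model takes hematocrit as a decimal fraction while clinical tables
#' report percent; this is the single conversion point.
#'
#' @param hct_percent Hematocrit in percent, open interval (0, 100).
#' @return `hct_percent / 100`, a fraction in (0, 1).
#' @examples
#' hct_percent_to_fraction(43)  # 0.43
#' @export
hct_percent_to_fraction <- function(hct_percent) {
  bad <- !is.finite(hct_percent) | hct_percent <= 0 | hct_percent >= 100
  if (any(bad)) {
    stop("hematocrit percent must lie in (0, 100); got ",
         paste(format(hct_percent[bad]), collapse = ", "), call. = FALSE)
  }
  hct_percent / 100
}

.check_predict_inputs <- function(cov) {
  if (any(cov$vis == 0, na.rm = TRUE)) {
    stop("model undefined at VIS 0 (zero denominator)", call. = FALSE)
  }
  viol <- validate_covariates(cov)
  if (length(viol) > 0) {
    stop("invalid covariates:\n  ", paste(viol, collapse = "\n  "),
         call. = FALSE)
  }
}

#' Predict total urine volume over 32 post-operative hours
#'
#' Direct evaluation of the closed-form model: the bracketed product
#' `((a*W + b)/(W + d)) * F * (1 - Hct)` is formed first and then raised to
#' the volume exponent, exactly as the formula groups it.
#'
#' @param cov Covariate table ([patient_covariates()]); vectorized over rows.
#' @param coeffs Model coefficients, default [uop_coefficients()].
#' @return Predicted total urine volume in mL over 32 h, one value per row;
#'   finite and positive for all valid inputs.
#' @examples
#' predict_total_volume(patient_covariates(6.1, 0.43, 7.32, 95, 7, 10))
#' @export
predict_total_volume <- function(cov, coeffs = uop_coefficients()) {
  .check_predict_inputs(cov)
  a <- coeffs$numerator_linear[1]
  b <- coeffs$numerator_linear[2]
  bracket <- ((a * cov$weight_kg + b) / (cov$weight_kg + coeffs$denominator_offset)) *
    coeffs$flow_constant * (1 - cov$hct_fraction)
  coeffs$leading_constant * bracket^coeffs$volume_exponent *
    cov$ph^coeffs$ph_exponent /
    (cov$cpb_minutes^coeffs$cpb_exponent *
       cov$vis^coeffs$vis_exponent *
       cov$cvp_mmhg^coeffs$cvp_exponent)
}

#' Predict urine-output rate in ml/kg/hr
#'
#' The predicted total volume divided by weight (kg) and by the 32-hour
#' window: `rate = Qu / (weight_kg * 32)`.
#'
#' @inheritParams predict_total_volume
#' @return Predicted urine output in ml/kg/hr, one value per row.
#' @examples
#' predict_rate(patient_covariates(6.1, 0.43, 7.32, 95, 7, 10))  # ~2.90
#' @export
predict_rate <- function(cov, coeffs = uop_coefficients()) {
  predict_total_volume(cov, coeffs) / (cov$weight_kg * 32)
}
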