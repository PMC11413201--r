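#' Regression error metrics for predicted vs. observed outcomes
#'
#' Computes the five-metric suite used to externally validate the model:
#' mean absolute error, median absolute error (even-length medians are the
#' midpoint of the two central order statistics), mean squared error
#' (divisor `n`), its square root, and the R-squared score. R-squared is
#' the coefficient of determination `1 - SSres/SStot`, not a squared
#' correlation: the two diverge for biased predictions and the coefficient
#' of determination can be negative.
#'
#' @param observed,predicted Numeric vectors of equal length `>= 2`.
#' @return A list of class `uop_metric_set` with elements `mae`, `medae`,
#'   `mse`, `rmse`, `r2` and `n`. When `observed` is constant, `r2` is
#'   `NA` (undefined) and the other metrics are still computed.
#' @examples
#' compute_metrics(c(1, 2, 3), c(2, 2, 2))
#' @export
compute_metrics <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop("observed and predicted must have equal length", call. = FALSE)
  }
  n <- length(observed)
  if (n < 2) stop("need at least 2 observations", call. = FALSE)
  res <- observed - predicted
  mse <- mean(res^2)
  sstot <- sum((observed - mean(observed))^2)
  r2 <- if (sstot == 0) NA_real_ else 1 - sum(res^2) / sstot
  structure(list(
    mae = mean(abs(res)),
    medae = stats::median(abs(res)),
    mse = mse,
    rmse = sqrt(mse),
    r2 = r2,
    n = n
  ), class = "uop_metric_set")
}

.metric_names <- c("mae", "medae", "mse", "rmse", "r2")

#' @export
print.uop_metric_set <- function(x, ...) {
  cat(sprintf("Metrics (n = %d): MAE %.3f, MedAE %.3f, MSE %.3f, RMSE %.3f, R2 %s\n",
              x$n, x$mae, x$medae, x$mse, x$rmse,
              if (is.na(x$r2)) "NA" else sprintf("%.3f", x$r2)))
  invisible(x)
}

#' Subsampling confidence intervals for the metric suite
#'
#' Point estimates come from the full sample. Interval bounds come from a
#' subsampling procedure: in each iteration, `floor(fraction * n)` indices
#' are drawn without replacement (subsampling, not bootstrap), the five
#' metrics are recomputed on that subsample, and the 2.5th/97.5th
#' percentiles of the iteration values (linear interpolation between order
#' statistics) give the bounds. The defaults — half the data, 10
#' iterations — reproduce the validation study's procedure; with only 10
#' draws the percentiles sit near the extreme iteration values. A
#' normal-theory alternative (`mean +/- 1.96 * SD` of the iteration
#' values) is available via `ci_method = "normal"`.
#'
#' @inheritParams compute_metrics
#' @param fraction Subsample proportion, default 0.5.
#' @param iterations Number of subsample iterations, default 10.
#' @param seed RNG seed for the index draws (set when non-NULL).
#' @param ci_method `"percentile"` (default) or `"normal"`.
#' @return A list of class `uop_interval_set`: one element per metric, each
#'   a list `(point, lo, hi)`, plus `n`, `fraction`, `iterations`.
#' @examples
#' obs <- rnorm(40); prd <- obs + rnorm(40, 0, 0.5)
#' subsample_cis(obs, prd, seed = 1)
#' @export
subsample_cis <- function(observed, predicted, fraction = 0.5,
                          iterations = 10, seed = NULL,
                          ci_method = c("percentile", "normal")) {
  ci_method <- match.arg(ci_method)
  if (iterations < 2) stop("need at least 2 iterations", call. = FALSE)
  n <- length(observed)
  m <- floor(fraction * n)
  if (m < 2) {
    stop(sprintf("subsample too small: floor(%g * %d) = %d < 2", fraction, n, m),
         call. = FALSE)
  }
  point <- compute_metrics(observed, predicted)
  if (!is.null(seed)) set.seed(seed)
  draws <- matrix(NA_real_, nrow = iterations, ncol = length(.metric_names),
                  dimnames = list(NULL, .metric_names))
  for (it in seq_len(iterations)) {
    idx <- sample.int(n, m, replace = FALSE)
    ms <- compute_metrics(observed[idx], predicted[idx])
    draws[it, ] <- unlist(ms[.metric_names])
  }
  out <- lapply(.metric_names, function(nm) {
    v <- draws[, nm]
    if (anyNA(v) || is.na(point[[nm]])) {
      return(list(point = point[[nm]], lo = NA_real_, hi = NA_real_))
    }
    if (ci_method == "percentile") {
      b <- unname(stats::quantile(v, c(0.025, 0.975), type = 7))
    } else {
      b <- mean(v) + c(-1, 1) * 1.96 * stats::sd(v)
    }
    list(point = point[[nm]], lo = b[1], hi = b[2])
  })
  names(out) <- .metric_names
  structure(c(out, list(n = n, fraction = fraction, iterations = iterations)),
            class = "uop_interval_set")
}

#' @export
print.uop_interval_set <- function(x, ...) {
  cat(sprintf("Metric intervals (n = %d; %.0f%% subsamples x %d):\n",
              x$n, 100 * x$fraction, x$iterations))
  for (nm in .metric_names) {
    m <- x[[nm]]
    cat(sprintf("  %-5s %s\n", toupper(nm), format_interval(m)))
  }
  invisible(x)
}

#' Tukey IQR outlier detection
#'
#' Flags values below `Q1 - 1.5 * IQR` or above `Q3 + 1.5 * IQR`. Quartiles
#' use linear interpolation between order statistics (quantile position
#' `p * (n - 1)` in the sorted zero-indexed sample, i.e. the default type-7
#' convention); the convention matters, as quartile definitions differ
#' across ecosystems and change outlier flags at small `n`.
#'
#' @param values Numeric vector, length `>= 4`.
#' @return Logical mask, `TRUE` where the value is an outlier.
#' @examples
#' detect_outliers(c(2, 2, 2, 2, 10))  # only 10 flagged
#' @export
detect_outliers <- function(values) {
  if (length(values) < 4) {
    stop("need at least 4 values for quartile-based outlier detection",
         call. = FALSE)
  }
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  values < q[1] - 1.5 * iqr | values > q[2] + 1.5 * iqr
}

#' Split a cohort into the age and surgical-risk subgroups
#'
#' Partitions used in the subgroup analyses: infants (`age_days < 365`)
#' vs. older children (`>= 365`), and lower surgical risk (STAT category
#' 1–2) vs. higher (3–5). Each pair covers the cohort exactly.
#'
#' @param encounters Cohort tibble with `age_days` and `stat_category`.
#' @return Named list of four integer index vectors: `age_lt_12m`,
#'   `age_ge_12m`, `stat_lt_3`, `stat_ge_3`.
#' @examples
#' split_subgroups(sample_cohort(cohort_spec(n_encounters = 20, seed = 1)))
#' @export
split_subgroups <- function(encounters) {
  for (col in c("age_days", "stat_category")) {
    if (!col %in% names(encounters)) {
      stop("cohort lacks required column: ", col, call. = FALSE)
    }
    bad <- which(is.na(encounters[[col]]))
    if (length(bad) > 0) {
      stop(sprintf("missing %s on row %d", col, bad[1]), call. = FALSE)
    }
  }
  list(
    age_lt_12m = which(encounters$age_days < 365),
    age_ge_12m = which(encounters$age_days >= 365),
    stat_lt_3 = which(encounters$stat_category < 3),
    stat_ge_3 = which(encounters$stat_category >= 3)
  )
}

#' Analysis settings for the validation pipeline
#'
#' Defaults reproduce the study's stated procedure: 50% subsamples, 10
#' iterations, percentile intervals, outliers detected on the observed
#' urine-output values (the alternative, residual-based detection, is a
#' switch).
#'
#' @param fraction Subsample proportion.
#' @param iterations Subsample iterations.
#' @param seed RNG seed for the subsampling draws.
#' @param ci_method `"percentile"` or `"normal"`.
#' @param outlier_on `"observed"` (default) or `"residual"`.
#' @return A list of class `uop_analysis_config`.
#' @export
analysis_config <- function(fraction = 0.5, iterations = 10, seed = 1L,
                            ci_method = c("percentile", "normal"),
                            outlier_on = c("observed", "residual")) {
  structure(list(
    fraction = fraction,
    iterations = iterations,
    seed = as.integer(seed),
    ci_method = match.arg(ci_method),
    outlier_on = match.arg(outlier_on)
  ), class = "uop_analysis_config")
}

.subgroup_labels <- c(
  all = "All patients",
  age_lt_12m = "Patients < 12 months",
  age_ge_12m = "Patients >= 12 months",
  stat_lt_3 = "STAT category < 3",
  stat_ge_3 = "STAT category >= 3"
)

#' Run the full external-validation analysis
#'
#' Applies the exclusion filter, evaluates the prediction model on every
#' retained encounter, computes the five-metric suite with subsampling
#' confidence intervals overall and in the four subgroups (infants vs.
#' older children; STAT < 3 vs. >= 3), and flags outliers. Deterministic
#' for a fixed `config$seed`.
#'
#' @param encounters Raw cohort tibble (exclusions not yet applied).
#' @param config An [analysis_config()].
#' @param coeffs Model coefficients, default [uop_coefficients()].
#' @return A list of class `uop_validation_report`: `overall` and
#'   `subgroups` interval sets, `outlier_mask`, `exclusion_tally`,
#'   `per_encounter` (tibble of id, observed, predicted, residual,
#'   outlier), and `config`.
#' @examples
#' rep <- run_validation(sample_cohort(cohort_spec(n_encounters = 60, seed = 2)))
#' rep$overall
#' @export
run_validation <- function(encounters, config = analysis_config(),
                           coeffs = uop_coefficients()) {
  filtered <- apply_exclusions(encounters)
  kept <- filtered$retained
  if (nrow(kept) == 0) {
    stop("empty cohort after exclusions: nothing to validate", call. = FALSE)
  }
  cov <- patient_covariates(kept$weight_kg, kept$hct_fraction, kept$ph,
                            kept$cpb_minutes, kept$vis, kept$cvp_mmhg)
  predicted <- predict_rate(cov, coeffs)
  observed <- kept$uop_ml_kg_hr

  overall <- subsample_cis(observed, predicted,
                           fraction = config$fraction,
                           iterations = config$iterations,
                           seed = config$seed,
                           ci_method = config$ci_method)
  groups <- split_subgroups(kept)
  subgroups <- vector("list", length(groups))
  names(subgroups) <- names(groups)
  for (k in seq_along(groups)) {
    idx <- groups[[k]]
    subgroups[[k]] <- if (floor(config$fraction * length(idx)) >= 2) {
      # offset seeds keep the blocks independent yet reproducible
      subsample_cis(observed[idx], predicted[idx],
                    fraction = config$fraction,
                    iterations = config$iterations,
                    seed = config$seed + k,
                    ci_method = config$ci_method)
    } else {
      structure(list(n = length(idx)), class = "uop_interval_set_empty")
    }
  }

  outlier_mask <- if (config$outlier_on == "observed") {
    detect_outliers(observed)
  } else {
    detect_outliers(observed - predicted)
  }

  structure(list(
    overall = overall,
    subgroups = subgroups,
    outlier_mask = outlier_mask,
    exclusion_tally = filtered$tally,
    per_encounter = tibble::tibble(
      encounter_id = kept$encounter_id,
      observed = observed,
      predicted = predicted,
      residual = observed - predicted,
      outlier = outlier_mask
    ),
    retained = kept,
    config = config
  ), class = "uop_validation_report")
}

#' @export
print.uop_validation_report <- function(x, ...) {
  cat(sprintf("Validation report: %d encounters analyzed (%d input, %d excluded)\n",
              x$exclusion_tally[["n_retained"]],
              x$exclusion_tally[["n_input"]],
              x$exclusion_tally[["n_input"]] - x$exclusion_tally[["n_retained"]]))
  cat(sprintf("  outliers flagged: %d\n", sum(x$outlier_mask)))
  cat("Overall ")
  print(x$overall)
  invisible(x)
}
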