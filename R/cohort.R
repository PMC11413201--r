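#' Fit a log-normal distribution to a printed median and quartiles
#'
#' Cohort tables report covariates as median (IQR); a two-parameter positive
#' distribution has to be chosen to simulate from them. The log-normal fit
#' takes `meanlog = ln(median)` — so the fitted median matches exactly — and
#' `sdlog = (ln q3 - ln q1) / (2 * z0.75)` with `z0.75 = qnorm(0.75)`, so the
#' fitted quartile ratio `q3/q1` matches exactly. The individual quartiles
#' are matched only when the printed quartiles are log-symmetric about the
#' median; printed asymmetry beyond log-normal shape is accepted as
#' approximation.
#'
#' @param median,q1,q3 Printed median and first/third quartiles,
#'   `0 < q1 < median < q3`.
#' @return Named numeric `c(meanlog, sdlog)`.
#' @examples
#' fit_lognormal_from_quantiles(6.1, 3.8, 15.5)
#' @export
fit_lognormal_from_quantiles <- function(median, q1, q3) {
  if (!(is.finite(q1) && is.finite(median) && is.finite(q3)) ||
      !(0 < q1 && q1 < median && median < q3)) {
    stop(sprintf("quantiles must satisfy 0 < q1 < median < q3; got (%s, %s, %s)",
                 format(median), format(q1), format(q3)), call. = FALSE)
  }
  c(meanlog = log(median),
    sdlog = (log(q3) - log(q1)) / (2 * stats::qnorm(0.75)))
}

#' Fit a normal distribution to a printed median and quartiles
#'
#' Symmetric analogue of [fit_lognormal_from_quantiles()], used for
#' covariates that are not right-skewed (arterial pH, hematocrit percent):
#' `mean = median`, `sd = (q3 - q1) / (2 * z0.75)`.
#'
#' @param median,q1,q3 Printed median and quartiles, `q1 < median < q3`.
#' @return Named numeric `c(mean, sd)`.
#' @examples
#' fit_normal_from_quantiles(7.32, 7.28, 7.36)
#' @export
fit_normal_from_quantiles <- function(median, q1, q3) {
  if (!(is.finite(q1) && is.finite(median) && is.finite(q3)) ||
      !(q1 < median && median < q3)) {
    stop(sprintf("quantiles must satisfy q1 < median < q3; got (%s, %s, %s)",
                 format(median), format(q1), format(q3)), call. = FALSE)
  }
  c(mean = median, sd = (q3 - q1) / (2 * stats::qnorm(0.75)))
}

#' Noise standard deviation attaining a target coefficient of determination
#'
#' The generator simulates observed outcome as
#' `observed = prediction + bias + eps`, `eps ~ N(0, sigma^2)`. Under this
#' model the population R-squared of predictions against observed values is
#' `R2 = 1 - (bias^2 + sigma^2) / (Vp + sigma^2)` where `Vp` is the variance
#' of the predictions. Solving for sigma gives
#' `sigma = sqrt((Vp * (1 - R2) - bias^2) / R2)`.
#'
#' @param prediction_variance Variance of the model predictions, `>= 0`.
#' @param bias Constant offset added to every prediction.
#' @param target_r2 Target R-squared, in (0, 1).
#' @return The noise standard deviation sigma.
#' @examples
#' calibrate_noise_sd(1, 0, 0.5)  # 1
#' @export
calibrate_noise_sd <- function(prediction_variance, bias, target_r2) {
  if (!is.finite(target_r2) || target_r2 <= 0 || target_r2 >= 1) {
    stop("target_r2 must lie in (0, 1)", call. = FALSE)
  }
  if (!is.finite(prediction_variance) || prediction_variance < 0) {
    stop("prediction_variance must be a finite non-negative number", call. = FALSE)
  }
  slack <- prediction_variance * (1 - target_r2) - bias^2
  if (slack <= 0) {
    stop(sprintf(paste0(
      "target R2 = %g unattainable with this noise model: requires ",
      "prediction_variance * (1 - target_r2) > bias^2, but %g * %g = %g <= %g"),
      target_r2, prediction_variance, 1 - target_r2,
      prediction_variance * (1 - target_r2), bias^2), call. = FALSE)
  }
  sqrt(slack / target_r2)
}

#' Specification of a synthetic encounter cohort
#'
#' Defaults are calibrated to the published validation cohort summaries:
#' covariate median/IQR triples, the STAT-category mix (56/77/43/28/9 of
#' 213), the headline R-squared of 0.29 and the observed urine-output
#' median of 2.59 ml/kg/hr. Exclusion-event probabilities are small
#' independent Bernoulli rates; the source study does not report
#' per-criterion counts, so these are package choices.
#'
#' @param n_encounters Number of encounters to simulate (>= 2).
#' @param seed RNG seed (integer).
#' @param covariate_quantiles Named list of `c(median, q1, q3)` triples for
#'   `weight`, `age`, `cpb`, `ph`, `hct_pct`, `cvp`, `vis`.
#' @param stat_weights Probabilities of STAT categories 1..5 (normalized).
#' @param target_r2 Target R-squared of predictions vs. simulated observed
#'   urine output, in (0, 1).
#' @param target_median_uop Target median of simulated observed urine
#'   output, ml/kg/hr.
#' @param exclusion_rates Named per-flag probabilities (`preop_krt`,
#'   `reop_32h`, `ecmo_32h`, `krt_32h`, `catheter_lt_32h`, `missing_data`).
#' @return A list of class `uop_cohort_spec`.
#' @examples
#' cohort_spec(n_encounters = 213, seed = 1)
#' @export
cohort_spec <- function(n_encounters = 213,
                        seed = 1L,
                        covariate_quantiles = list(
                          weight = c(6.1, 3.8, 15.5),
                          age = c(172, 51, 1655),
                          cpb = c(95, 74, 134),
                          ph = c(7.32, 7.28, 7.36),
                          hct_pct = c(43, 38, 48),
                          cvp = c(10, 7.0, 13.0),
                          vis = c(7.0, 5.0, 10.0)
                        ),
                        stat_weights = c(`1` = 56, `2` = 77, `3` = 43,
                                         `4` = 28, `5` = 9) / 213,
                        target_r2 = 0.29,
                        target_median_uop = 2.59,
                        exclusion_rates = c(preop_krt = 0.01,
                                            reop_32h = 0.02,
                                            ecmo_32h = 0.015,
                                            krt_32h = 0.01,
                                            catheter_lt_32h = 0.03,
                                            missing_data = 0.02)) {
  if (n_encounters < 2) stop("n_encounters must be >= 2", call. = FALSE)
  needed <- c("weight", "age", "cpb", "ph", "hct_pct", "cvp", "vis")
  missing_q <- setdiff(needed, names(covariate_quantiles))
  if (length(missing_q) > 0) {
    stop("covariate_quantiles lacks: ", paste(missing_q, collapse = ", "),
         call. = FALSE)
  }
  for (nm in needed) {
    q <- covariate_quantiles[[nm]]
    if (length(q) != 3 || !(q[2] < q[1] && q[1] < q[3])) {
      stop(sprintf("covariate_quantiles$%s must be c(median, q1, q3) with q1 < median < q3", nm),
           call. = FALSE)
    }
  }
  if (length(stat_weights) != 5 || any(stat_weights < 0) || sum(stat_weights) <= 0) {
    stop("stat_weights must be five non-negative probabilities", call. = FALSE)
  }
  stat_weights <- stat_weights / sum(stat_weights)
  if (target_r2 <= 0 || target_r2 >= 1) {
    stop("target_r2 must lie in (0, 1)", call. = FALSE)
  }
  flag_names <- c("preop_krt", "reop_32h", "ecmo_32h", "krt_32h",
                  "catheter_lt_32h", "missing_data")
  rates <- exclusion_rates[flag_names]
  if (any(is.na(rates)) || any(rates < 0) || any(rates > 1)) {
    stop("exclusion_rates must name all six flags with probabilities in [0, 1]",
         call. = FALSE)
  }
  names(rates) <- flag_names
  structure(list(
    n_encounters = as.integer(n_encounters),
    seed = as.integer(seed),
    covariate_quantiles = covariate_quantiles,
    stat_weights = stat_weights,
    target_r2 = target_r2,
    target_median_uop = target_median_uop,
    exclusion_rates = rates
  ), class = "uop_cohort_spec")
}

#' @export
print.uop_cohort_spec <- function(x, ...) {
  cat(sprintf("Synthetic cohort spec: %d encounters, seed %d\n",
              x$n_encounters, x$seed))
  cat(sprintf("  target R2 %.2f, target median UOP %.2f ml/kg/hr\n",
              x$target_r2, x$target_median_uop))
  invisible(x)
}

.flag_names <- c("preop_krt", "reop_32h", "ecmo_32h", "krt_32h",
                 "catheter_lt_32h", "missing_data")

#' Simulate a synthetic encounter cohort
#'
#' Draws covariates from distributions quantile-fitted to the spec's
#' median/IQR triples: log-normal for the right-skewed positive covariates
#' (weight, age, CPB duration, VIS, CVP) and normal for arterial pH and
#' hematocrit percent (the latter clamped to (5, 75)). STAT categories are
#' sampled from the spec's category mix. The observed urine output is the
#' model prediction plus a constant bias plus Gaussian noise, with negative
#' draws redrawn; [calibrate_noise_sd()] gives the starting noise SD, and
#' bias and SD are then refined numerically so the cohort's realized median
#' observed output hits `target_median_uop` and the realized R-squared of
#' predictions against observations hits `target_r2` (the closed form alone
#' is exact only for untruncated noise on a symmetric prediction
#' distribution). Identical seeds give identical cohorts.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble of encounters, one row each: identifiers, age, STAT
#'   category, the six model covariates (hematocrit as a fraction),
#'   `uop_ml_kg_hr`, and six logical exclusion flags.
#' @examples
#' sample_cohort(cohort_spec(n_encounters = 5, seed = 42))
#' @export
sample_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "uop_cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_encounters
  q <- spec$covariate_quantiles

  draw_ln <- function(triple) {
    fit <- fit_lognormal_from_quantiles(triple[1], triple[2], triple[3])
    stats::rlnorm(n, fit["meanlog"], fit["sdlog"])
  }
  draw_n <- function(triple) {
    fit <- fit_normal_from_quantiles(triple[1], triple[2], triple[3])
    stats::rnorm(n, fit["mean"], fit["sd"])
  }

  weight <- draw_ln(q$weight)
  age <- draw_ln(q$age)
  cpb <- draw_ln(q$cpb)
  vis <- draw_ln(q$vis)
  cvp <- draw_ln(q$cvp)
  ph <- draw_n(q$ph)
  hct_pct <- pmin(pmax(draw_n(q$hct_pct), 5), 75)
  stat <- sample(1:5, n, replace = TRUE, prob = spec$stat_weights)

  cov <- patient_covariates(weight, hct_percent_to_fraction(hct_pct), ph,
                            cpb, vis, cvp, check = FALSE)
  pred <- predict_rate(cov)

  u <- stats::runif(n)
  uop <- .calibrate_observed(pred, u, spec$target_median_uop,
                             spec$target_r2)$uop

  flags <- lapply(.flag_names, function(f) {
    stats::runif(n) < spec$exclusion_rates[[f]]
  })
  names(flags) <- .flag_names

  tibble::tibble(
    encounter_id = sprintf("E%05d", seq_len(n)),
    patient_id = sprintf("P%05d", seq_len(n)),
    age_days = age,
    weight_kg = weight,
    stat_category = as.integer(stat),
    cpb_minutes = cpb,
    ph = ph,
    hct_fraction = cov$hct_fraction,
    cvp_mmhg = cvp,
    vis = vis,
    uop_ml_kg_hr = uop,
    !!!flags
  )
}

# Simulated observed outcome: prediction + bias + Gaussian noise, with
# negative draws redrawn (implemented by inversion as noise conditioned on a
# non-negative outcome, given the fixed uniforms u). The closed form of
# calibrate_noise_sd() is exact for untruncated noise on a symmetric
# prediction distribution; the prediction distribution here is right-skewed
# and the non-negativity redraw shifts both the realized median and the
# realized R2, so bias and noise SD are refined numerically: for a given SD
# the bias solves median(observed) = target (monotone, unique root), and the
# SD in turn solves R2(predictions, observed) = target. Deterministic given
# u; returns the closed-form solution when the refinement cannot bracket a
# root (degenerate small-n cohorts).
.calibrate_observed <- function(pred, u, target_median, target_r2) {
  vp <- mean((pred - mean(pred))^2)
  bias0 <- target_median - stats::median(pred)
  # clamp the starting bias into the closed form's attainable region; small
  # cohorts can need a bias beyond it, which the refinement then absorbs
  bias_start <- sign(bias0) * min(abs(bias0),
                                  0.99 * sqrt(vp * (1 - target_r2)))
  sigma0 <- calibrate_noise_sd(vp, bias_start, target_r2)

  obs_at <- function(bias, sigma) {
    # noise conditioned on a non-negative outcome, drawn by inversion
    # through the upper tail (stays finite however negative pred + bias is)
    p_keep <- stats::pnorm((pred + bias) / sigma)
    eps <- stats::qnorm(p_keep * (1 - u), lower.tail = FALSE)
    pmax(pred + bias + sigma * eps, 0)
  }
  bias_bound <- sqrt(vp * (1 - target_r2)) * 0.999
  bias_for <- function(sigma) {
    g <- function(b) stats::median(obs_at(b, sigma)) - target_median
    lo <- -3 * (abs(bias0) + sigma + 1)
    if (g(lo) > 0) return(max(lo, -bias_bound))
    hi <- abs(bias0) + sigma + 1
    if (g(hi) < 0) return(min(hi, bias_bound))
    stats::uniroot(g, c(lo, hi), tol = 1e-8)$root
  }
  r2_at <- function(sigma) {
    obs <- obs_at(bias_for(sigma), sigma)
    1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
  }
  sigma <- tryCatch({
    h <- function(s) r2_at(s) - target_r2
    lo <- sigma0 / 20
    hi <- sigma0 * 4
    if (h(lo) < 0 || h(hi) > 0) sigma0
    else stats::uniroot(h, c(lo, hi), tol = 1e-7)$root
  }, error = function(e) sigma0)
  bias <- tryCatch(bias_for(sigma), error = function(e) bias0)
  list(bias = bias, sd = sigma, uop = obs_at(bias, sigma))
}

#' Filter a cohort by the study exclusion criteria
#'
#' Removes encounters that are repeat surgeries of an already-seen patient
#' (input order is the time proxy: only the first encounter per
#' `patient_id` is kept), carry any exclusion flag (pre-operative kidney
#' replacement therapy; re-operation, ECMO or KRT within the first 32
#' post-operative hours; urinary catheter removed before 32 h), have a
#' vasoactive-inotropic score of 0 (the model is undefined there), or have
#' any missing or invalid model input. Each removed row is tallied once,
#' under the first matching reason in that order.
#'
#' @param encounters Cohort tibble as from [sample_cohort()] or
#'   [read_cohort_csv()].
#' @return A list with `retained` (the filtered tibble) and `tally`, a
#'   named integer vector of class `uop_exclusion_tally` with one count per
#'   reason plus `n_input` and `n_retained`.
#' @examples
#' apply_exclusions(sample_cohort(cohort_spec(n_encounters = 50, seed = 1)))
#' @export
apply_exclusions <- function(encounters) {
  n <- nrow(encounters)
  reasons <- c("duplicate", .flag_names[1:5], "vis_zero", "missing_data")
  model_cols <- c("weight_kg", "hct_fraction", "ph", "cpb_minutes", "vis",
                  "cvp_mmhg", "uop_ml_kg_hr")

  reason_of <- rep(NA_character_, n)
  dup <- duplicated(encounters$patient_id)
  flag_mat <- vapply(.flag_names,
                     function(f) as.logical(encounters[[f]]),
                     logical(n))
  flag_mat <- matrix(flag_mat, nrow = n,
                     dimnames = list(NULL, .flag_names))
  vis_zero <- !is.na(encounters$vis) & encounters$vis == 0
  cov_bad <- rowSums(!is.finite(as.matrix(encounters[model_cols]))) > 0
  # hematocrit outside (0,1) counts as invalid input, not a model error
  cov_bad <- cov_bad |
    (is.finite(encounters$hct_fraction) &
       (encounters$hct_fraction <= 0 | encounters$hct_fraction >= 1))

  pick <- function(cond, reason) {
    hit <- is.na(reason_of) & cond
    reason_of[hit] <<- reason
  }
  pick(dup, "duplicate")
  for (f in .flag_names[1:5]) pick(flag_mat[, f], f)
  pick(vis_zero, "vis_zero")
  pick(flag_mat[, "missing_data"] | cov_bad, "missing_data")

  tally <- vapply(reasons, function(r) sum(reason_of == r, na.rm = TRUE), 0L)
  retained <- encounters[is.na(reason_of), , drop = FALSE]
  tally <- c(tally, n_input = n, n_retained = nrow(retained))
  class(tally) <- "uop_exclusion_tally"
  list(retained = retained, tally = tally)
}

#' @export
print.uop_exclusion_tally <- function(x, ...) {
  cat(sprintf("Exclusion tally: %d of %d encounters retained\n",
              x[["n_retained"]], x[["n_input"]]))
  reasons <- setdiff(names(x), c("n_input", "n_retained"))
  for (r in reasons) {
    if (x[[r]] > 0) cat(sprintf("  %-16s %d\n", r, x[[r]]))
  }
  invisible(x)
}
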