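# Independent oracles, coded separately from the package's computation
# paths: the prediction formula evaluated in the log domain, loop/closed-form
# metric implementations, and a hand-rolled interpolated quantile.

oracle_total_volume <- function(w, hct, ph, cpb, vis, cvp) {
  lg <- log(6.06) +
    1.01 * (log(4 * w + 7) - log(w + 90) + log(558) + log1p(-hct)) +
    0.07 * log(ph) - 0.01 * log(cpb) - 0.08 * log(vis) - 0.04 * log(cvp)
  exp(lg)
}

random_valid_covariates <- function(n) {
  patient_covariates(
    weight_kg = runif(n, 0.5, 100),
    hct_fraction = runif(n, 0.05, 0.95),
    ph = runif(n, 6.8, 7.8),
    cpb_minutes = runif(n, 10, 400),
    vis = runif(n, 0.5, 60),
    cvp_mmhg = runif(n, 1, 25)
  )
}

oracle_metrics <- function(obs, prd) {
  n <- length(obs)
  ae <- se <- numeric(n)
  for (i in seq_len(n)) {
    ae[i] <- abs(obs[i] - prd[i])
    se[i] <- (obs[i] - prd[i])^2
  }
  sorted_ae <- sort(ae)
  medae <- if (n %% 2 == 1) sorted_ae[(n + 1) / 2] else
    (sorted_ae[n / 2] + sorted_ae[n / 2 + 1]) / 2
  obar <- sum(obs) / n
  sstot <- sum((obs - obar)^2)
  list(
    mae = sum(ae) / n,
    medae = medae,
    mse = sum(se) / n,
    rmse = sqrt(sum(se) / n),
    r2 = if (sstot == 0) NA_real_ else 1 - sum(se) / sstot
  )
}

# quantile at sorted position p * (n - 1), zero-indexed, linear interpolation
oracle_quantile <- function(x, p) {
  xs <- sort(x)
  h <- p * (length(x) - 1)
  lo <- floor(h)
  xs[lo + 1] + (h - lo) * (xs[min(lo + 2, length(x))] - xs[lo + 1])
}

oracle_tukey_mask <- function(x) {
  q1 <- oracle_quantile(x, 0.25)
  q3 <- oracle_quantile(x, 0.75)
  iqr <- q3 - q1
  x < q1 - 1.5 * iqr | x > q3 + 1.5 * iqr
}

# minimal valid encounter table for exclusion-filter and pipeline tests
make_encounters <- function(n,
                            patient_id = sprintf("P%03d", seq_len(n)),
                            vis = rep(7, n),
                            uop = rep(2.5, n)) {
  enc <- tibble::tibble(
    encounter_id = sprintf("E%03d", seq_len(n)),
    patient_id = patient_id,
    age_days = rep(200, n),
    weight_kg = rep(6.1, n),
    stat_category = rep(2L, n),
    cpb_minutes = rep(95, n),
    ph = rep(7.32, n),
    hct_fraction = rep(0.43, n),
    cvp_mmhg = rep(10, n),
    vis = vis,
    uop_ml_kg_hr = uop
  )
  for (f in c("preop_krt", "reop_32h", "ecmo_32h", "krt_32h",
              "catheter_lt_32h", "missing_data")) {
    enc[[f]] <- rep(FALSE, n)
  }
  enc
}

cohort_predictions <- function(cohort) {
  predict_rate(patient_covariates(cohort$weight_kg, cohort$hct_fraction,
                                  cohort$ph, cohort$cpb_minutes, cohort$vis,
                                  cohort$cvp_mmhg))
}
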