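# peduop

Prediction and external validation of post-operative urine output in
pediatric cardiac surgery.

## The problem

Urine output (UOP) in the first hours after cardiac surgery with
cardiopulmonary bypass (CPB) is a key indicator of kidney function, fluid
balance and low cardiac output risk in children. A closed-form clinical
model predicts the total urine volume over the first 32 post-operative
hours from six variables available at the moment of pediatric cardiac ICU
admission:

```
Qu = 6.06 * [ ((4W + 7)/(W + 90)) * 558 * (1 - Hct) ]^1.01
          * pH^0.07 / ( CPB^0.01 * VIS^0.08 * CVP^0.04 )
```

where `W` is weight (kg), `Hct` the first post-operative hematocrit as a
decimal fraction, `pH` the first arterial serum pH, `CPB` the bypass
duration (minutes), `VIS` the first vasoactive-inotropic score and `CVP`
the first central venous pressure (mmHg). The predicted rate in ml/kg/hr
is `Qu / (W * 32)`. The model is undefined when VIS is 0 (zero
denominator).

This package is for biostatisticians and intensive-care researchers who
want to evaluate such a deterministic prediction rule the way an external
validation study does. It provides:

- exact evaluation of the formula with domain checking (`predict_rate()`,
  `predict_total_volume()`, `validate_covariates()`);
- a synthetic encounter-cohort generator calibrated to published cohort
  summaries — covariates drawn from distributions quantile-fitted to
  median/IQR triples, observed UOP simulated as prediction + bias +
  Gaussian noise with the bias and noise SD calibrated so the cohort's
  median UOP and the R² of predictions vs. observations hit their targets
  (`cohort_spec()`, `sample_cohort()`, `calibrate_noise_sd()`);
- the study's exclusion filter with per-reason tallies
  (`apply_exclusions()`);
- the five-metric validation suite — MAE, MedAE, MSE, RMSE and the R²
  score (coefficient of determination, `1 - SSres/SStot`) — with
  subsampling confidence intervals (50% of the data, 10 iterations,
  interpolated 2.5th/97.5th percentiles), Tukey IQR outlier detection and
  age (< 12 months) / STAT-category (< 3) subgroup analyses
  (`compute_metrics()`, `subsample_cis()`, `detect_outliers()`,
  `run_validation()`);
- tabular, JSON and scatter-plot reports plus a command-line interface
  (`render_report_tables()`, `write_report_json()`, `render_scatter()`,
  `cli_main()`).

## Worked example

Predict UOP for a typical encounter (the cohort's median covariates), then
validate the model on a synthetic 213-encounter cohort:

```r
library(peduop)

cov <- patient_covariates(
  weight_kg = 6.1, hct_fraction = hct_percent_to_fraction(43),
  ph = 7.32, cpb_minutes = 95, vis = 7, cvp_mmhg = 10
)
predict_total_volume(cov)  # 565.6 mL over 32 h
predict_rate(cov)          # 2.90 ml/kg/hr

cohort <- sample_cohort(cohort_spec(n_encounters = 213, seed = 42))
report <- run_validation(cohort, analysis_config(seed = 42))
report
#> Validation report: 196 encounters analyzed (213 input, 17 excluded)
#>   outliers flagged: 4
#> Overall Metric intervals (n = 196; 50% subsamples x 10):
#>   MAE   1.63 (1.53–1.76)
#>   MEDAE 1.46 (1.30–1.52)
#>   MSE   4.08 (3.84–4.75)
#>   RMSE  2.02 (1.96–2.18)
#>   R2    0.04 (-0.13–0.25)
```

The predicted 2.90 ml/kg/hr at the median covariates sits close to the
target median observed UOP of 2.59 ml/kg/hr. The error metrics of a small
synthetic cohort are larger and noisier than those of the real validation
cohort: the generator draws covariates independently from heavy-tailed
quantile fits, which spreads the predictions (and hence the calibrated
noise) well beyond what the clinical data showed, and a 213-row cohort
leaves wide subsampling intervals. At n = 10,000 the calibration targets
are recovered closely (see below). `render_report_tables(report)` formats
the full five-metric × five-column table (overall plus the age and STAT
subgroups) and a cohort summary; `render_scatter(report, "scatter.pdf")`
draws predicted vs. observed UOP with the 45° line and outliers in red.

The same pipeline is scriptable:

```sh
Rscript inst/scripts/peduop demo --seed 7 --out demo_out/
```

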