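Package: peduop
Title: Prediction and External Validation of Post-Operative Urine Output
    in Pediatric Cardiac Surgery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a closed-form clinical model that predicts urine
    output over the first 32 post-operative hours in children undergoing
    cardiac surgery with cardiopulmonary bypass, together with an external
    validation pipeline: a synthetic encounter-cohort generator calibrated
    to published cohort summaries (median/IQR quantile matching, noise
    calibrated to a target coefficient of determination), cohort exclusion
    filtering with reason tallies, regression error metrics (MAE, MedAE,
    MSE, RMSE, R2) with subsampling confidence intervals, Tukey IQR outlier
    detection, age and surgical-risk subgroup analyses, and tabular,
    JSON, and graphical reports.
License: MIT
Encoding: UTF-8
Imports:
    ggplot2,
    grDevices,
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
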