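# Cohort CSV interchange schema. Hematocrit travels as percent in files and
# as a fraction internally; flags are serialized 0/1; missing numerics are
# empty fields.
cohort_schema_columns <- c(
  "encounter_id", "patient_id", "age_days", "weight_kg", "stat_category",
  "cpb_minutes", "ph", "hct_pct", "cvp_mmhg", "vis", "uop_ml_kg_hr",
  "preop_krt", "reop_32h", "ecmo_32h", "krt_32h", "catheter_lt_32h",
  "missing_data"
)

.schema_numeric <- c("age_days", "weight_kg", "stat_category", "cpb_minutes",
                     "ph", "hct_pct", "cvp_mmhg", "vis", "uop_ml_kg_hr")

#' Write a cohort to CSV
#'
#' Emits the interchange schema: fixed column order, hematocrit as percent,
#' flags as 0/1, floats formatted to at most 6 significant digits, missing
#' numerics as empty fields. An empty cohort yields a header-only file.
#'
#' @param encounters Cohort tibble (internal representation, hematocrit as
#'   a fraction).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_cohort_csv(sample_cohort(cohort_spec(n_encounters = 5, seed = 1)), f)
#' @export
write_cohort_csv <- function(encounters, path) {
  df <- data.frame(
    encounter_id = as.character(encounters$encounter_id),
    patient_id = as.character(encounters$patient_id),
    age_days = encounters$age_days,
    weight_kg = encounters$weight_kg,
    stat_category = encounters$stat_category,
    cpb_minutes = encounters$cpb_minutes,
    ph = encounters$ph,
    hct_pct = encounters$hct_fraction * 100,
    cvp_mmhg = encounters$cvp_mmhg,
    vis = encounters$vis,
    uop_ml_kg_hr = encounters$uop_ml_kg_hr,
    stringsAsFactors = FALSE
  )
  for (col in .schema_numeric) {
    x <- df[[col]]
    df[[col]] <- ifelse(is.na(x), "", sprintf("%.6g", x))
  }
  df$stat_category <- ifelse(is.na(encounters$stat_category), "",
                             as.character(encounters$stat_category))
  for (f in .flag_names) {
    df[[f]] <- as.integer(as.logical(encounters[[f]]))
  }
  df <- df[, cohort_schema_columns]
  ok <- tryCatch({
    utils::write.table(df, path, sep = ",", row.names = FALSE,
                       col.names = TRUE, quote = FALSE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop(sprintf("failed to write cohort CSV to '%s': %s",
                 path, conditionMessage(ok)), call. = FALSE)
  }
  invisible(path)
}

#' Read a cohort from CSV
#'
#' Parses the interchange schema. Column order and header case are
#' irrelevant; all schema columns must be present. Hematocrit is converted
#' from percent to fraction here, the single ingest conversion point. Rows
#' with unparseable or out-of-range numeric fields are kept with their
#' `missing_data` flag set rather than dropped silently; a parse summary is
#' emitted as a message.
#'
#' @param path CSV file path.
#' @return Cohort tibble in the internal representation.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("cohort file not found: '%s'", path), call. = FALSE)
  }
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         strip.white = TRUE)
  names(raw) <- tolower(names(raw))
  absent <- setdiff(cohort_schema_columns, names(raw))
  if (length(absent) > 0) {
    stop("cohort CSV lacks mandatory columns: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  n <- nrow(raw)
  num <- function(col) suppressWarnings(as.numeric(raw[[col]]))
  flag <- function(col) {
    v <- suppressWarnings(as.integer(raw[[col]]))
    !is.na(v) & v != 0L
  }
  hct_pct <- num("hct_pct")
  hct_ok <- is.finite(hct_pct) & hct_pct > 0 & hct_pct < 100
  out <- tibble::tibble(
    encounter_id = raw$encounter_id,
    patient_id = raw$patient_id,
    age_days = num("age_days"),
    weight_kg = num("weight_kg"),
    stat_category = suppressWarnings(as.integer(raw$stat_category)),
    cpb_minutes = num("cpb_minutes"),
    ph = num("ph"),
    hct_fraction = ifelse(hct_ok, hct_pct / 100, NA_real_),
    cvp_mmhg = num("cvp_mmhg"),
    vis = num("vis"),
    uop_ml_kg_hr = num("uop_ml_kg_hr")
  )
  for (f in .flag_names) out[[f]] <- flag(f)
  needed <- c("age_days", "weight_kg", "stat_category", "cpb_minutes",
              "ph", "hct_fraction", "cvp_mmhg", "vis", "uop_ml_kg_hr")
  unparseable <- rowSums(is.na(out[needed])) > 0
  out$missing_data <- out$missing_data | unparseable
  message(sprintf("read %d encounters from '%s' (%d with missing or unparseable fields)",
                  n, path, sum(unparseable)))
  out
}

# "0.70 (0.67-0.73)" cells, en dash, two decimals; em dash when undefined
format_interval <- function(m, digits = 2) {
  if (is.null(m) || is.na(m$point)) return("—")
  if (is.na(m$lo) || is.na(m$hi)) return(sprintf("%.*f", digits, m$point))
  sprintf("%.*f (%.*f–%.*f)", digits, m$point, digits, m$lo, digits, m$hi)
}

.metric_display <- c(
  mae = "Mean absolute error (95% CI)",
  medae = "Median absolute error (95% CI)",
  mse = "Mean squared error (95% CI)",
  rmse = "Root mean squared error (95% CI)",
  r2 = "R2 score (95% CI)"
)

#' Render the validation report as performance and cohort-summary tables
#'
#' Produces the five-metric by five-column performance table (all patients
#' and the four subgroups), each cell formatted `point (lo-hi)` to two
#' decimals (internal values are never rounded), plus a cohort summary of
#' medians and interquartile ranges. Empty subgroups render as an em dash.
#'
#' @param report A [run_validation()] report.
#' @return A list with `metrics_table` (tibble of formatted cells),
#'   `cohort_summary` (tibble of median/IQR rows) and `text`, a printable
#'   character rendering of both.
#' @export
render_report_tables <- function(report) {
  blocks <- c(list(all = report$overall), report$subgroups)
  cols <- lapply(names(blocks), function(nm) {
    blk <- blocks[[nm]]
    if (inherits(blk, "uop_interval_set_empty")) {
      rep("—", length(.metric_names))
    } else {
      unname(vapply(.metric_names, function(m) format_interval(blk[[m]]),
                    character(1)))
    }
  })
  ns <- vapply(blocks, function(b) as.integer(b$n %||% 0L), integer(1))
  metrics_table <- tibble::tibble(metric = unname(.metric_display))
  for (k in seq_along(blocks)) {
    metrics_table[[sprintf("%s (n=%d)", .subgroup_labels[[names(blocks)[k]]],
                           ns[k])]] <- cols[[k]]
  }

  kept <- report$retained
  summarize_var <- function(label, x, digits = 2) {
    q <- stats::quantile(x, c(0.5, 0.25, 0.75), type = 7, names = FALSE)
    tibble::tibble(
      variable = label,
      summary = sprintf("%.*f (%.*f–%.*f)", digits, q[1], digits, q[2],
                        digits, q[3])
    )
  }
  cohort_summary <- rbind(
    summarize_var("Age in days, median (IQR)", kept$age_days, 0),
    summarize_var("Weight in kg, median (IQR)", kept$weight_kg, 1),
    summarize_var("CPB duration in minutes, median (IQR)", kept$cpb_minutes, 0),
    summarize_var("Arterial serum pH, median (IQR)", kept$ph, 2),
    summarize_var("Hematocrit %, median (IQR)", kept$hct_fraction * 100, 0),
    summarize_var("CVP in mmHg, median (IQR)", kept$cvp_mmhg, 1),
    summarize_var("VIS, median (IQR)", kept$vis, 1),
    summarize_var("UOP in ml/kg/hr, median (IQR)", kept$uop_ml_kg_hr, 2)
  )

  fmt_tbl <- function(tb) {
    widths <- vapply(names(tb), function(cn) {
      max(nchar(c(cn, tb[[cn]]), type = "width"))
    }, numeric(1))
    pad <- function(v, w) formatC(v, width = w, flag = "-")
    header <- paste(mapply(pad, names(tb), widths), collapse = "  ")
    rows <- apply(mapply(pad, tb, widths), 1, paste, collapse = "  ")
    c(header, strrep("-", nchar(header, type = "width")), rows)
  }
  text <- c(
    "Model predictive performance",
    fmt_tbl(metrics_table),
    "",
    sprintf("Cohort summary (n = %d analyzed of %d input)",
            report$exclusion_tally[["n_retained"]],
            report$exclusion_tally[["n_input"]]),
    fmt_tbl(cohort_summary)
  )
  list(metrics_table = metrics_table, cohort_summary = cohort_summary,
       text = text)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.interval_block_json <- function(blk) {
  if (inherits(blk, "uop_interval_set_empty")) {
    return(list(n = blk$n, metrics = NULL))
  }
  metrics <- lapply(.metric_names, function(m) {
    list(point = blk[[m]]$point, lo = blk[[m]]$lo, hi = blk[[m]]$hi)
  })
  names(metrics) <- .metric_names
  list(n = blk$n, metrics = metrics)
}

#' Serialize a validation report to a JSON-ready list
#'
#' Schema: an `overall` block and four named `subgroups` blocks, each with
#' `n` and per-metric `{point, lo, hi}`; the exclusion tally; the outlier
#' count and flagged encounter ids; and the analysis settings. Writing with
#' [write_report_json()] and re-parsing reproduces every numeric field.
#'
#' @param report A [run_validation()] report.
#' @return A nested list mirroring the JSON document.
#' @export
report_to_json <- function(report) {
  list(
    overall = .interval_block_json(report$overall),
    subgroups = lapply(report$subgroups, .interval_block_json),
    exclusions = as.list(unclass(report$exclusion_tally)),
    outliers = list(
      n = sum(report$outlier_mask),
      encounter_ids = report$per_encounter$encounter_id[report$outlier_mask]
    ),
    settings = unclass(report$config)
  )
}

#' Write the validation report JSON document
#'
#' @param report A [run_validation()] report.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  # 17 significant digits: doubles survive the write/parse round trip exactly
  jsonlite::write_json(report_to_json(report), path, auto_unbox = TRUE,
                       digits = I(17), null = "null", pretty = TRUE)
  invisible(path)
}

#' Predicted-versus-observed scatter plot
#'
#' Scatter of predicted (vertical) against observed (horizontal) urine
#' output with the 45-degree line of perfect agreement; outliers are drawn
#' in red. Written as a PDF.
#'
#' @param report A [run_validation()] report with at least one encounter.
#' @param path Output file path (PDF).
#' @return `path`, invisibly.
#' @export
render_scatter <- function(report, path) {
  pe <- report$per_encounter
  if (nrow(pe) == 0) stop("empty report: nothing to plot", call. = FALSE)
  pe$status <- factor(ifelse(pe$outlier, "outlier", "retained"),
                      levels = c("retained", "outlier"))
  p <- ggplot2::ggplot(pe, ggplot2::aes(x = observed, y = predicted,
                                        colour = status)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey40") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(retained = "black",
                                            outlier = "red"),
                                 drop = FALSE) +
    ggplot2::labs(
      x = "Observed UOP (ml/kg/hr)",
      y = "Predicted UOP (ml/kg/hr)",
      colour = NULL,
      title = "Predicted vs. observed urine output"
    ) +
    ggplot2::theme_minimal()
  grDevices::pdf(path, width = 6, height = 5)
  on.exit(grDevices::dev.off(), add = TRUE)
  print(p)
  invisible(path)
}
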