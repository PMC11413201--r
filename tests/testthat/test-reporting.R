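# CSV interchange, report rendering, JSON round-trip and the CLI.

test_that("cohort CSV round-trips through write and read", {
  co <- sample_cohort(cohort_spec(n_encounters = 40, seed = 17))
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(co, f)
  back <- suppressMessages(read_cohort_csv(f))
  expect_equal(back$encounter_id, co$encounter_id)
  for (col in c("age_days", "weight_kg", "cpb_minutes", "ph", "hct_fraction",
                "cvp_mmhg", "vis", "uop_ml_kg_hr")) {
    expect_equal(back[[col]], co[[col]], tolerance = 1e-5)
  }
  expect_identical(back$stat_category, co$stat_category)
  expect_identical(back$missing_data, co$missing_data)
})

test_that("flags serialize as 0/1 and empty cohorts give a header-only file", {
  co <- make_encounters(2)
  co$ecmo_32h[2] <- TRUE
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(co, f)
  lines <- readLines(f)
  expect_equal(length(lines), 3)
  expect_match(lines[2], ",0,0,0,0,0,0$")
  expect_match(lines[3], ",0,0,1,0,0,0$")

  write_cohort_csv(co[0, ], f)
  expect_equal(length(readLines(f)), 1)
})

test_that("reader is order- and case-insensitive and flags unparseable rows", {
  co <- make_encounters(3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(co, f)
  lines <- readLines(f)
  header <- strsplit(lines[1], ",")[[1]]
  perm <- sample(seq_along(header))
  shuffle <- function(ln) paste(strsplit(ln, ",")[[1]][perm], collapse = ",")
  reordered <- c(toupper(paste(header[perm], collapse = ",")),
                 vapply(lines[-1], shuffle, character(1)))
  writeLines(reordered, f)
  back <- suppressMessages(read_cohort_csv(f))
  expect_equal(back$weight_kg, co$weight_kg, tolerance = 1e-5)

  # blank pH cell: row kept, missing_data set
  lines[3] <- sub("^(([^,]*,){6})[^,]*", "\\1", lines[3])
  writeLines(lines, f)
  back <- suppressMessages(read_cohort_csv(f))
  expect_equal(nrow(back), 3)
  expect_true(is.na(back$ph[2]))
  expect_identical(back$missing_data, c(FALSE, TRUE, FALSE))
})

test_that("reader names absent mandatory columns", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("encounter_id,weight_kg\nE1,6.1", f)
  expect_error(read_cohort_csv(f), "hct_pct")
  expect_error(read_cohort_csv(file.path(tempdir(), "nope.csv")), "not found")
})

test_that("performance table has the published shape and cell format", {
  co <- sample_cohort(cohort_spec(n_encounters = 213, seed = 4))
  rep <- run_validation(co, analysis_config(seed = 4))
  tabs <- render_report_tables(rep)
  expect_equal(nrow(tabs$metrics_table), 5)
  expect_equal(ncol(tabs$metrics_table), 6)
  cells <- unlist(tabs$metrics_table[, -1])
  expect_true(all(grepl("^-?\\d+\\.\\d{2} \\(-?\\d+\\.\\d{2}–-?\\d+\\.\\d{2}\\)$",
                        cells)))
  expect_equal(nrow(tabs$cohort_summary), 8)
  expect_true(any(grepl("Model predictive performance", tabs$text)))
})

test_that("perfect fit renders zero cells and empty subgroups render as a dash", {
  zero <- c(preop_krt = 0, reop_32h = 0, ecmo_32h = 0, krt_32h = 0,
            catheter_lt_32h = 0, missing_data = 0)
  co <- sample_cohort(cohort_spec(n_encounters = 40, seed = 6,
                                  exclusion_rates = zero))
  co$uop_ml_kg_hr <- cohort_predictions(co)
  co$age_days <- rep(100, nrow(co))  # every patient an infant
  rep <- run_validation(co, analysis_config(seed = 2, outlier_on = "residual"))
  tabs <- render_report_tables(rep)
  expect_equal(tabs$metrics_table[[2]][1], "0.00 (0.00–0.00)")
  expect_true(all(tabs$metrics_table[[4]] == "—"))
})

test_that("report JSON round-trips all numeric fields", {
  co <- sample_cohort(cohort_spec(n_encounters = 100, seed = 14))
  rep <- run_validation(co, analysis_config(seed = 3))
  f <- withr::local_tempfile(fileext = ".json")
  write_report_json(rep, f)
  parsed <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  for (nm in c("mae", "medae", "mse", "rmse", "r2")) {
    expect_equal(parsed$overall$metrics[[nm]]$point, rep$overall[[nm]]$point,
                 tolerance = 1e-15)
    expect_equal(parsed$subgroups$age_lt_12m$metrics[[nm]]$lo,
                 rep$subgroups$age_lt_12m[[nm]]$lo, tolerance = 1e-15)
  }
  expect_equal(parsed$exclusions$n_retained,
               rep$exclusion_tally[["n_retained"]])
})

test_that("scatter plot writes a nonempty file", {
  co <- sample_cohort(cohort_spec(n_encounters = 80, seed = 15))
  rep <- run_validation(co, analysis_config(seed = 2))
  f <- withr::local_tempfile(fileext = ".pdf")
  render_scatter(rep, f)
  expect_true(file.exists(f))
  expect_gt(file.size(f), 1000)
})

test_that("run configuration parses flat key = value files over defaults", {
  cfg <- parse_run_config(NULL)
  expect_equal(cfg$fraction, 0.5)
  expect_equal(cfg$iterations, 10L)
  expect_equal(cfg$ci_method, "percentile")
  expect_equal(cfg$outlier_on, "observed")

  f <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# comment", "seed = 12", "fraction = 0.4",
               "ci_method = normal"), f)
  cfg <- parse_run_config(f)
  expect_equal(cfg$seed, 12L)
  expect_equal(cfg$fraction, 0.4)
  expect_equal(cfg$ci_method, "normal")
  writeLines("bogus_key = 1", f)
  expect_error(parse_run_config(f), "unknown config key")
})

test_that("CLI demo is seed-deterministic and writes the full output set", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  expect_equal(suppressMessages(
    cli_main(c("demo", "--seed", "7", "--n", "120", "--out", d1))), 0L)
  expect_equal(suppressMessages(
    cli_main(c("demo", "--seed", "7", "--n", "120", "--out", d2))), 0L)
  for (f in c("cohort.csv", "report.json", "report_tables.txt",
              "per_encounter.csv", "scatter.pdf")) {
    expect_true(file.exists(file.path(d1, f)))
  }
  expect_identical(readLines(file.path(d1, "report.json")),
                   readLines(file.path(d2, "report.json")))
  expect_identical(readLines(file.path(d1, "cohort.csv")),
                   readLines(file.path(d2, "cohort.csv")))
})

test_that("CLI predict reports unpredictable rows without failing", {
  d <- withr::local_tempdir()
  co <- make_encounters(3, vis = c(7, 0, 7))
  cohort_file <- file.path(d, "cohort.csv")
  write_cohort_csv(co, cohort_file)
  out_file <- file.path(d, "pred.csv")
  status <- NULL
  expect_warning(
    status <- suppressMessages(
      cli_main(c("predict", "--cohort", cohort_file, "--out", out_file))),
    "unpredictable")
  expect_equal(status, 0L)
  res <- utils::read.csv(out_file)
  expect_equal(sum(is.na(res$predicted_uop_ml_kg_hr)), 1)
  expect_equal(which(is.na(res$predicted_uop_ml_kg_hr)), 2L)
  expect_equal(res$predicted_uop_ml_kg_hr[1], 2.8974, tolerance = 1e-4)
})

test_that("CLI exits nonzero with a one-line diagnostic on handled errors", {
  d <- withr::local_tempdir()
  empty <- file.path(d, "empty.csv")
  write_cohort_csv(make_encounters(0), empty)
  expect_equal(suppressMessages(
    cli_main(c("validate", "--cohort", empty, "--out", d))), 1L)
  expect_message(cli_main(c("frobnicate")), "unknown subcommand")
  expect_equal(suppressMessages(cli_main(c("frobnicate"))), 1L)
  expect_equal(suppressMessages(cli_main(c("simulate", "--bad", "1"))), 1L)
  expect_equal(suppressMessages(cli_main(character(0))), 1L)
})
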