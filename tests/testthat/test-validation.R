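make_report <- function(n = 937, seed = 42, ...) {
  co <- generate_cohort(sim_config(n_participants = n), seed = seed)
  suppressWarnings(run_validation(co, ...))
}

test_that("the full grid has 16 cells, 64 subgroup rows and consistent counts", {
  rep <- make_report()
  expect_equal(nrow(rep$cells), 16) # 4 models x 2 criteria x 2 states
  expect_equal(nrow(rep$subgroups), 64) # x 4 axes x 2 strata
  expect_equal(nrow(rep$errors), 0)
  expect_setequal(unique(rep$cells$model),
                  c("ADRS", "SIMPLIFIED_FINDRISC", "ADA", "IRS"))
  expect_true(all(rep$cells$cases <= rep$cells$n))
  # n per cell equals both states' n (same complete-case cohort)
  by_cell <- dplyr::count(rep$cells, model, criterion)
  expect_true(all(by_cell$n == 2))
  # strata within an axis partition the cell's complete-case cohort
  sizes <- rep$subgroups %>%
    dplyr::group_by(model, criterion, axis) %>%
    dplyr::summarise(n = sum(n), .groups = "drop")
  cells_n <- rep$cells %>%
    dplyr::filter(state == "original") %>%
    dplyr::select(model, criterion, n)
  joined <- dplyr::left_join(sizes, cells_n, by = c("model", "criterion"))
  expect_true(all(joined$n.x == joined$n.y))
})

test_that("recalibration preserves the C-statistic in every cell", {
  rep <- make_report()
  wide <- rep$cells %>%
    dplyr::select(model, criterion, state, c) %>%
    tidyr::pivot_wider(names_from = state, values_from = c)
  expect_equal(wide$original, wide$recalibrated, tolerance = 1e-12)
  # and the recalibrated state moves E/O toward 1
  eo <- rep$cells %>%
    dplyr::select(model, criterion, state, eo) %>%
    tidyr::pivot_wider(names_from = state, values_from = eo)
  expect_true(all(abs(eo$recalibrated - 1) <= abs(eo$original - 1) + 1e-9))
})

test_that("min-events warnings track cells with fewer than 100 cases", {
  rep <- make_report()
  warned <- rep$warnings %>%
    dplyr::filter(stage == "min_events") %>%
    dplyr::distinct(model, criterion)
  low <- rep$cells %>%
    dplyr::filter(state == "original",
                  cases < 100 | (n - cases) < 100) %>%
    dplyr::distinct(model, criterion)
  expect_equal(dplyr::arrange(warned, model, criterion),
               dplyr::arrange(low, model, criterion))
  expect_equal(
    unique(rep$cells$min_events[rep$cells$cases >= 100 &
                                  rep$cells$n - rep$cells$cases >= 100]),
    "pass")
})

test_that("iterated recalibration drives every cell's E/O to 1", {
  rep <- make_report(n = 500, seed = 7, recalibrate = "iterated",
                     subgroups = character(0))
  recal <- dplyr::filter(rep$cells, state == "recalibrated")
  expect_true(all(abs(recal$eo - 1) < 1e-6))
})

test_that("per-cell failures are reported without aborting the grid", {
  co <- generate_cohort(sim_config(n_participants = 400), seed = 8)
  broken <- score_spec(
    name = "BROKEN", form = "logistic", intercept = -2,
    items = list(list(predictor = "systolic_bp", kind = "linear_coefficient",
                      coefficient = 0.01))
  )
  specs <- c(bundled_score_specs("ADRS"), list(BROKEN = broken))
  co2 <- inject_missingness(co, list(systolic_bp = 1), seed = 1)
  rep <- suppressWarnings(run_validation(co2, specs, criteria = "fpg",
                                         subgroups = character(0)))
  expect_equal(nrow(rep$cells), 2) # ADRS still computed
  expect_equal(rep$errors$model, "BROKEN")
})

test_that("reports round-trip through JSON and flatten to CSV", {
  rep <- make_report(n = 400, seed = 3, subgroups = c("sex", "residency"))
  path <- withr::local_tempfile(fileext = ".json")
  write_report(rep, path, "json")
  back <- read_report(path)
  expect_equal(back$cells, rep$cells, tolerance = 1e-12)
  expect_equal(back$subgroups, rep$subgroups, tolerance = 1e-12)
  expect_equal(back$meta$models, rep$meta$models)
  dir <- withr::local_tempdir()
  write_report(rep, dir, "csv")
  expect_setequal(list.files(dir), c("cells.csv", "subgroups.csv",
                                     "errors.csv", "warnings.csv"))
  cells_csv <- readr::read_csv(file.path(dir, "cells.csv"),
                               show_col_types = FALSE)
  expect_equal(nrow(cells_csv), nrow(rep$cells))
  expect_equal(names(cells_csv), names(rep$cells))
})

test_that("tidiers, display rounding and plots expose the report", {
  rep <- make_report(n = 400, seed = 3, subgroups = character(0))
  expect_identical(tidy(rep), rep$cells)
  g <- glance(rep)
  expect_equal(g$n_cells, nrow(rep$cells))
  fr <- format_report(rep)
  expect_true(all(round(fr$c, 2) == fr$c))
  expect_true(all(round(fr$sensitivity, 1) == fr$sensitivity))
  p1 <- autoplot(rep)
  p2 <- autoplot(rep, "eo")
  expect_s3_class(p1, "ggplot")
  expect_s3_class(p2, "ggplot")
  roc <- roc_curve(c(0.8, 0.4, 0.5, 0.3), c(1, 1, 0, 0))
  expect_s3_class(autoplot(roc), "ggplot")
  cb <- calibration_bins(runif(50), rbinom(50, 1, 0.3), g = 5)
  expect_s3_class(autoplot(cb), "ggplot")
})

test_that("the command-line wrapper simulates and validates deterministically", {
  cli <- system.file("cli", "t2dval.R", package = "t2dval")
  dir <- withr::local_tempdir()
  csv <- file.path(dir, "cohort.csv")
  run <- function(...) {
    system2(file.path(R.home("bin"), "Rscript"), c(cli, ...),
            stdout = TRUE, stderr = TRUE)
  }
  out1 <- run("simulate", "--seed", "11", "--out", csv)
  expect_true(file.exists(csv))
  expect_true(file.exists(file.path(dir, "cohort_true_model.json")))
  rep_dir <- file.path(dir, "rep")
  out2 <- run("validate", "--cohort", csv, "--criterion", "both",
              "--subgroups", "sex", "--out", rep_dir)
  expect_true(file.exists(file.path(rep_dir, "report.json")))
  rep <- read_report(file.path(rep_dir, "report.json"))
  expect_equal(nrow(rep$cells), 16)
  # rerunning with the same seed is byte-identical
  csv2 <- file.path(dir, "cohort2.csv")
  run("simulate", "--seed", "11", "--out", csv2)
  expect_identical(readLines(csv), readLines(csv2))
})
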