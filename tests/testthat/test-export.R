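fixture_experiment <- function() {
  make_exact_runs(days = c(2, 5, 8),
                  fractions_by_group = list(WT = c(1, 0.5, 0.25),
                                            mut = c(1, 0.25, 0.05)))
}

test_that("export_runs emits one row per well per run with configured columns", {
  fx <- make_exact_runs(days = c(2, 4), fractions_by_group =
                          list(WT = c(1, 1)), n_rep = 3)
  tab <- export_runs(fx$runs, fx$wells, curve_params(),
                     export_config("runs", dt_inflection = TRUE))
  expect_identical(nrow(tab), 6L)  # 2 runs x 3 wells
  expect_true(all(c("well_name", "run_name", "day", "dt_interval",
                    "dt_inflection") %in% names(tab)))
  expect_false(any(grepl("^od_", names(tab))))  # append_ods off by default
  expect_equal(tab$dt_interval, rep(1.5, 6), tolerance = 1e-9)

  # OD columns appear only when requested, background-subtracted by default
  tab2 <- export_runs(fx$runs, fx$wells, curve_params(),
                      export_config("runs", append_ods = TRUE))
  od_cols <- grep("^od_", names(tab2))
  expect_length(od_cols, length(fx$runs[[1]]$table$times))
  expect_equal(tab2[1, od_cols[1]][[1]],
               max(fx$runs[[1]]$table$wells[1, 1] - 0.15, 1e-4))
  tab3 <- export_runs(fx$runs, fx$wells, curve_params(),
                      export_config("runs", append_ods = TRUE,
                                    subtract_background = FALSE))
  expect_equal(tab3[1, grep("^od_", names(tab3))[1]][[1]],
               unname(fx$runs[[1]]$table$wells[1, 1]))
})

test_that("export_runs honors well and run selections", {
  fx <- make_exact_runs(days = c(2, 4), fractions_by_group =
                          list(WT = c(1, 1)), n_rep = 3)
  tab <- export_runs(fx$runs, fx$wells, curve_params(),
                     export_config("runs", selected_wells = 1L))
  expect_identical(nrow(tab), 2L)
  expect_true(all(tab$well_position == 1L))
  tab2 <- export_runs(fx$runs, fx$wells, curve_params(),
                      export_config("runs", selected_runs = 4))
  expect_true(all(tab2$day == 4))
  expect_error(export_runs(fx$runs, fx$wells, curve_params(),
                           export_config("runs", selected_wells = 99L)),
               "empty well selection")
})

test_that("export_lineages ungrouped gives one row per well", {
  fx <- fixture_experiment()
  ln <- build_lineages(fx$runs, fx$wells)
  tab <- export_lineages(ln, export_config("lineages",
                                           show_time_shifts = TRUE))
  expect_identical(nrow(tab), 6L)
  expect_true(all(c("survival_day_2", "survival_day_5", "survival_day_8",
                    "time_shift_day_5", "survival_integral")
                  %in% names(tab)))
  expect_equal(tab$survival_day_2, rep(1, 6))
})

test_that("export_lineages grouped gives one row per group with spreads", {
  fx <- fixture_experiment()
  ln <- build_lineages(fx$runs, fx$wells)
  cfg <- export_config("lineages", grouping = "average",
                       reference_group = "WT", pct_change = TRUE,
                       log2_ratio = TRUE, t_test = TRUE)
  tab <- export_lineages(ln, cfg)
  expect_identical(nrow(tab), 2L)
  expect_true(all(c("survival_integral", "survival_integral_sd",
                    "pct_change", "log2_ratio", "t_stat", "p_value")
                  %in% names(tab)))
})

test_that("a t-test without grouping is refused", {
  expect_error(export_config("lineages", t_test = TRUE,
                             reference_group = "WT"),
               "grouping option")
  fx <- fixture_experiment()
  ln <- build_lineages(fx$runs, fx$wells)
  cfg <- export_config("lineages", grouping = "average",
                       reference_group = "WT", t_test = TRUE)
  cfg$grouping <- "none"  # forced past the constructor
  expect_error(export_lineages(ln, cfg), "grouping option")
})

test_that("lineage tables survive a CSV round trip at printed precision", {
  fx <- fixture_experiment()
  ln <- build_lineages(fx$runs, fx$wells)
  tab <- export_lineages(ln, export_config("lineages"))
  f <- tempfile(fileext = ".csv")
  write_export(tab, f)
  back <- utils::read.csv(f)
  for (col in grep("^survival", names(tab), value = TRUE))
    expect_equal(back[[col]], tab[[col]], tolerance = 1e-6)
})
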