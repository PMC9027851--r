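test_that("a run emits all result tables, a summary and a complete manifest", {
  dir <- withr::local_tempdir()
  fit <- run_bia("croatia", dir)
  expected <- c("table02_population.csv", "table09_costs.csv",
                "table10_utilization.csv", "table11_event_savings.csv",
                "table12_avoided_events.csv", "table13_sensitivity.csv",
                "summary.csv")
  expect_true(all(file.exists(file.path(dir, expected))))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  expect_true(all(expected %in% manifest$files$file))
  expect_equal(manifest$mode, "published_tables")
  expect_match(manifest$input_checksum, "^[0-9a-f]{32}$")
})

test_that("summary CSV equals the fit object (single source of truth)", {
  dir <- withr::local_tempdir()
  fit <- run_bia(croatia_scenario(), dir)
  s <- utils::read.csv(file.path(dir, "summary.csv"))
  expect_equal(s$budget_impact, fit$totals$budget_impact)
  expect_equal(s$total_costs, fit$totals$total_costs)
  expect_equal(s$cost_per_patient_year_display, 57)
  expect_equal(s$incremental_cost_per_patient_display, 0.67)
})

test_that("identical runs are byte-identical", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  run_bia(croatia_scenario(), d1)
  run_bia(croatia_scenario(), d2)
  for (f in list.files(d1, pattern = "\\.csv$"))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  cmp <- compare_runs(d1, d2)
  expect_equal(nrow(cmp), 0)
})

test_that("compare_runs localizes the mode contrast to the override cells", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  run_bia(croatia_scenario("published_tables"), d1)
  run_bia(croatia_scenario("as_stated"), d2)
  cmp <- compare_runs(d1, d2, threshold = 0)
  expect_true(all(cmp$flagged))
  ev <- utils::read.csv(file.path(d1, "table11_event_savings.csv"))
  diff_ev <- cmp[cmp$file == "table11_event_savings.csv" &
                   cmp$column == "savings", ]
  key <- unique(paste(ev$event[diff_ev$row], ev$group[diff_ev$row]))
  fams <- c("Stroke CVD", "Myocardial infarction - fatal CVD",
            "Myocardial infarction - nonfatal DMT2+CVD",
            "Myocardial infarction - nonfatal CVD",
            "Angina DMT2+CVD", "Angina CVD",
            "Revascularization - stenotic coronary arteries DMT2+CVD",
            "Revascularization - stenotic coronary arteries CVD")
  expect_setequal(setdiff(key, "Total "), fams)
  # population and utilization tables are mode-invariant
  expect_false("table02_population.csv" %in% cmp$file)
  expect_false("table10_utilization.csv" %in% cmp$file)
})

test_that("invalid inputs fail with diagnostics", {
  expect_error(run_bia(tempfile("missing", fileext = ".yaml"), tempdir()),
               "not found")
  expect_error(compare_runs(withr::local_tempdir(), withr::local_tempdir()),
               "no common CSV")
})
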