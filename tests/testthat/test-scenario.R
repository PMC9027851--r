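test_that("built-in scenario has the documented structure in both modes", {
  for (mode in c("published_tables", "as_stated")) {
    s <- croatia_scenario(mode)
    expect_s3_class(s, "cmm_scenario")
    expect_length(s$years, 3)
    expect_equal(nrow(s$services), 8)
    expect_equal(nrow(s$events), 12)
    expect_equal(s$enrollment_fractions, c(0.05, 0.07, 0.09))
    expect_length(validate_scenario(s), 0)
  }
  expect_equal(croatia_scenario("published_tables")$costs$therapy_cost_per_patient_year,
               37.4733)
  expect_equal(croatia_scenario("as_stated")$costs$therapy_cost_per_patient_year,
               37.47)
})

test_that("the two modes differ only in the documented override fields", {
  pub <- croatia_scenario("published_tables")
  ast <- croatia_scenario("as_stated")
  # identical everywhere except: label/mode, therapy cost, event overrides,
  # fixed labour/training totals
  expect_identical(pub$years, ast$years)
  expect_identical(pub$population, ast$population)
  expect_identical(pub$enrollment_fractions, ast$enrollment_fractions)
  expect_identical(pub$services, ast$services)
  expect_identical(pub$sensitivity_factors, ast$sensitivity_factors)
  base_cols <- setdiff(names(pub$events),
                       c("override_risk_reduction", "override_unit_cost"))
  expect_identical(pub$events[, base_cols], ast$events[, base_cols])
  expect_true(all(is.na(ast$events$override_risk_reduction)))
  expect_true(all(is.na(ast$events$override_unit_cost)))
  rr_ov <- which(!is.na(pub$events$override_risk_reduction))
  uc_ov <- which(!is.na(pub$events$override_unit_cost))
  expect_identical(pub$events$group[rr_ov], c("CVD", "CVD"))
  expect_identical(pub$events$event[rr_ov],
                   c("Stroke", "Myocardial infarction - fatal"))
  expect_length(uc_ov, 6)  # nonfatal MI, angina, revascularization x 2 groups
  expect_equal(unique(pub$events$override_unit_cost[uc_ov]), 864.79)
  same_costs <- setdiff(names(pub$costs),
                        c("therapy_cost_per_patient_year",
                          "fixed_labour_costs", "fixed_training_costs"))
  expect_identical(pub$costs[same_costs], ast$costs[same_costs])
  expect_null(pub$costs$fixed_labour_costs)
  expect_length(ast$costs$fixed_labour_costs, 3)
})

test_that("validation reports violations as data, naming field and rule", {
  s <- croatia_scenario()
  expect_length(validate_scenario(s), 0)

  bad <- unclass(s)
  bad$enrollment_fractions[2] <- 1.2
  v <- validate_scenario(bad)
  expect_length(v, 1)
  expect_match(v, "enrollment_fractions")

  bad <- unclass(s)
  bad$services$unit_price[3] <- -1
  v <- validate_scenario(bad)
  expect_length(v, 1)
  expect_match(v, "unit_price")

  bad <- unclass(s)
  bad$years <- c(2023L, 2022L, 2024L)
  v <- validate_scenario(bad)
  expect_length(v, 1)
  expect_match(v, "years")

  bad <- unclass(s)
  bad$population$typo_field <- 1
  expect_match(validate_scenario(bad), "unknown field 'typo_field'")
})

test_that("overrides are rejected outside published_tables mode", {
  s <- unclass(croatia_scenario("published_tables"))
  s$mode <- "as_stated"
  expect_match(paste(validate_scenario(s), collapse = "; "),
               "overrides may only be populated in published_tables")
})

test_that("scenario documents round-trip through YAML and JSON", {
  scenarios <- list(croatia_scenario("published_tables"),
                    croatia_scenario("as_stated"),
                    random_scenario(seed = 11),
                    random_scenario(seed = 12, n_years = 5,
                                    n_services = 2, n_events = 0))
  for (s in scenarios) for (ext in c(".yaml", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_scenario(s, path)
    expect_equal(read_scenario(path), s, tolerance = 1e-12)
  }
})

test_that("shipped scenario documents equal the in-code parameterization", {
  for (mode in c("published_tables", "as_stated")) {
    path <- system.file("extdata",
                        if (mode == "published_tables") "croatia_published.yaml"
                        else "croatia_as_stated.yaml", package = "cmmbia")
    expect_equal(read_scenario(path), croatia_scenario(mode), tolerance = 1e-12)
  }
})

test_that("malformed documents fail with a named diagnostic", {
  expect_error(read_scenario(tempfile("nope", fileext = ".yaml")), "not found")
  p <- withr::local_tempfile(fileext = ".yaml")
  writeLines("label: x\nyears: [2022", p)
  expect_error(read_scenario(p), "parse error")
  p2 <- withr::local_tempfile(fileext = ".yaml")
  s <- scenario_list <- yaml::read_yaml(system.file(
    "extdata", "croatia_published.yaml", package = "cmmbia"))
  scenario_list$mystery_knob <- 1
  writeLines(yaml::as.yaml(scenario_list), p2)
  expect_error(read_scenario(p2), "mystery_knob")
})
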