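test_that("effective risk reduction chains incidence, guideline effect, efficiency", {
  expect_equal(effective_risk_reduction(23.86, 0.40, 0.9), 0.0085896)
  expect_equal(effective_risk_reduction(14.60, 0.35, 0.9), 0.0045990)
  expect_equal(effective_risk_reduction(50, 0, 0.9), 0)
  expect_error(effective_risk_reduction(10, 1.5, 0.9), "fractions")
})

test_that("event unit costs sum components unless overridden", {
  expect_equal(event_unit_cost(list(inpatient_cost = 1182.24,
                                    followup_cost = 1176,
                                    device_cost = 2473.95,
                                    override_unit_cost = NA_real_)), 4832.19)
  expect_equal(event_unit_cost(list(inpatient_cost = 864.79, followup_cost = 0,
                                    device_cost = 0,
                                    override_unit_cost = NA_real_)), 864.79)
  expect_equal(event_unit_cost(list(inpatient_cost = 0, followup_cost = 0,
                                    device_cost = 0,
                                    override_unit_cost = NA_real_)), 0)
  expect_equal(event_unit_cost(list(inpatient_cost = 1806.20,
                                    followup_cost = 1176, device_cost = 0,
                                    override_unit_cost = 864.79)), 864.79)
})

test_that("avoided events round half-up from the unrounded expectation", {
  av <- avoided_events(10217, 0.0085896)
  expect_equal(av$expected, 87.759944, tolerance = 1e-6)
  expect_equal(av$rounded, 88)
  expect_equal(avoided_events(22325, 0.0045990)$rounded, 103)
  expect_equal(avoided_events(0, 0.5), list(expected = 0, rounded = 0))
})

test_that("published-tables mode reproduces every printed event cell", {
  fit <- croatia_fit()
  cells <- fit$events[fit$events$event != "Total", ]
  for (i in seq_len(nrow(ref$event_rows))) {
    rows <- cells[cells$event == ref$event_rows$event[i] &
                    cells$group == ref$event_rows$group[i], ]
    expect_equal(nrow(rows), 3)
    expect_cell_close(rows$savings, ref$event_savings[i, ])
    expect_equal(rows$avoided_rounded, ref$avoided[i, ])
  }
  tot <- fit$events[fit$events$event == "Total", ]
  expect_cell_close(tot$savings, ref$event_yearly, rel = 5e-4)
  expect_lte(abs(sum(cells$savings) - ref$event_total), 5e-4 * ref$event_total)
})

test_that("savings must come from unrounded expected events", {
  # oracle: rounded-count x cost misses at least one printed cell by more
  # than the replication tolerance, while the unrounded expectation meets all
  fit <- croatia_fit()
  cells <- fit$events[fit$events$event != "Total", ]
  printed <- unlist(lapply(seq_len(nrow(ref$event_rows)), function(i)
    ref$event_savings[i, ]))
  ordered <- do.call(rbind, lapply(seq_len(nrow(ref$event_rows)), function(i)
    cells[cells$event == ref$event_rows$event[i] &
            cells$group == ref$event_rows$group[i], ]))
  tol <- pmax(5, 0.001 * printed)
  expect_true(all(abs(ordered$savings - printed) <= tol))
  rounded_version <- ordered$avoided_rounded * ordered$unit_cost
  expect_gt(sum(abs(rounded_version - printed) > tol), 0)
})

test_that("as_stated mode recomputes from the literal parameter tables", {
  fit <- bia(croatia_scenario("as_stated"))
  cells <- fit$events[fit$events$event != "Total", ]
  stroke_cvd <- cells[cells$event == "Stroke" & cells$group == "CVD" &
                        cells$year == 2022, ]
  # independent recomputation: enrolled x (7.70/1000 x 0.35 x 0.9) x 3135.45
  enrolled_2022 <- (765687 - 240398) * 0.85 * 0.05
  expect_equal(stroke_cvd$savings,
               enrolled_2022 * (7.70 / 1000 * 0.35 * 0.9) * 3135.45,
               tolerance = 1e-12)
  expect_equal(stroke_cvd$risk_reduction, 0.0024255)
})

test_that("mode contrast: exactly the five override families differ", {
  pub <- event_savings_ledger(croatia_scenario("published_tables"))
  ast <- event_savings_ledger(croatia_scenario("as_stated"))
  pub_c <- pub[pub$event != "Total", ]
  ast_c <- ast[ast$event != "Total", ]
  differs <- abs(pub_c$savings - ast_c$savings) > 1e-9
  key <- paste(pub_c$event, pub_c$group)
  expect_setequal(unique(key[differs]), c(
    "Stroke CVD", "Myocardial infarction - fatal CVD",
    "Myocardial infarction - nonfatal DMT2+CVD",
    "Myocardial infarction - nonfatal CVD",
    "Angina DMT2+CVD", "Angina CVD",
    "Revascularization - stenotic coronary arteries DMT2+CVD",
    "Revascularization - stenotic coronary arteries CVD"))
})

test_that("event savings are linear in enrollment and incidence", {
  s <- random_scenario(33)
  base <- event_savings_ledger(s)
  base_tot <- sum(base$savings[base$event != "Total"])
  s2 <- s
  s2$events$incidence_per_1000 <- 2 * s2$events$incidence_per_1000
  doubled <- event_savings_ledger(s2)
  expect_equal(sum(doubled$savings[doubled$event != "Total"]), 2 * base_tot,
               tolerance = 1e-12)
  s3 <- s
  s3$enrollment_fractions <- 0.5 * s3$enrollment_fractions
  halved <- event_savings_ledger(s3)
  expect_equal(sum(halved$savings[halved$event != "Total"]), 0.5 * base_tot,
               tolerance = 1e-12)
})
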