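test_that("visits, FTE and headcount follow the capacity model", {
  expect_equal(annual_visits(32541.7, 2), 65083.4)
  expect_equal(annual_visits(0, 2), 0)
  f <- pharmacist_fte(119504.88, 2904)
  expect_equal(f$fte, 41.1518, tolerance = 1e-5)
  expect_equal(f$headcount, 41L)
  expect_equal(pharmacist_fte(92027.88, 2904)$headcount, 32L)
  expect_equal(pharmacist_fte(2904, 2904), list(fte = 1, headcount = 1L))
  expect_error(pharmacist_fte(10, 0), "capacity")
})

test_that("labour, training and therapy components price correctly", {
  expect_equal(labour_cost(22.41164, 28000), 627525.9, tolerance = 1e-6)
  expect_equal(labour_cost(41.1518, 28000), 1152250.4, tolerance = 1e-6)
  expect_equal(labour_cost(0, 28000), 0)
  # as_stated mode prices the integer headcount
  expect_equal(labour_cost(22.41164, 28000, "as_stated", 22L), 616000)
  expect_equal(training_cost(22, 200), 4400)
  expect_equal(training_cost(0, 200), 0)
  expect_equal(therapy_cost(0, 37.4733), 0)
  expect_lte(abs(therapy_cost(32541.6975, 37.4733) - 1219446), 3)
  expect_lte(abs(therapy_cost(59752.414, 37.4733) - 2239122), 3)
})

test_that("the published-tables cost ledger reproduces the printed cost table", {
  fit <- croatia_fit()
  led <- fit$costs
  yearly <- led[led$year != "Total", ]
  expect_equal(yearly$headcount, ref$headcount)
  expect_cell_close(yearly$labour_cost, ref$labour)
  expect_cell_close(yearly$therapy_cost, ref$therapy)
  tot <- led[led$year == "Total", ]
  expect_lte(abs(tot$labour_cost + tot$training_cost - ref$labour_total), 5)
  expect_lte(abs(tot$therapy_cost - ref$therapy_total), 10)
  expect_lte(abs(tot$total_cost - ref$costs_total), 10)
})

test_that("as_stated mode uses the fixed printed labour and training totals", {
  led <- cost_ledger(croatia_scenario("as_stated"))
  yearly <- led[led$year != "Total", ]
  expect_equal(yearly$labour_cost, c(632008.13, 889177.20, 1154142.67))
  expect_equal(yearly$training_cost, c(4482.27, 1855.73, 1892.40))
  # without fixed values, as_stated falls back to headcount pricing
  s <- random_scenario(21)
  s$mode <- "as_stated"
  led2 <- cost_ledger(s)
  y2 <- led2[led2$year != "Total", ]
  expect_equal(y2$labour_cost,
               y2$headcount * s$costs$annual_cost_per_pharmacist)
  expect_equal(y2$training_cost,
               y2$new_hires * s$costs$training_cost_per_pharmacist)
})

test_that("labour is linear in FTE and therapy linear in enrollment", {
  set.seed(7)
  for (i in 1:10) {
    fte <- runif(1, 0, 100); k <- runif(1, 0.1, 10)
    expect_equal(labour_cost(k * fte, 28000), k * labour_cost(fte, 28000),
                 tolerance = 1e-12)
    n <- runif(1, 0, 1e5)
    expect_equal(therapy_cost(k * n, 37.47), k * therapy_cost(n, 37.47),
                 tolerance = 1e-12)
  }
})

test_that("headcount is non-decreasing under non-decreasing enrollment and growth", {
  for (seed in 1:15) {
    s <- random_scenario(seed)
    s$population$growth_rate <- abs(s$population$growth_rate)
    s$enrollment_fractions <- sort(s$enrollment_fractions)
    led <- cost_ledger(s)
    h <- led$headcount[led$year != "Total"]
    expect_true(all(diff(h) >= 0))
  }
})
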