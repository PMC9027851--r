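#' Run the budget-impact model
#'
#' The model's single entry point: projects the eligible and enrolled
#' population, builds the intervention cost ledger, the utilization-savings
#' ledger and the clinical-event savings ledger, aggregates them into the
#' net budget impact and per-patient metrics, and evaluates the
#' deterministic sensitivity scan.
#'
#' The budget impact is total direct costs minus total savings (both
#' savings families); a negative value means the service saves more than
#' it costs (dominant intervention). Per-patient metrics divide by the
#' total enrolled headcount over the horizon (sum of per-year rounded
#' totals): cost per treated patient per year, displayed to the nearest
#' euro, and the incremental cost per treated patient, displayed to two
#' decimals.
#'
#' @param scenario a [cmm_scenario] (default: the built-in Croatia
#'   parameterization in published-tables mode).
#' @param factors sensitivity multipliers (> 0) applied to both savings-side
#'   rate families; defaults to the scenario's own.
#' @return object of class \code{cmm_bia}: a list with the scenario, the
#'   \code{projection}, the three ledgers (\code{costs},
#'   \code{utilization}, \code{events}), \code{totals} (total_costs,
#'   total_utilization_savings, total_event_savings, total_savings,
#'   budget_impact, avoided_events_total), \code{per_patient},
#'   \code{sensitivity} (see [sensitivity_scan()]) and
#'   \code{breakeven_factor}.
#' @examples
#' fit <- bia(croatia_scenario())
#' fit$totals$budget_impact
#' summary(fit)
#' @export
bia <- function(scenario = croatia_scenario(), factors = scenario$sensitivity_factors) {
  stopifnot(inherits(scenario, "cmm_scenario"))
  v <- validate_scenario(scenario)
  if (length(v)) fail("invalid scenario:\n", paste0("  - ", v, collapse = "\n"))

  projection <- enrollment_projection(scenario)
  costs <- cost_ledger(scenario, projection)
  util <- utilization_ledger(scenario, projection)
  events <- event_savings_ledger(scenario, projection)

  total_costs <- costs$total_cost[costs$year == "Total"]
  total_util <- util$total[util$service == "Total"]
  ev_cells <- event_cells(events)
  total_event <- sum(ev_cells$savings)
  total_savings <- total_util + total_event
  budget_impact <- total_costs - total_savings
  enrolled_total <- sum(proj_total(projection, "enrolled_rounded"))

  per_patient <- list(
    enrolled_total = enrolled_total,
    cost_per_patient_year = total_costs / enrolled_total,
    incremental_cost_per_patient = budget_impact / enrolled_total,
    cost_per_patient_year_display =
      round_half_up(total_costs / enrolled_total),
    incremental_cost_per_patient_display =
      round_half_up(budget_impact / enrolled_total, 2)
  )

  fit <- structure(list(
    scenario = scenario, projection = projection,
    costs = costs, utilization = util, events = events,
    totals = list(
      total_costs = total_costs,
      total_utilization_savings = total_util,
      total_event_savings = total_event,
      total_savings = total_savings,
      budget_impact = budget_impact,
      avoided_events_total = sum(ev_cells$avoided_rounded)
    ),
    per_patient = per_patient
  ), class = "cmm_bia")
  fit$sensitivity <- sensitivity_scan(scenario, factors, projection = projection)
  fit$breakeven_factor <- if (total_savings > 0 || total_costs == 0)
    breakeven_factor(fit) else NA_real_
  fit
}

#' Deterministic sensitivity scan over savings-side rates
#'
#' For each factor \code{f}, both the avoided-service rates and the
#' effective risk reductions are multiplied by \code{f} and the model is
#' re-run (costs are unaffected). Because every savings ledger is linear
#' in its rates, the result equals \code{total_costs - f * total_savings};
#' the re-run is checked against this closed form and any disagreement
#' beyond numerical noise is an error. A factor above 1 models
#' underestimated benefits; below 1, overestimated benefits (e.g. 0.6 is
#' the 40%-overestimation scenario).
#'
#' @param scenario a [cmm_scenario].
#' @param factors positive multipliers; 1 reproduces the baseline.
#' @param projection optional precomputed [enrollment_projection()].
#' @return data frame with columns \code{factor}, \code{total_savings},
#'   \code{budget_impact}, \code{incremental_cost_per_patient} and its
#'   display rounding (nearest euro).
#' @examples
#' sensitivity_scan(croatia_scenario(), c(1, 0.95, 0.6))
#' @export
sensitivity_scan <- function(scenario, factors,
                             projection = enrollment_projection(scenario)) {
  if (any(factors <= 0)) fail("sensitivity_scan: factors must be > 0")
  costs <- cost_ledger(scenario, projection)
  total_costs <- costs$total_cost[costs$year == "Total"]
  base_util <- utilization_ledger(scenario, projection)
  base_event <- event_savings_ledger(scenario, projection)
  base_savings <- base_util$total[base_util$service == "Total"] +
    sum(event_cells(base_event)$savings)
  enrolled_total <- sum(proj_total(projection, "enrolled_rounded"))

  rows <- lapply(factors, function(f) {
    u <- utilization_ledger(scenario, projection, rate_scale = f)
    e <- event_savings_ledger(scenario, projection, rr_scale = f)
    sav <- u$total[u$service == "Total"] + sum(event_cells(e)$savings)
    bi <- total_costs - sav
    closed <- total_costs - f * base_savings
    if (abs(bi - closed) > 1e-9 * max(1, abs(closed)))
      fail("sensitivity_scan: re-run disagrees with closed form at f = ", f)
    data.frame(factor = f, total_savings = sav, budget_impact = bi,
               incremental_cost_per_patient = bi / enrolled_total,
               incremental_cost_per_patient_display =
                 round_half_up(bi / enrolled_total))
  })
  do.call(rbind, rows)
}

#' Break-even savings factor
#'
#' The common multiplier on both savings-side rate families at which the
#' budget impact is exactly zero: total costs divided by total savings.
#' Values just above 1 mean the baseline is close to break-even.
#'
#' @param fit a fitted \code{cmm_bia} object.
#' @return scalar factor (0 when costs are 0; error if savings are 0 with
#'   positive costs).
#' @examples
#' breakeven_factor(bia(croatia_scenario()))  # ~1.012
#' @export
breakeven_factor <- function(fit) {
  stopifnot(inherits(fit, "cmm_bia"))
  tc <- fit$totals$total_costs
  ts <- fit$totals$total_savings
  if (tc == 0) return(0)
  if (ts <= 0) fail("breakeven_factor: total savings must be > 0")
  tc / ts
}

#' @export
print.cmm_bia <- function(x, ...) {
  eur <- function(v) formatC(v, format = "f", digits = 0, big.mark = ",")
  t <- x$totals
  cat("CMM budget-impact model run\n")
  cat("  scenario:          ", x$scenario$label, "\n", sep = "")
  cat("  horizon:           ", paste(range(x$scenario$years), collapse = "-"),
      "\n", sep = "")
  cat("  enrolled patients: ",
      format(x$per_patient$enrolled_total, big.mark = ","), "\n", sep = "")
  cat("  total costs:        EUR ", eur(t$total_costs), "\n", sep = "")
  cat("  total savings:      EUR ", eur(t$total_savings),
      "  (utilization ", eur(t$total_utilization_savings),
      " + events ", eur(t$total_event_savings), ")\n", sep = "")
  cat("  budget impact:      EUR ", eur(t$budget_impact), "\n", sep = "")
  cat("  avoided events:    ", t$avoided_events_total, "\n", sep = "")
  cat("  cost/patient/year:  EUR ", x$per_patient$cost_per_patient_year_display,
      "   incremental/patient: EUR ",
      sprintf("%.2f", x$per_patient$incremental_cost_per_patient_display),
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.cmm_bia <- function(object, ...) {
  structure(list(fit = object), class = "summary.cmm_bia")
}

#' @export
print.summary.cmm_bia <- function(x, ...) {
  fit <- x$fit
  print(fit)
  cat("\nPer-year costs (EUR):\n")
  print(fit$costs[, c("year", "headcount", "labour_cost", "training_cost",
                      "therapy_cost", "total_cost")], row.names = FALSE)
  cat("\nSensitivity of the budget impact to the savings-side rates:\n")
  print(fit$sensitivity, row.names = FALSE, digits = 7)
  cat("\nBreak-even savings factor: ", sprintf("%.4f", fit$breakeven_factor),
      "\n", sep = "")
  invisible(x)
}

#' Plot a budget-impact model run
#'
#' Two base-graphics panels: yearly costs against savings, and the budget
#' impact as a function of the savings-side scaling factor with the
#' break-even point marked.
#'
#' @param x a \code{cmm_bia} object.
#' @param ... passed to [graphics::barplot()].
#' @return \code{x}, invisibly.
#' @export
plot.cmm_bia <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  yrs <- as.character(x$scenario$years)
  costs <- x$costs$total_cost[x$costs$year != "Total"]
  util <- as.matrix(x$utilization[x$utilization$service == "Total", yrs])[1, ]
  evs <- vapply(x$scenario$years, function(y)
    sum(event_cells(x$events)$savings[event_cells(x$events)$year == y]),
    numeric(1))
  graphics::barplot(rbind(costs, util + evs) / 1e6, beside = TRUE,
                    names.arg = yrs, col = c("grey30", "grey70"),
                    ylab = "EUR (millions)", main = "Costs vs savings", ...)
  graphics::legend("topleft", c("costs", "savings"),
                   fill = c("grey30", "grey70"), bty = "n")
  f <- seq(0.5, 1.1, by = 0.05)
  bi <- x$totals$total_costs - f * x$totals$total_savings
  graphics::plot(f, bi / 1e6, type = "l", xlab = "savings scaling factor",
                 ylab = "budget impact (EUR millions)",
                 main = "Sensitivity")
  graphics::abline(h = 0, lty = 3)
  graphics::points(x$breakeven_factor, 0, pch = 19)
  invisible(x)
}
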