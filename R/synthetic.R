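#' Generate a random valid scenario
#'
#' Draws a complete scenario from broad bounds bracketing realistic
#' national-scale parameterizations, for property testing of every model
#' stage without any real parameter set. A fixed seed gives a reproducible
#' scenario; the draw order is append-only (new parameters are drawn after
#' all existing ones), so extending the generator never reshuffles
#' existing draws.
#'
#' Bounds: on-medication population base 1e5-1e7 (log-uniform) with an
#' on-medication fraction 0.01-0.5; growth -0.02-0.05; enrollment
#' fractions 0-0.2; avoided counts 0-12,000 against 33,706 encounters;
#' unit prices 5-5,000 EUR (log-uniform); incidence 0.5-50 per 1000;
#' guideline risk reductions 0.05-0.6; efficiency 0.5-1.
#'
#' @param seed integer seed driving one pseudo-random stream.
#' @param n_years number of horizon years (>= 1).
#' @param n_services avoided-service categories.
#' @param n_events clinical-event specifications.
#' @return a validated [cmm_scenario] in \code{published_tables} mode with
#'   no overrides.
#' @examples
#' s <- random_scenario(seed = 1)
#' validate_scenario(s)  # character(0)
#' @export
random_scenario <- function(seed = 0, n_years = 3, n_services = 8, n_events = 12) {
  stopifnot(n_years >= 1, n_services >= 0, n_events >= 0)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  runif_log <- function(n, lo, hi) exp(stats::runif(n, log(lo), log(hi)))

  pop <- runif_log(1, 1e5, 1e7)
  comb_frac <- stats::runif(1, 0.01, 0.5)
  combined <- pop * comb_frac
  dmt2 <- combined * stats::runif(1, 0, 1)
  growth <- stats::runif(1, -0.02, 0.05)
  poly <- stats::runif(1, 0, 1)
  enroll <- stats::runif(n_years, 0, 0.2)
  visits_pp <- sample(1:4, 1)
  capacity <- stats::runif(1, 1000, 4000)
  annual_cost <- stats::runif(1, 10000, 50000)
  training <- stats::runif(1, 50, 500)
  therapy <- runif_log(1, 5, 200)

  services <- data.frame(
    name = sprintf("service_%02d", seq_len(n_services)),
    avoided_count = stats::runif(n_services, 0, 12000),
    adjustment = stats::runif(n_services, 0.5, 1),
    encounters_base = rep(33706, n_services),
    unit_price = runif_log(n_services, 5, 5000),
    stringsAsFactors = FALSE
  )
  events <- data.frame(
    event = sprintf("event_%02d", seq_len(n_events)),
    group = rep_len(c("DMT2+CVD", "CVD"), n_events),
    incidence_per_1000 = stats::runif(n_events, 0.5, 50),
    guideline_risk_reduction = stats::runif(n_events, 0.05, 0.6),
    efficiency = stats::runif(n_events, 0.5, 1),
    inpatient_cost = runif_log(n_events, 100, 5000),
    followup_cost = stats::runif(n_events, 0, 2000),
    device_cost = numeric(n_events),
    override_risk_reduction = rep(NA_real_, n_events),
    override_unit_cost = rep(NA_real_, n_events),
    stringsAsFactors = FALSE
  )
  cmm_scenario(
    label = sprintf("synthetic scenario (seed %d)", seed),
    years = seq(2022, length.out = n_years),
    mode = "published_tables",
    population = list(dmt2_on_medication = dmt2,
                      combined_on_medication = combined,
                      growth_rate = growth, polypharmacy_fraction = poly),
    enrollment_fractions = enroll,
    costs = list(visits_per_patient_year = visits_pp,
                 visit_capacity_per_pharmacist_year = capacity,
                 annual_cost_per_pharmacist = annual_cost,
                 training_cost_per_pharmacist = training,
                 therapy_cost_per_patient_year = therapy),
    services = services,
    events = events
  )
}

#' Multiplicatively perturb every numeric parameter of a scenario
#'
#' Each numeric parameter is multiplied by \code{1 + u}, \code{u} uniform
#' in \code{[-relative_noise, relative_noise]}. Fractions are capped at 1
#' and the overlap ordering (combined >= DMT2) is preserved, so the result
#' is always a valid scenario.
#'
#' @param s a [cmm_scenario].
#' @param relative_noise noise half-width, in \eqn{[0, 0.5]}.
#' @param seed integer seed.
#' @return a perturbed, validated [cmm_scenario].
#' @examples
#' perturb_scenario(croatia_scenario(), 0.05, seed = 1)
#' @export
perturb_scenario <- function(s, relative_noise, seed = 0) {
  stopifnot(inherits(s, "cmm_scenario"))
  if (relative_noise < 0 || relative_noise > 0.5)
    fail("perturb_scenario: relative_noise must be in [0, 0.5]")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  jig <- function(x, cap1 = FALSE) {
    y <- x * (1 + stats::runif(length(x), -relative_noise, relative_noise))
    if (cap1) pmin(y, 1) else y
  }
  p <- s$population
  p$dmt2_on_medication <- jig(p$dmt2_on_medication)
  p$combined_on_medication <- max(jig(p$combined_on_medication),
                                  p$dmt2_on_medication)
  p$growth_rate <- jig(p$growth_rate)
  p$polypharmacy_fraction <- jig(p$polypharmacy_fraction, cap1 = TRUE)
  co <- s$costs
  for (f in c("visits_per_patient_year", "visit_capacity_per_pharmacist_year",
              "annual_cost_per_pharmacist", "training_cost_per_pharmacist",
              "therapy_cost_per_patient_year"))
    co[[f]] <- jig(co[[f]])
  sv <- s$services
  sv$avoided_count <- jig(sv$avoided_count)
  sv$adjustment <- jig(sv$adjustment, cap1 = TRUE)
  sv$unit_price <- jig(sv$unit_price)
  ev <- s$events
  ev$incidence_per_1000 <- jig(ev$incidence_per_1000)
  ev$guideline_risk_reduction <- jig(ev$guideline_risk_reduction, cap1 = TRUE)
  ev$efficiency <- jig(ev$efficiency, cap1 = TRUE)
  ev$inpatient_cost <- jig(ev$inpatient_cost)
  ev$followup_cost <- jig(ev$followup_cost)
  ev$device_cost <- jig(ev$device_cost)
  ok <- !is.na(ev$override_risk_reduction)
  ev$override_risk_reduction[ok] <- jig(ev$override_risk_reduction[ok], cap1 = TRUE)
  ok <- !is.na(ev$override_unit_cost)
  ev$override_unit_cost[ok] <- jig(ev$override_unit_cost[ok])

  cmm_scenario(
    label = s$label,
    years = s$years, mode = s$mode, population = p,
    enrollment_fractions = jig(s$enrollment_fractions, cap1 = TRUE),
    costs = co, services = sv, events = ev,
    sensitivity_factors = s$sensitivity_factors
  )
}
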