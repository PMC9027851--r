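#' Per-visit rate of an avoided healthcare service
#'
#' Rates transfer from the source utilization study as avoided services per
#' CMM encounter: avoided count (optionally adjusted downward) divided by
#' the study's total encounters. Rates are kept at full precision; the
#' 3-decimal printed values are display rounding.
#'
#' @param avoided services avoided in the source study.
#' @param adjustment fraction of the source count retained (default 1;
#'   0.7 for clinic outpatient visits, since pharmacists in Croatia cannot
#'   prescribe and a share of GP contacts remains necessary).
#' @param encounters total CMM encounters in the source study (> 0).
#' @return avoided services per visit, unrounded.
#' @examples
#' service_rate(10313, 0.7, 33706)  # 0.21418...
#' @export
service_rate <- function(avoided, adjustment = 1, encounters = 33706) {
  if (any(encounters <= 0)) fail("service_rate: encounters must be > 0")
  if (any(adjustment < 0 | adjustment > 1))
    fail("service_rate: adjustment must be in [0,1]")
  avoided * adjustment / encounters
}

#' Savings from one avoided-service category
#'
#' @param rate avoided services per visit.
#' @param visits annual CMM visits.
#' @param unit_price EUR per service (DRG-based).
#' @return EUR, unrounded.
#' @examples
#' avoided_service_savings(277 / 33706, 65083.4, 47.19)
#' @export
avoided_service_savings <- function(rate, visits, unit_price) {
  if (any(rate < 0) || any(visits < 0) || any(unit_price < 0))
    fail("avoided_service_savings: inputs must be >= 0")
  rate * visits * unit_price
}

#' Utilization-savings ledger
#'
#' Prices every avoided-service category in every year: per-visit rate x
#' annual visits x unit price. Yearly and grand totals are sums of the
#' unrounded cells.
#'
#' @param scenario a [cmm_scenario].
#' @param projection result of [enrollment_projection()]; computed when
#'   omitted.
#' @param rate_scale multiplier applied to every service rate (sensitivity
#'   analysis; default 1).
#' @return data frame, one row per service (plus \code{"Total"}), one
#'   column per year plus \code{total}; values EUR unrounded. The
#'   per-visit rates are attached as column \code{rate}.
#' @examples
#' utilization_ledger(croatia_scenario())
#' @export
utilization_ledger <- function(scenario,
                               projection = enrollment_projection(scenario),
                               rate_scale = 1) {
  sv <- scenario$services
  visits <- annual_visits(proj_total(projection),
                          scenario$costs$visits_per_patient_year)
  rates <- service_rate(sv$avoided_count, sv$adjustment, sv$encounters_base) *
    rate_scale
  cells <- outer(rates * sv$unit_price, visits)  # services x years
  colnames(cells) <- as.character(scenario$years)
  out <- data.frame(service = sv$name, rate = rates, cells,
                    total = rowSums(cells),
                    check.names = FALSE, stringsAsFactors = FALSE)
  tot <- data.frame(service = "Total", rate = NA_real_,
                    t(colSums(cells)), total = sum(cells),
                    check.names = FALSE, stringsAsFactors = FALSE)
  rbind(out, tot)
}
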