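#' Annual CMM patient visits
#'
#' @param enrolled_unrounded enrolled patients (unrounded).
#' @param visits_per_patient visits per patient per year.
#' @return unrounded visit count.
#' @examples
#' annual_visits(32541.7, 2)
#' @export
annual_visits <- function(enrolled_unrounded, visits_per_patient) {
  if (any(enrolled_unrounded < 0) || any(visits_per_patient < 0))
    fail("annual_visits: inputs must be >= 0")
  enrolled_unrounded * visits_per_patient
}

#' Pharmacist workload and headcount
#'
#' Full-time-equivalent pharmacist need is annual visits divided by the
#' annual per-pharmacist visit capacity; the headcount is the half-up
#' rounded FTE.
#'
#' @param visits annual visits.
#' @param capacity visits per pharmacist per year (> 0).
#' @return list with \code{fte} (unrounded) and \code{headcount} (integer).
#' @examples
#' pharmacist_fte(119504.88, 2904)  # fte 41.15, headcount 41
#' @export
pharmacist_fte <- function(visits, capacity) {
  if (any(capacity <= 0)) fail("pharmacist_fte: capacity must be > 0")
  fte <- visits / capacity
  list(fte = fte, headcount = as.integer(round_half_up(fte)))
}

#' Pharmacist labour cost
#'
#' In \code{published_tables} mode labour is priced on the unrounded FTE
#' (this reproduces the printed cost cells to the euro); in
#' \code{as_stated} mode it is priced on the integer headcount.
#'
#' @param fte unrounded full-time equivalents.
#' @param annual_cost EUR per pharmacist-year (salary plus attributed
#'   administrative support).
#' @param mode \code{"published_tables"} or \code{"as_stated"}.
#' @param headcount integer headcount (required for \code{as_stated}).
#' @return EUR.
#' @examples
#' labour_cost(22.41164, 28000)
#' @export
labour_cost <- function(fte, annual_cost, mode = "published_tables",
                        headcount = round_half_up(fte)) {
  if (any(fte < 0) || any(annual_cost < 0)) fail("labour_cost: inputs must be >= 0")
  if (mode == "published_tables") fte * annual_cost else headcount * annual_cost
}

#' One-off training cost for newly hired pharmacists
#'
#' @param new_headcount pharmacists hired this year (headcount difference
#'   from the previous year, floored at 0).
#' @param unit_cost EUR per trained pharmacist.
#' @return EUR.
#' @examples
#' training_cost(22, 200)
#' @export
training_cost <- function(new_headcount, unit_cost) {
  if (any(new_headcount < 0) || any(unit_cost < 0))
    fail("training_cost: inputs must be >= 0")
  new_headcount * unit_cost
}

#' Therapy-modification cost
#'
#' CMM typically resolves drug-therapy problems by adding therapy or
#' raising subtherapeutic doses, which increases medication spending; this
#' enters the model as a per-patient-year cost.
#'
#' @param enrolled_unrounded enrolled patients (unrounded).
#' @param per_patient_year EUR per patient per year.
#' @return EUR.
#' @examples
#' therapy_cost(32541.7, 37.4733)
#' @export
therapy_cost <- function(enrolled_unrounded, per_patient_year) {
  if (any(enrolled_unrounded < 0) || any(per_patient_year < 0))
    fail("therapy_cost: inputs must be >= 0")
  enrolled_unrounded * per_patient_year
}

#' Yearly direct-cost ledger of the CMM intervention
#'
#' Combines visits, pharmacist FTE/headcount, labour, training and
#' therapy-modification costs per year. In \code{published_tables} mode
#' labour is unrounded FTE x annual cost and training is folded into the
#' labour term (no separate charge); in \code{as_stated} mode fixed
#' per-year labour/training totals are used verbatim when the scenario
#' provides them, otherwise headcount x annual cost and new-hires x unit
#' training cost.
#'
#' @param scenario a [cmm_scenario].
#' @param projection result of [enrollment_projection()]; computed when
#'   omitted.
#' @return data frame with one row per year (plus a \code{"Total"} row):
#'   \code{visits}, \code{fte}, \code{headcount}, \code{new_hires},
#'   \code{labour_cost}, \code{training_cost}, \code{therapy_cost},
#'   \code{total_cost}, all EUR unrounded.
#' @examples
#' cost_ledger(croatia_scenario())
#' @export
cost_ledger <- function(scenario, projection = enrollment_projection(scenario)) {
  co <- scenario$costs
  enrolled <- proj_total(projection)
  visits <- annual_visits(enrolled, co$visits_per_patient_year)
  ph <- pharmacist_fte(visits, co$visit_capacity_per_pharmacist_year)
  new_hires <- pmax(ph$headcount - c(0L, ph$headcount[-length(ph$headcount)]), 0L)

  if (scenario$mode == "published_tables") {
    lab <- labour_cost(ph$fte, co$annual_cost_per_pharmacist, "published_tables")
    trn <- rep(0, length(lab))
  } else {
    lab <- if (!is.null(co$fixed_labour_costs)) as.numeric(co$fixed_labour_costs)
           else labour_cost(ph$fte, co$annual_cost_per_pharmacist, "as_stated",
                            ph$headcount)
    trn <- if (!is.null(co$fixed_training_costs)) as.numeric(co$fixed_training_costs)
           else training_cost(new_hires, co$training_cost_per_pharmacist)
  }
  thr <- therapy_cost(enrolled, co$therapy_cost_per_patient_year)

  out <- data.frame(
    year = as.character(scenario$years), visits = visits, fte = ph$fte,
    headcount = ph$headcount, new_hires = new_hires,
    labour_cost = lab, training_cost = trn, therapy_cost = thr,
    total_cost = lab + trn + thr, stringsAsFactors = FALSE
  )
  tot <- data.frame(
    year = "Total", visits = sum(visits), fte = sum(ph$fte),
    headcount = NA_integer_, new_hires = sum(new_hires),
    labour_cost = sum(lab), training_cost = sum(trn),
    therapy_cost = sum(thr), total_cost = sum(lab + trn + thr),
    stringsAsFactors = FALSE
  )
  rbind(out, tot)
}
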