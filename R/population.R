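#' Project a count forward under constant yearly growth
#'
#' Year 1 equals the base count; each later year multiplies the previous
#' (unrounded) value by \code{1 + growth_rate}. Values are never rounded
#' internally; rounding is a display concern.
#'
#' @param base first-year count (>= 0).
#' @param growth_rate yearly growth as a fraction (0.01 = 1%).
#' @param n_years number of years (>= 1).
#' @return numeric vector of length \code{n_years}, unrounded.
#' @examples
#' grow_counts(240398, 0.01, 3)  # 240398.0 242802.0 245230.0
#' @export
grow_counts <- function(base, growth_rate, n_years) {
  if (!is_count(base) || base < 0) fail("grow_counts: base must be a count >= 0")
  if (!is_count(n_years) || n_years < 1) fail("grow_counts: n_years must be >= 1")
  out <- numeric(n_years)
  out[1] <- base
  for (k in seq_len(n_years - 1L)) out[k + 1L] <- out[k] * (1 + growth_rate)
  out
}

#' Split the on-medication population into disease groups
#'
#' The overlap correction assumes every patient with type 2 diabetes also
#' has an established cardiovascular disease, so the DMT2+CVD group equals
#' the DMT2-on-medication count and the CVD-only group is the remainder.
#'
#' @param dmt2_on_med DMT2 patients on medication.
#' @param combined_on_med all DMT2+CVD patients on medication
#'   (overlap-corrected total); must be >= \code{dmt2_on_med}.
#' @return named list with components \code{dmt2_cvd} and \code{cvd_only}.
#' @examples
#' split_overlap(240398, 765687)
#' @export
split_overlap <- function(dmt2_on_med, combined_on_med) {
  if (any(combined_on_med < dmt2_on_med))
    fail("split_overlap: combined_on_med must be >= dmt2_on_med")
  list(dmt2_cvd = dmt2_on_med, cvd_only = combined_on_med - dmt2_on_med)
}

#' Apply the polypharmacy filter to on-medication counts
#'
#' Only patients taking five or more medicines daily are CMM-eligible.
#'
#' @param on_medication numeric vector (or matrix) of on-medication counts.
#' @param polypharmacy_fraction share on 5+ medicines, in \eqn{[0,1]}.
#' @return unrounded eligible counts, same shape as the input.
#' @examples
#' eligible_counts(765687, 0.85)  # 650833.95
#' @export
eligible_counts <- function(on_medication, polypharmacy_fraction) {
  if (polypharmacy_fraction < 0 || polypharmacy_fraction > 1)
    fail("eligible_counts: polypharmacy_fraction must be in [0,1]")
  on_medication * polypharmacy_fraction
}

#' Apply the yearly enrollment schedule to eligible counts
#'
#' @param eligible numeric vector of unrounded eligible counts, one per year.
#' @param enrollment_fractions per-year fractions in \eqn{[0,1]}.
#' @return list with \code{unrounded} and \code{rounded} (half-up) enrolled
#'   counts. Downstream cost computations consume the unrounded values;
#'   rounded counts are display headcounts only.
#' @examples
#' enrolled_counts(c(650833.95, 657342.29), c(0.05, 0.07))
#' @export
enrolled_counts <- function(eligible, enrollment_fractions) {
  if (any(enrollment_fractions < 0 | enrollment_fractions > 1))
    fail("enrolled_counts: enrollment_fractions must be in [0,1]")
  u <- eligible * enrollment_fractions
  list(unrounded = u, rounded = round_half_up(u))
}

#' Per-year, per-group enrollment projection
#'
#' Runs the full population pipeline for a scenario: growth projection of
#' the on-medication counts, overlap split into the DMT2+CVD and CVD-only
#' groups, polypharmacy filter, and the enrollment schedule.
#'
#' @param scenario a [cmm_scenario].
#' @return data frame with one row per year and group
#'   (\code{"DMT2+CVD"}, \code{"CVD"}) plus a \code{"Total"} row per year;
#'   columns \code{year}, \code{group}, \code{on_medication},
#'   \code{eligible}, \code{enrolled} (all unrounded) and
#'   \code{enrolled_rounded}.
#' @examples
#' enrollment_projection(croatia_scenario())
#' @export
enrollment_projection <- function(scenario) {
  stopifnot(inherits(scenario, "cmm_scenario"))
  p <- scenario$population
  n <- length(scenario$years)
  dmt2 <- grow_counts(p$dmt2_on_medication, p$growth_rate, n)
  comb <- grow_counts(p$combined_on_medication, p$growth_rate, n)
  groups <- split_overlap(dmt2, comb)
  onmed <- rbind(`DMT2+CVD` = groups$dmt2_cvd, CVD = groups$cvd_only)
  elig <- eligible_counts(onmed, p$polypharmacy_fraction)
  proj <- do.call(rbind, lapply(seq_len(n), function(y) {
    enr <- enrolled_counts(elig[, y], scenario$enrollment_fractions[y])
    tot_enr <- enrolled_counts(sum(elig[, y]), scenario$enrollment_fractions[y])
    data.frame(
      year = scenario$years[y],
      group = c(rownames(onmed), "Total"),
      on_medication = c(onmed[, y], sum(onmed[, y])),
      eligible = c(elig[, y], sum(elig[, y])),
      enrolled = c(enr$unrounded, tot_enr$unrounded),
      enrolled_rounded = c(enr$rounded, tot_enr$rounded),
      stringsAsFactors = FALSE, row.names = NULL
    )
  }))
  class(proj) <- c("cmm_projection", "data.frame")
  proj
}

# convenience extractors used by the ledgers
proj_total <- function(projection, column = "enrolled") {
  projection[projection$group == "Total", column]
}
proj_group <- function(projection, group, column = "enrolled") {
  projection[projection$group == group, column]
}
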