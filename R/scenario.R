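#' Construct a CMM budget-impact scenario
#'
#' A scenario bundles every parameter of one model run: the horizon, the
#' on-medication population and its growth, the enrollment schedule, the
#' intervention cost parameters, the avoided-service catalogue, the
#' clinical-event catalogue and the sensitivity factors. It is the single
#' input to [bia()].
#'
#' Two parameter modes are supported. \code{"published_tables"} is the
#' replication mode: it may carry per-event overrides of the effective risk
#' reduction or the unit cost where the printed parameter tables of the
#' source material are internally inconsistent with the printed result
#' tables. \code{"as_stated"} uses the parameter tables literally, with no
#' overrides, and may instead carry fixed per-year labour/training totals.
#'
#' @param label short human-readable scenario name.
#' @param years integer vector of strictly increasing year labels.
#' @param mode \code{"published_tables"} or \code{"as_stated"}.
#' @param population named list: \code{dmt2_on_medication} (patients with
#'   type 2 diabetes on medication, first year), \code{combined_on_medication}
#'   (all DMT2+CVD patients on medication, overlap-corrected),
#'   \code{growth_rate} (yearly prevalence growth, fraction),
#'   \code{polypharmacy_fraction} (share on five or more medicines),
#'   and optionally \code{provenance} (free-form documentation fields,
#'   never computed on).
#' @param enrollment_fractions numeric vector, one entry per year, each in
#'   \eqn{[0,1]}: the share of eligible patients enrolled in CMM that year.
#' @param costs named list: \code{visits_per_patient_year},
#'   \code{visit_capacity_per_pharmacist_year}, \code{annual_cost_per_pharmacist}
#'   (EUR, salary incl. attributed administrative support),
#'   \code{training_cost_per_pharmacist} (EUR, one-off),
#'   \code{therapy_cost_per_patient_year} (EUR, added medication cost), and
#'   optionally \code{fixed_labour_costs} / \code{fixed_training_costs}
#'   (per-year EUR totals used verbatim in \code{as_stated} mode).
#' @param services data frame of avoided healthcare services with columns
#'   \code{name}, \code{avoided_count} (events in the source utilization
#'   study), \code{adjustment} (fraction of the source count retained,
#'   default 1), \code{encounters_base} (CMM encounters in the source
#'   study), \code{unit_price} (EUR, DRG-based).
#' @param events data frame of unwanted clinical events with columns
#'   \code{event}, \code{group} (\code{"DMT2+CVD"} or \code{"CVD"}),
#'   \code{incidence_per_1000}, \code{guideline_risk_reduction} (relative
#'   risk reduction when the blood-pressure target is met),
#'   \code{efficiency} (achieved fraction of the target effect, default 0.9),
#'   \code{inpatient_cost}, \code{followup_cost}, \code{device_cost} (EUR),
#'   and optional \code{override_risk_reduction}, \code{override_unit_cost}
#'   (NA where not overridden; only populated in \code{published_tables}
#'   mode).
#' @param sensitivity_factors positive multipliers applied to both savings-side
#'   rate families in the sensitivity scan.
#' @return an object of class \code{cmm_scenario}.
#' @seealso [croatia_scenario()], [validate_scenario()], [read_scenario()],
#'   [random_scenario()]
#' @export
cmm_scenario <- function(label, years, mode = c("published_tables", "as_stated"),
                         population, enrollment_fractions, costs,
                         services, events,
                         sensitivity_factors = c(1.05, 0.95, 0.8, 0.6)) {
  mode <- match.arg(mode)
  s <- structure(list(
    label = as.character(label)[1],
    years = as.integer(years),
    mode = mode,
    population = apply_defaults(population, population_defaults()),
    enrollment_fractions = as.numeric(enrollment_fractions),
    costs = coerce_fixed(apply_defaults(costs, cost_defaults(mode))),
    services = normalize_services(services),
    events = normalize_events(events),
    sensitivity_factors = as.numeric(sensitivity_factors)
  ), class = "cmm_scenario")
  v <- validate_scenario(s)
  if (length(v)) fail("invalid scenario:\n", paste0("  - ", v, collapse = "\n"))
  s
}

population_defaults <- function() {
  list(dmt2_on_medication = NULL, combined_on_medication = NULL,
       growth_rate = NULL, polypharmacy_fraction = NULL, provenance = NULL)
}

# per-year fixed cost vectors may arrive as lists from JSON documents
coerce_fixed <- function(co) {
  for (f in c("fixed_labour_costs", "fixed_training_costs"))
    if (!is.null(co[[f]])) co[[f]] <- as.numeric(unlist(co[[f]]))
  co
}

cost_defaults <- function(mode) {
  list(visits_per_patient_year = 2,
       visit_capacity_per_pharmacist_year = 2904,
       annual_cost_per_pharmacist = 28000,
       training_cost_per_pharmacist = 200,
       therapy_cost_per_patient_year =
         if (mode == "published_tables") 37.4733 else 37.47,
       fixed_labour_costs = NULL,
       fixed_training_costs = NULL)
}

# fill defaults; keep user values; refuse unknown keys later in validation
apply_defaults <- function(x, defaults) {
  if (is.null(x)) x <- list()
  out <- defaults
  # out[k] <- list(v) keeps NULL-valued components instead of deleting them;
  # unknown keys are retained so validation can name them
  for (k in names(x)) out[k] <- list(x[[k]])
  out
}

service_columns <- c("name", "avoided_count", "adjustment", "encounters_base",
                     "unit_price")

normalize_services <- function(services) {
  df <- as.data.frame(services, stringsAsFactors = FALSE)
  df$adjustment <- fill_default(df$adjustment, 1, nrow(df))
  df$encounters_base <- fill_default(df$encounters_base, 33706, nrow(df))
  df
}

# absent or NA entries take the documented default
fill_default <- function(x, default, n) {
  if (is.null(x)) return(rep(default, n))
  x <- as.numeric(x)
  x[is.na(x)] <- default
  x
}

event_columns <- c("event", "group", "incidence_per_1000",
                   "guideline_risk_reduction", "efficiency",
                   "inpatient_cost", "followup_cost", "device_cost",
                   "override_risk_reduction", "override_unit_cost")

normalize_events <- function(events) {
  df <- as.data.frame(events, stringsAsFactors = FALSE)
  df$efficiency <- fill_default(df$efficiency, 0.9, nrow(df))
  df$device_cost <- fill_default(df$device_cost, 0, nrow(df))
  if (is.null(df$override_risk_reduction)) df$override_risk_reduction <- NA_real_
  if (is.null(df$override_unit_cost)) df$override_unit_cost <- NA_real_
  df$override_risk_reduction <- as.numeric(df$override_risk_reduction)
  df$override_unit_cost <- as.numeric(df$override_unit_cost)
  df
}

#' Validate a scenario against the model's invariants
#'
#' Checks every structural and range invariant of the scenario data model.
#' Violations are returned as data, not thrown: each element names the
#' field, the rule and the observed value.
#'
#' @param s a [cmm_scenario] (or a bare list with the same shape).
#' @return character vector of violations; empty when the scenario is valid.
#' @examples
#' validate_scenario(croatia_scenario())  # character(0)
#' @export
validate_scenario <- function(s) {
  v <- character(0)
  chk <- function(cond, msg, ...) {
    if (!isTRUE(cond)) v <<- c(v, sprintf(msg, ...))
    invisible(NULL)
  }

  v <- c(v, unknown_keys(s, c("label", "years", "mode", "population",
                              "enrollment_fractions", "costs", "services",
                              "events", "sensitivity_factors"), "scenario"))

  chk(is.character(s$label) && length(s$label) == 1L, "label: must be a single string")
  chk(length(s$years) >= 1L, "years: must be nonempty")
  if (length(s$years) > 1L)
    chk(all(diff(s$years) > 0), "years: must be strictly increasing (observed %s)",
        paste(s$years, collapse = ", "))
  chk(s$mode %in% c("published_tables", "as_stated"),
      "mode: must be 'published_tables' or 'as_stated' (observed '%s')", s$mode)

  p <- s$population
  v <- c(v, unknown_keys(p, names(population_defaults()), "population"))
  chk(is_count(p$dmt2_on_medication) && p$dmt2_on_medication >= 0,
      "population.dmt2_on_medication: must be a count >= 0")
  chk(is_count(p$combined_on_medication) && p$combined_on_medication >= 0,
      "population.combined_on_medication: must be a count >= 0")
  if (is_count(p$dmt2_on_medication) && is_count(p$combined_on_medication))
    chk(p$combined_on_medication >= p$dmt2_on_medication,
        "population: combined_on_medication (%s) must be >= dmt2_on_medication (%s)",
        p$combined_on_medication, p$dmt2_on_medication)
  chk(is_count(p$growth_rate) && p$growth_rate > -1,
      "population.growth_rate: must be a number > -1")
  chk(is_count(p$polypharmacy_fraction) &&
        p$polypharmacy_fraction >= 0 && p$polypharmacy_fraction <= 1,
      "population.polypharmacy_fraction: must be in [0,1] (observed %s)",
      format(p$polypharmacy_fraction))

  ef <- s$enrollment_fractions
  chk(length(ef) == length(s$years),
      "enrollment_fractions: need one entry per year (%d != %d)",
      length(ef), length(s$years))
  chk(all(is.finite(ef)) && all(ef >= 0 & ef <= 1),
      "enrollment_fractions: each must be in [0,1] (observed %s)",
      paste(format(ef), collapse = ", "))

  co <- s$costs
  v <- c(v, unknown_keys(co, names(cost_defaults("as_stated")), "costs"))
  for (f in c("visits_per_patient_year", "visit_capacity_per_pharmacist_year",
              "annual_cost_per_pharmacist", "training_cost_per_pharmacist",
              "therapy_cost_per_patient_year"))
    chk(is_count(co[[f]]) && co[[f]] > 0, "costs.%s: must be > 0", f)
  for (f in c("fixed_labour_costs", "fixed_training_costs"))
    if (!is.null(co[[f]]))
      chk(length(co[[f]]) == length(s$years) && all(co[[f]] >= 0),
          "costs.%s: must have one value >= 0 per year", f)

  sv <- s$services
  v <- c(v, unknown_keys(sv, service_columns, "services"))
  if (nrow(sv) > 0) {
    chk(all(sv$avoided_count >= 0), "services.avoided_count: must be >= 0")
    chk(all(sv$adjustment >= 0 & sv$adjustment <= 1),
        "services.adjustment: must be in [0,1]")
    chk(all(sv$encounters_base > 0), "services.encounters_base: must be > 0")
    chk(all(sv$unit_price >= 0), "services.unit_price: must be >= 0")
    r <- sv$avoided_count * sv$adjustment / sv$encounters_base
    chk(all(r >= 0 & r <= 1), "services: implied per-visit rate outside [0,1]")
  }

  ev <- s$events
  v <- c(v, unknown_keys(ev, event_columns, "events"))
  if (nrow(ev) > 0) {
    chk(all(ev$group %in% c("DMT2+CVD", "CVD")),
        "events.group: must be 'DMT2+CVD' or 'CVD'")
    chk(all(ev$incidence_per_1000 >= 0), "events.incidence_per_1000: must be >= 0")
    chk(all(ev$guideline_risk_reduction >= 0 & ev$guideline_risk_reduction <= 1),
        "events.guideline_risk_reduction: must be in [0,1]")
    chk(all(ev$efficiency >= 0 & ev$efficiency <= 1),
        "events.efficiency: must be in [0,1]")
    for (f in c("inpatient_cost", "followup_cost", "device_cost"))
      chk(all(ev[[f]] >= 0), "events.%s: must be >= 0", f)
    has_ov <- any(!is.na(ev$override_risk_reduction)) ||
      any(!is.na(ev$override_unit_cost))
    if (has_ov)
      chk(identical(s$mode, "published_tables"),
          "events: overrides may only be populated in published_tables mode")
  }

  chk(all(is.finite(s$sensitivity_factors)) && all(s$sensitivity_factors > 0),
      "sensitivity_factors: must all be > 0")
  v
}

#' @export
print.cmm_scenario <- function(x, ...) {
  cat("CMM budget-impact scenario: ", x$label, "\n", sep = "")
  cat("  mode:    ", x$mode, "\n", sep = "")
  cat("  horizon: ", paste(range(x$years), collapse = "-"),
      " (", length(x$years), " years)\n", sep = "")
  cat("  population: ", format(x$population$combined_on_medication, big.mark = ","),
      " on medication (", format(x$population$dmt2_on_medication, big.mark = ","),
      " DMT2), growth ", 100 * x$population$growth_rate, "%/yr, ",
      100 * x$population$polypharmacy_fraction, "% on 5+ medicines\n", sep = "")
  cat("  enrollment: ", paste(sprintf("%g%%", 100 * x$enrollment_fractions),
                              collapse = ", "), "\n", sep = "")
  cat("  catalogue: ", nrow(x$services), " avoided services, ",
      nrow(x$events), " clinical event specs\n", sep = "")
  invisible(x)
}

# ---- document I/O ---------------------------------------------------------

scenario_to_list <- function(s) {
  out <- unclass(s)
  out$services <- lapply(seq_len(nrow(s$services)), function(i)
    as.list(s$services[i, , drop = FALSE]))
  out$events <- lapply(seq_len(nrow(s$events)), function(i) {
    e <- as.list(s$events[i, , drop = FALSE])
    # NA overrides are absent fields in the document form
    if (is.na(e$override_risk_reduction)) e$override_risk_reduction <- NULL
    if (is.na(e$override_unit_cost)) e$override_unit_cost <- NULL
    e
  })
  out$population <- Filter(Negate(is.null), out$population)
  out$costs <- Filter(Negate(is.null), out$costs)
  out
}

scenario_from_list <- function(x) {
  need <- c("label", "years", "mode", "population", "enrollment_fractions",
            "costs", "services", "events")
  miss <- setdiff(need, names(x))
  if (length(miss)) fail("scenario document: missing field(s) ",
                         paste(miss, collapse = ", "))
  bad <- setdiff(names(x), c(need, "sensitivity_factors"))
  if (length(bad)) fail("scenario document: unknown field(s) ",
                        paste(bad, collapse = ", "))
  rowbind <- function(recs, cols) {
    if (length(recs) == 0)
      return(as.data.frame(setNames(lapply(cols, function(k)
        if (k %in% c("name", "event", "group")) character(0) else numeric(0)),
        cols), stringsAsFactors = FALSE))
    do.call(rbind, lapply(recs, function(r) {
      extra <- setdiff(names(r), cols)
      if (length(extra)) fail("scenario document: unknown field(s) ",
                              paste(extra, collapse = ", "), " in record '",
                              r[[1]], "'")
      for (k in setdiff(cols, names(r))) r[[k]] <- NA
      as.data.frame(r[cols], stringsAsFactors = FALSE)
    }))
  }
  cmm_scenario(
    label = x$label, years = unlist(x$years), mode = x$mode,
    population = x$population,
    enrollment_fractions = unlist(x$enrollment_fractions),
    costs = x$costs,
    services = normalize_services(rowbind(x$services, service_columns)),
    events = normalize_events(rowbind(x$events, event_columns)),
    sensitivity_factors =
      if (is.null(x$sensitivity_factors)) c(1.05, 0.95, 0.8, 0.6)
      else unlist(x$sensitivity_factors)
  )
}

#' Read and write scenario documents
#'
#' Scenario documents are YAML (canonical) or JSON (accepted); the format is
#' chosen by file extension. Documents are validated on read: unknown keys
#' and invariant violations are errors, so parameter typos fail fast.
#' `write_scenario()` followed by `read_scenario()` reproduces the scenario
#' (numeric values round-trip at full double precision).
#'
#' @param path file path; extension \code{.yaml}/\code{.yml} or \code{.json}.
#' @param s a [cmm_scenario].
#' @return `read_scenario()` returns a validated [cmm_scenario];
#'   `write_scenario()` returns `path` invisibly.
#' @examples
#' p <- tempfile(fileext = ".yaml")
#' write_scenario(croatia_scenario(), p)
#' identical_fields <- all.equal(read_scenario(p), croatia_scenario())
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) fail("scenario file not found: ", path)
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
             error = function(e) fail("JSON parse error in ", path, ": ",
                                      conditionMessage(e)))
  } else {
    tryCatch(yaml::read_yaml(path),
             error = function(e) fail("YAML parse error in ", path, ": ",
                                      conditionMessage(e)))
  }
  scenario_from_list(x)
}

#' @rdname read_scenario
#' @export
write_scenario <- function(s, path) {
  stopifnot(inherits(s, "cmm_scenario"))
  x <- scenario_to_list(s)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    writeLines(yaml::as.yaml(x, precision = 17), path)
  }
  invisible(path)
}
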