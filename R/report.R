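# CSV report emission and run comparison. Cells store full precision;
# separate *_display columns carry the printed-style rounding (integer EUR,
# 2-decimal per-patient figures, 3-decimal rates, 5-decimal risks) so
# replication checks never round twice.

#' Write all result tables of a model run as CSV
#'
#' Emits one UTF-8 CSV ('.' decimal separator) per result table —
#' population projection, direct costs, utilization savings, event
#' savings, avoided events, sensitivity — plus a one-row summary and a
#' JSON run manifest listing every emitted file with its checksum.
#'
#' @param fit a [bia()] result.
#' @param dir output directory (created if missing).
#' @return the manifest as a list, invisibly.
#' @examples
#' fit <- bia(croatia_scenario())
#' out <- write_bia_tables(fit, tempfile("run"))
#' @export
write_bia_tables <- function(fit, dir) {
  stopifnot(inherits(fit, "cmm_bia"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  emit <- function(df, file) {
    path <- file.path(dir, file)
    utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8",
                     quote = FALSE)
    path
  }

  proj <- fit$projection
  proj$on_medication_display <- round_half_up(proj$on_medication)
  proj$eligible_display <- round_half_up(proj$eligible)
  files <- emit(proj, "table02_population.csv")

  costs <- fit$costs
  for (col in c("labour_cost", "training_cost", "therapy_cost", "total_cost"))
    costs[[paste0(col, "_display")]] <- round_half_up(costs[[col]])
  files <- c(files, emit(costs, "table09_costs.csv"))

  util <- fit$utilization
  util$rate_display <- round_half_up(util$rate, 3)
  for (col in c(as.character(fit$scenario$years), "total"))
    util[[paste0(col, "_display")]] <- round_half_up(util[[col]])
  files <- c(files, emit(util, "table10_utilization.csv"))

  ev <- fit$events
  ev$mode <- fit$scenario$mode
  ev$risk_reduction_display <- round_half_up(ev$risk_reduction, 5)
  ev$savings_display <- round_half_up(ev$savings)
  files <- c(files, emit(ev[, c("mode", setdiff(names(ev), "mode"))],
                         "table11_event_savings.csv"))

  av <- event_cells(fit$events)[, c("event", "group", "year",
                                    "expected_events", "avoided_rounded")]
  av$mode <- fit$scenario$mode
  files <- c(files, emit(av[, c("mode", "event", "group", "year",
                                "expected_events", "avoided_rounded")],
                         "table12_avoided_events.csv"))

  sens <- fit$sensitivity
  sens$budget_impact_display <- round_half_up(sens$budget_impact)
  files <- c(files, emit(sens, "table13_sensitivity.csv"))

  t <- fit$totals
  summary_df <- data.frame(
    total_costs = t$total_costs,
    total_utilization_savings = t$total_utilization_savings,
    total_event_savings = t$total_event_savings,
    total_savings = t$total_savings,
    budget_impact = t$budget_impact,
    avoided_events_total = t$avoided_events_total,
    enrolled_total = fit$per_patient$enrolled_total,
    cost_per_patient_year = fit$per_patient$cost_per_patient_year,
    cost_per_patient_year_display = fit$per_patient$cost_per_patient_year_display,
    incremental_cost_per_patient = fit$per_patient$incremental_cost_per_patient,
    incremental_cost_per_patient_display =
      fit$per_patient$incremental_cost_per_patient_display,
    breakeven_factor = fit$breakeven_factor
  )
  files <- c(files, emit(summary_df, "summary.csv"))

  scen_path <- file.path(dir, "scenario.yaml")
  write_scenario(fit$scenario, scen_path)
  manifest <- list(
    scenario_label = fit$scenario$label,
    mode = fit$scenario$mode,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("cmmbia")),
    input_checksum = unname(tools::md5sum(scen_path)),
    files = data.frame(file = basename(c(files, scen_path)),
                       md5 = unname(tools::md5sum(c(files, scen_path))),
                       stringsAsFactors = FALSE)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Load, validate, run and report in one call
#'
#' The batch entry point: loads a scenario document (or takes a scenario
#' object), optionally switches the parameter mode, runs [bia()] and
#' writes all report tables to \code{dir}.
#'
#' @param scenario a [cmm_scenario] or a path to a scenario document.
#' @param dir output directory.
#' @param mode optional mode override (\code{"published_tables"} or
#'   \code{"as_stated"}); only meaningful for the built-in scenario names.
#' @return the [bia()] fit, invisibly; tables and manifest are written to
#'   \code{dir}.
#' @export
run_bia <- function(scenario, dir, mode = NULL) {
  if (is.character(scenario)) {
    scenario <- if (identical(scenario, "croatia"))
      croatia_scenario(if (is.null(mode)) "published_tables" else mode)
    else read_scenario(scenario)
  }
  fit <- bia(scenario)
  write_bia_tables(fit, dir)
  invisible(fit)
}

#' Cell-wise comparison of two report directories
#'
#' Reads every CSV common to both directories and reports per-cell
#' absolute and relative differences of the numeric columns, flagging
#' cells whose absolute difference exceeds \code{threshold}.
#'
#' @param dir_a,dir_b report directories written by [write_bia_tables()].
#' @param threshold absolute-difference flag level (default 0: every
#'   differing cell is flagged).
#' @return data frame with columns \code{file}, \code{row}, \code{column},
#'   \code{a}, \code{b}, \code{abs_diff}, \code{rel_diff}, \code{flagged};
#'   zero rows when the runs are numerically identical.
#' @export
compare_runs <- function(dir_a, dir_b, threshold = 0) {
  csvs <- intersect(list.files(dir_a, pattern = "\\.csv$"),
                    list.files(dir_b, pattern = "\\.csv$"))
  if (length(csvs) == 0) fail("compare_runs: no common CSV files")
  out <- lapply(csvs, function(f) {
    a <- utils::read.csv(file.path(dir_a, f), stringsAsFactors = FALSE)
    b <- utils::read.csv(file.path(dir_b, f), stringsAsFactors = FALSE)
    if (!identical(dim(a), dim(b)) || !identical(names(a), names(b)))
      fail("compare_runs: schema mismatch in ", f)
    num <- names(a)[vapply(a, is.numeric, logical(1))]
    cells <- lapply(num, function(col) {
      va <- a[[col]]; vb <- b[[col]]
      d <- abs(va - vb)
      diff <- which(!is.na(d) & d > 0)
      if (length(diff) == 0) return(NULL)
      data.frame(file = f, row = diff, column = col,
                 a = va[diff], b = vb[diff], abs_diff = d[diff],
                 rel_diff = d[diff] / pmax(abs(va[diff]), .Machine$double.eps),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, cells)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(file = character(0), row = integer(0),
                      column = character(0), a = numeric(0), b = numeric(0),
                      abs_diff = numeric(0), rel_diff = numeric(0))
  out$flagged <- out$abs_diff > threshold
  out[order(out$file, out$column, out$row), , drop = FALSE]
}
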