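#' Run the full co-ventilation screening and tuning protocol
#'
#' Executes the complete decision-support pipeline for pairing an index
#' patient with a co-ventilation partner and deriving shared ventilator
#' settings:
#' 1. validate the index patient's settings against the safety limits
#'    (abort on violation);
#' 2. predict the index patient's steady-state tidal volume;
#' 3. screen all candidates under the shared settings (green 6-8 mL/kg
#'    band), producing a ranked match report;
#' 4. build the R-E tidal-volume map at the index weight;
#' 5. for the top-ranked candidate, compute the ideal joint pressure,
#'    estimate the starting PIP, and tune the square-wave PIP to recover
#'    both patients' desired tidal volumes.
#'
#' Artifacts (grid CSV, match report JSON, tuning report JSON, steady-cycle
#' trace CSV) are written to `out_dir` when given; numbers in the JSON
#' reports are rounded to reporting precision (0.1 mL, 0.1 cmH2O, 0.01
#' mL/kg) so identical configurations produce byte-identical reports.
#'
#' @param cohort Named list of [patient_mechanics()] (e.g. from
#'   [read_cohort()] or [preset_cohort()]).
#' @param index_id Id of the index (already-ventilated) patient in `cohort`.
#' @param settings The index patient's [vent_settings()].
#' @param Rc Common circuit resistance for the paired stage, cmH2O.s/L.
#' @param limits [safety_limits()] used throughout.
#' @param grid_resolution Cells per axis of the R-E map (default 200).
#' @param step,pip_max Tuning step and PIP cap passed to [tune_pip()].
#' @param out_dir Output directory for artifacts, or `NULL` to skip writing.
#' @param quiet Suppress stage log messages (default `FALSE`).
#' @return Object of class `protocol_result`: list with `status`
#'   (`"ok"` or `"no-match"`), `index_vt`, `match` (a `match_report`),
#'   `grid` (an `re_grid`), and - when a partner was found - `partner_id`,
#'   `tuning` (a `tuning_result`) and `report` (a `co_mv_report`).
#' @examples
#' \donttest{
#' res <- run_protocol(preset_cohort(), "P1", preset_settings(),
#'                     grid_resolution = 50, quiet = TRUE)
#' res$partner_id
#' }
#' @export
run_protocol <- function(cohort, index_id, settings, Rc = 8,
                         limits = safety_limits(), grid_resolution = 200L,
                         step = 0.5, pip_max = NULL, out_dir = NULL,
                         quiet = FALSE) {
  say <- function(stage, fmt, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  if (!index_id %in% names(cohort))
    stop("index patient '", index_id, "' not found in cohort")
  index <- cohort[[index_id]]
  candidates <- cohort[setdiff(names(cohort), index_id)]
  if (is.null(pip_max)) pip_max <- limits$pplat_max

  say("validate", "checking index settings (PIP %g / PEEP %g, RR %g, I:E 1:%g)",
      settings$PIP, settings$PEEP, settings$RR, settings$ie_e)
  viol <- validate_settings(settings, limits)
  if (nrow(viol) > 0L) {
    msg <- paste(viol$criterion, collapse = "; ")
    stop("index settings violate safety limits: ", msg)
  }

  index_vt <- scm_tidal_volume(index, settings)
  say("scm", "index %s predicted VT %.1f mL (%.2f mL/kg)",
      index_id, 1000 * index_vt$vt_L, index_vt$vt_ml_per_kg)

  match <- screen_candidates(index, settings, candidates, limits = limits)
  n_elig <- sum(match$candidates$eligible)
  say("screen", "%d of %d candidates in the %g-%g mL/kg band",
      n_elig, nrow(match$candidates), limits$vt_min, limits$vt_max)

  grid <- build_re_grid(settings, index$weight, resolution = grid_resolution)
  say("grid", "R-E map %dx%d at %g kg", grid_resolution, grid_resolution,
      index$weight)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(round_df(as.data.frame(grid), c(VT_mlkg = 2)),
                     file.path(out_dir, "grid.csv"), row.names = FALSE)
    write_match_json(match, file.path(out_dir, "match_report.json"))
  }

  if (n_elig == 0L) {
    say("result", "no eligible partner for %s: protocol ends with no match",
        index_id)
    out <- structure(list(status = "no-match", index_vt = index_vt,
                          match = match, grid = grid),
                     class = "protocol_result")
    if (!is.null(out_dir)) write_tuning_json(NULL, file.path(out_dir, "tuning_report.json"))
    return(out)
  }

  partner_id <- match$candidates$id[which(match$candidates$rank == 1L)]
  partner <- cohort[[partner_id]]
  say("pair", "selected partner: %s (VT %.2f mL/kg)", partner_id,
      match$candidates$vt_ml_per_kg[match$candidates$id == partner_id])

  circuit <- co_vent_circuit(index, partner, Rc = Rc)
  tuning <- tune_pip(circuit, settings, step = step, pip_max = pip_max)
  say("tune", "PIP_EST %.2f -> final PIP %.1f cmH2O after %d DCM runs",
      tuning$pip_est, tuning$pip_final, tuning$iterations)
  report <- co_mv_report(tuning, circuit, limits = limits)

  if (!is.null(out_dir)) {
    write_tuning_json(report, file.path(out_dir, "tuning_report.json"))
    final_cycle <- dcm_tidal_volume(circuit, tuning$settings_final)
    write_trace_csv(final_cycle$trace, file.path(out_dir, "trace.csv"))
  }

  structure(list(status = "ok", index_vt = index_vt, match = match,
                 grid = grid, partner_id = partner_id, circuit = circuit,
                 tuning = tuning, report = report),
            class = "protocol_result")
}

#' @export
print.protocol_result <- function(x, ...) {
  cat(sprintf("<protocol_result> status: %s\n", x$status))
  print(x$match)
  if (x$status == "ok") print(x$report)
  invisible(x)
}

# round named columns of a data frame to given decimal places
round_df <- function(d, digits) {
  for (nm in names(digits)) {
    if (nm %in% names(d)) d[[nm]] <- round(d[[nm]], digits[[nm]])
  }
  d
}

write_match_json <- function(match, path) {
  tab <- match$candidates
  tab$vt_ml_per_kg <- round(tab$vt_ml_per_kg, 2)
  jsonlite::write_json(
    list(index_patient_id = match$index_patient_id,
         index_vt_ml_per_kg = round(match$index_vt_ml_per_kg, 2),
         candidates = tab),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

write_tuning_json <- function(report, path) {
  if (is.null(report)) {
    jsonlite::write_json(list(status = "no-match"), path, auto_unbox = TRUE,
                         pretty = TRUE)
    return(invisible(path))
  }
  tab <- report$patients
  for (nm in c("ideal_vt_mL", "actual_vt_mL")) tab[[nm]] <- round(tab[[nm]], 1)
  for (nm in c("ideal_vt_mlkg", "actual_vt_mlkg", "percent_error"))
    tab[[nm]] <- round(tab[[nm]], 2)
  jsonlite::write_json(
    list(status = "ok",
         pip_est = round(report$pip_est, 1),
         pip_final = round(report$pip_final, 1),
         driving_pressure = round(report$driving_pressure, 1),
         settings_final = list(PIP = report$settings_final$PIP,
                               PEEP = report$settings_final$PEEP,
                               RR = report$settings_final$RR,
                               IE = paste0("1:", report$settings_final$ie_e)),
         cap_reached = report$cap_reached,
         patients = tab,
         violations = report$violations),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}
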