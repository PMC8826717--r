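#' Read a patient cohort from JSON or YAML
#'
#' A cohort file is a list of patient objects with fields `id`, `E`
#' (cmH2O/L), `R` (cmH2O.s/L), `weight` (kg) and optional `severity`.
#' The format is chosen by file extension (`.json` vs `.yaml`/`.yml`).
#'
#' @param path Path to the cohort file.
#' @return Named list of [patient_mechanics()] objects.
#' @export
read_cohort <- function(path) {
  raw <- read_structured(path)
  if (is.data.frame(raw)) raw <- split(raw, seq_len(nrow(raw)))
  if (length(raw) == 0L) stop("cohort file contains no patients: ", path)
  pts <- lapply(seq_along(raw), function(i) {
    p <- as.list(raw[[i]])
    for (f in c("id", "E", "R", "weight")) {
      if (is.null(p[[f]]) || length(p[[f]]) != 1L || is.na(p[[f]]))
        stop(sprintf("cohort entry %d: missing or invalid field '%s'", i, f))
    }
    patient_mechanics(as.character(p$id), as.numeric(p$E), as.numeric(p$R),
                      as.numeric(p$weight),
                      severity = if (is.null(p$severity)) NA_character_
                                 else as.character(p$severity))
  })
  names(pts) <- vapply(pts, `[[`, character(1), "id")
  if (anyDuplicated(names(pts))) stop("duplicate patient ids in cohort file")
  pts
}

#' Write a patient cohort to JSON or YAML
#'
#' @param cohort List of [patient_mechanics()] objects.
#' @param path Destination path; format chosen by extension.
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(cohort, path) {
  entries <- lapply(unname(cohort), function(p) {
    e <- list(id = p$id, E = p$E, R = p$R, weight = p$weight)
    if (!is.na(p$severity)) e$severity <- p$severity
    e
  })
  write_structured(entries, path)
  invisible(path)
}

#' Read ventilator settings from JSON or YAML
#'
#' A settings object has fields `PIP`, `PEEP` (cmH2O), `RR` (breaths/min),
#' `IE` (number or `"1:e"` string) and optional `rise_time` (s).
#'
#' @param path Path to the settings file.
#' @return A [vent_settings()] object.
#' @export
read_settings <- function(path) {
  s <- as.list(read_structured(path))
  for (f in c("PIP", "PEEP", "RR", "IE")) {
    if (is.null(s[[f]]))
      stop(sprintf("settings file missing field '%s'", f))
  }
  vent_settings(as.numeric(s$PIP), as.numeric(s$PEEP), as.numeric(s$RR), s$IE,
                rise_time = if (is.null(s$rise_time)) 0 else as.numeric(s$rise_time))
}

#' Write ventilator settings to JSON or YAML
#'
#' @param settings A [vent_settings()] object.
#' @param path Destination path; format chosen by extension.
#' @return Invisibly, `path`.
#' @export
write_settings <- function(settings, path) {
  write_structured(list(PIP = settings$PIP, PEEP = settings$PEEP,
                        RR = settings$RR, IE = paste0("1:", settings$ie_e),
                        rise_time = settings$rise_time),
                   path)
  invisible(path)
}

read_structured <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    json = jsonlite::fromJSON(path, simplifyDataFrame = FALSE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop("unsupported file extension '", ext, "' (expected json/yaml/yml)")
  )
}

write_structured <- function(x, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    json = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE),
    yaml = ,
    yml = yaml::write_yaml(x, path),
    stop("unsupported file extension '", ext, "' (expected json/yaml/yml)")
  )
  invisible(path)
}

#' Write a breath waveform to CSV
#'
#' Columns `time_s,paw_cmH2O,flow_lps,vol_l`, one row per sample.
#'
#' @param waveform A [breath_waveform()].
#' @param path Destination CSV path.
#' @return Invisibly, `path`.
#' @export
write_waveform_csv <- function(waveform, path) {
  utils::write.csv(as.data.frame(waveform), path, row.names = FALSE)
  invisible(path)
}

#' Read a breath waveform from CSV
#'
#' Expects the header `time_s,paw_cmH2O,flow_lps,vol_l` (`vol_l` optional;
#' integrated from flow when absent).
#'
#' @param path CSV path.
#' @return A [breath_waveform()].
#' @export
read_waveform_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("time_s", "paw_cmH2O", "flow_lps")
  if (!all(need %in% names(d)))
    stop("waveform CSV must have columns ", paste(need, collapse = ", "))
  breath_waveform(d$time_s, d$paw_cmH2O, d$flow_lps,
                  volume = if ("vol_l" %in% names(d)) d$vol_l else NULL)
}

#' Write a co-ventilation trace to CSV
#'
#' Columns `time_s,pvent_cmH2O,pj_cmH2O,flow1_lps,flow2_lps,vol1_l,vol2_l`.
#'
#' @param trace A `co_vent_trace` from [simulate_dcm()].
#' @param path Destination CSV path.
#' @return Invisibly, `path`.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
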