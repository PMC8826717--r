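#' Patient respiratory mechanics
#'
#' Bundles the lumped single-compartment parameters of one patient's
#' respiratory system: elastance `E` (cmH2O/L, the inverse of compliance),
#' airway resistance `R` (cmH2O.s/L) and body weight (kg, used to express
#' tidal volume in mL/kg). An optional free-text severity label
#' (e.g. `"Mild"`, `"Obstructive"`) is carried along for reporting.
#'
#' @param id Patient identifier (single string).
#' @param E Respiratory system elastance, cmH2O/L. Must be positive.
#' @param R Airway resistance, cmH2O.s/L. Must be positive.
#' @param weight Body weight in kg. Must be positive.
#' @param severity Optional severity label (free text) or `NA`.
#'
#' @return An object of class `patient_mechanics`: a list with elements
#'   `id`, `E`, `R`, `weight`, `severity`.
#' @examples
#' p <- patient_mechanics("P1", E = 20, R = 10, weight = 65, severity = "Mild")
#' p$E / p$R  # inverse time constant 1/tau
#' @export
patient_mechanics <- function(id, E, R, weight, severity = NA_character_) {
  stopifnot(is.character(id), length(id) == 1L)
  if (!is.finite(E) || E <= 0) stop("elastance E must be a positive number (cmH2O/L)")
  if (!is.finite(R) || R <= 0) stop("resistance R must be a positive number (cmH2O.s/L)")
  if (!is.finite(weight) || weight <= 0) stop("weight must be a positive number (kg)")
  structure(
    list(id = id, E = as.numeric(E), R = as.numeric(R),
         weight = as.numeric(weight), severity = as.character(severity)),
    class = "patient_mechanics"
  )
}

#' @export
print.patient_mechanics <- function(x, ...) {
  cat(sprintf("<patient_mechanics> %s%s: E = %g cmH2O/L, R = %g cmH2O.s/L, weight = %g kg\n",
              x$id,
              if (is.na(x$severity)) "" else paste0(" (", x$severity, ")"),
              x$E, x$R, x$weight))
  invisible(x)
}

#' Pressure-control ventilator settings
#'
#' Defines the square pressure waveform delivered in pressure-control (PC)
#' mode: peak inspiratory pressure `PIP` and positive end-expiratory pressure
#' `PEEP` (cmH2O), respiratory rate `RR` (breaths/min) and the
#' inspiratory:expiratory time ratio `IE`. The I:E ratio is stored as the
#' expiratory multiple `e` of `1:e`; `IE` accepts either that number (e.g.
#' `2`) or a string such as `"1:2"`. An optional linear pressure ramp of
#' duration `rise_time` seconds at inspiration onset replaces the
#' instantaneous PEEP-to-PIP step.
#'
#' @param PIP Peak inspiratory pressure, cmH2O; must exceed `PEEP`.
#' @param PEEP Positive end-expiratory pressure, cmH2O; must be >= 0.
#' @param RR Respiratory rate, breaths/min; must be positive.
#' @param IE I:E ratio as the expiratory multiple `e` (numeric) or a string
#'   `"1:e"`. Must be positive.
#' @param rise_time Optional linear ramp duration at inspiration onset,
#'   seconds (default 0: ideal square wave).
#'
#' @return An object of class `vent_settings`: list with `PIP`, `PEEP`, `RR`,
#'   `ie_e` (the expiratory multiple) and `rise_time`.
#' @examples
#' vent_settings(PIP = 17, PEEP = 7, RR = 15, IE = "1:2")
#' @export
vent_settings <- function(PIP, PEEP, RR, IE = 2, rise_time = 0) {
  e <- parse_ie(IE)
  if (!is.finite(PEEP) || PEEP < 0) stop("PEEP must be >= 0 cmH2O")
  if (!is.finite(PIP) || PIP <= PEEP) stop("PIP must exceed PEEP")
  if (!is.finite(RR) || RR <= 0) stop("RR must be positive (breaths/min)")
  if (!is.finite(e) || e <= 0) stop("I:E expiratory multiple must be positive")
  if (!is.finite(rise_time) || rise_time < 0) stop("rise_time must be >= 0 s")
  Ti <- (60 / RR) / (1 + e)
  if (rise_time >= Ti) stop("rise_time must be shorter than the inspiratory time")
  structure(
    list(PIP = as.numeric(PIP), PEEP = as.numeric(PEEP), RR = as.numeric(RR),
         ie_e = as.numeric(e), rise_time = as.numeric(rise_time)),
    class = "vent_settings"
  )
}

#' @export
print.vent_settings <- function(x, ...) {
  cat(sprintf("<vent_settings> PIP %g / PEEP %g cmH2O, RR %g bpm, I:E 1:%g%s\n",
              x$PIP, x$PEEP, x$RR, x$ie_e,
              if (x$rise_time > 0) sprintf(", rise %g s", x$rise_time) else ""))
  invisible(x)
}

# "1:2" -> 2; numeric passes through
parse_ie <- function(IE) {
  if (is.character(IE)) {
    m <- regmatches(IE, regexec("^\\s*1\\s*:\\s*([0-9.]+)\\s*$", IE))[[1]]
    if (length(m) != 2L) stop("I:E string must have the form \"1:e\", e.g. \"1:2\"")
    as.numeric(m[2])
  } else {
    as.numeric(IE)
  }
}

#' Breath timing from rate and I:E ratio
#'
#' Decomposes a ventilator setting into the breath period `T = 60/RR` and the
#' inspiratory/expiratory times `Ti = T/(1+e)`, `Te = T - Ti`, where `e` is
#' the expiratory multiple of the I:E ratio `1:e`.
#'
#' @param settings A [vent_settings()] object.
#' @return Named numeric vector `c(T = , Ti = , Te = )` in seconds, with
#'   `Ti + Te == T` exactly.
#' @examples
#' breath_timing(vent_settings(17, 7, RR = 15, IE = "1:2"))
#' @export
breath_timing <- function(settings) {
  stopifnot(inherits(settings, "vent_settings"))
  T <- 60 / settings$RR
  Ti <- T / (1 + settings$ie_e)
  c(T = T, Ti = Ti, Te = T - Ti)
}

#' Safe-ventilation limits
#'
#' Container for the clinical safety criteria a shared pressure-control
#' setting must satisfy: plateau pressure bound (strict `<`), PEEP range,
#' respiratory-rate range, I:E range (as expiratory multiples of `1:e`), and
#' the tidal-volume target band in mL per kg body weight. Defaults are the
#' consensus recommendations for lung-protective ventilation: PPLAT <
#' 35 cmH2O, PEEP 5-25 cmH2O, RR 12-20 breaths/min, I:E 1:2 to 1:5, VT 6-8
#' mL/kg. All bounds are inclusive except `pplat_max`.
#'
#' @param pplat_max Plateau-pressure bound, cmH2O (strict).
#' @param peep_min,peep_max PEEP range, cmH2O (inclusive).
#' @param rr_min,rr_max Respiratory-rate range, breaths/min (inclusive).
#' @param ie_min_multiple,ie_max_multiple I:E range as expiratory multiples
#'   (inclusive); the default 2-5 corresponds to 1:2-1:5.
#' @param vt_min,vt_max Tidal-volume band, mL/kg (inclusive).
#' @return An object of class `safety_limits`.
#' @export
safety_limits <- function(pplat_max = 35, peep_min = 5, peep_max = 25,
                          rr_min = 12, rr_max = 20,
                          ie_min_multiple = 2, ie_max_multiple = 5,
                          vt_min = 6, vt_max = 8) {
  structure(
    list(pplat_max = pplat_max, peep_min = peep_min, peep_max = peep_max,
         rr_min = rr_min, rr_max = rr_max,
         ie_min_multiple = ie_min_multiple, ie_max_multiple = ie_max_multiple,
         vt_min = vt_min, vt_max = vt_max),
    class = "safety_limits"
  )
}

#' Check ventilator settings against safety limits
#'
#' Compares a pressure-control setting with the safe-ventilation criteria and
#' returns the violations as data rather than raising errors. In PC mode the
#' inspiratory pressure level effectively is the plateau pressure, so `PIP`
#' is checked against the `pplat_max` bound.
#'
#' @param settings A [vent_settings()] object.
#' @param limits A [safety_limits()] object (defaults to the standard bounds).
#' @return A data frame with one row per violation and columns `criterion`,
#'   `actual`, `bound`; zero rows when all criteria pass.
#' @examples
#' validate_settings(vent_settings(17, 7, 15, "1:2"))   # no violations
#' validate_settings(vent_settings(17, 3, 25, "1:2"))   # PEEP and RR out of range
#' @export
validate_settings <- function(settings, limits = safety_limits()) {
  stopifnot(inherits(settings, "vent_settings"), inherits(limits, "safety_limits"))
  v <- list()
  add <- function(criterion, actual, bound) {
    v[[length(v) + 1L]] <<- data.frame(criterion = criterion, actual = actual,
                                       bound = bound, stringsAsFactors = FALSE)
  }
  if (settings$PIP >= limits$pplat_max)
    add(sprintf("PIP (as PPLAT) not below %g cmH2O", limits$pplat_max),
        settings$PIP, limits$pplat_max)
  if (settings$PEEP < limits$peep_min)
    add(sprintf("PEEP below %g cmH2O", limits$peep_min), settings$PEEP, limits$peep_min)
  if (settings$PEEP > limits$peep_max)
    add(sprintf("PEEP above %g cmH2O", limits$peep_max), settings$PEEP, limits$peep_max)
  if (settings$RR < limits$rr_min)
    add(sprintf("RR below %g breaths/min", limits$rr_min), settings$RR, limits$rr_min)
  if (settings$RR > limits$rr_max)
    add(sprintf("RR above %g breaths/min", limits$rr_max), settings$RR, limits$rr_max)
  if (settings$ie_e < limits$ie_min_multiple)
    add(sprintf("I:E shorter than 1:%g", limits$ie_min_multiple),
        settings$ie_e, limits$ie_min_multiple)
  if (settings$ie_e > limits$ie_max_multiple)
    add(sprintf("I:E longer than 1:%g", limits$ie_max_multiple),
        settings$ie_e, limits$ie_max_multiple)
  if (length(v) == 0L)
    return(data.frame(criterion = character(), actual = numeric(), bound = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, v)
}

#' Sampled ventilator pressure waveform
#'
#' Generates the PC-mode square pressure trace on a uniform time grid:
#' `PIP` during the inspiratory phase `[0, Ti)`, `PEEP` during expiration
#' `[Ti, T)`, repeated over `n_cycles` breaths. When `rise_time > 0` the
#' inspiration onset is a linear PEEP-to-PIP ramp over `[0, rise_time]`
#' instead of an instantaneous step.
#'
#' @param settings A [vent_settings()] object.
#' @param dt Sample interval, seconds (default 0.001). Must resolve the
#'   inspiratory phase (`dt < Ti`).
#' @param n_cycles Number of breaths to generate (default 1).
#' @return List with `time` (s) and `pressure` (cmH2O), both of length
#'   `n_cycles * round(T/dt)`, plus `dt`, `n_per_cycle` and `n_insp` (samples
#'   per cycle and per inspiratory phase).
#' @examples
#' pw <- pressure_waveform(vent_settings(17, 7, 15, "1:2"), dt = 0.01)
#' range(pw$pressure)
#' @export
pressure_waveform <- function(settings, dt = 0.001, n_cycles = 1L) {
  stopifnot(inherits(settings, "vent_settings"), dt > 0, n_cycles >= 1L)
  tm <- breath_timing(settings)
  if (dt >= tm[["Ti"]])
    stop("dt must be smaller than the inspiratory time Ti (resolution error)")
  n <- round(tm[["T"]] / dt)
  n_insp <- round(tm[["Ti"]] / dt)
  t1 <- (seq_len(n) - 1L) * dt
  p1 <- ifelse(t1 < n_insp * dt, settings$PIP, settings$PEEP)
  if (settings$rise_time > 0) {
    ramp <- t1 < settings$rise_time
    p1[ramp] <- settings$PEEP +
      (settings$PIP - settings$PEEP) * t1[ramp] / settings$rise_time
  }
  p <- rep(p1, n_cycles)
  list(time = (seq_along(p) - 1L) * dt, pressure = p,
       dt = dt, n_per_cycle = n, n_insp = n_insp)
}

#' Sampled breath waveform
#'
#' Container for a simulated or measured breath: uniform time grid, airway
#' pressure (cmH2O), flow (L/s) and volume above the end-expiratory baseline
#' (L). Used both as simulator output and as input to
#' [identify_mechanics()].
#'
#' @param time Time grid, seconds, strictly increasing with constant step.
#' @param pressure Airway pressure, cmH2O.
#' @param flow Flow, L/s (positive into the lung).
#' @param volume Volume above baseline, L. If `NULL`, integrated from flow by
#'   the trapezoidal rule.
#' @return Object of class `breath_waveform`: list with `dt`, `time`,
#'   `pressure`, `flow`, `volume`.
#' @export
breath_waveform <- function(time, pressure, flow, volume = NULL) {
  n <- length(time)
  stopifnot(n >= 2L, length(pressure) == n, length(flow) == n)
  dts <- diff(time)
  dt <- dts[1]
  if (any(dts <= 0) || max(abs(dts - dt)) > 1e-9 * max(dt, 1))
    stop("time must be strictly increasing with a constant step")
  if (is.null(volume)) volume <- cumtrapz(flow, dt)
  stopifnot(length(volume) == n)
  structure(list(dt = dt, time = time, pressure = pressure,
                 flow = flow, volume = volume),
            class = "breath_waveform")
}

#' @export
print.breath_waveform <- function(x, ...) {
  cat(sprintf("<breath_waveform> %d samples at dt = %g s (%.3g s total)\n",
              length(x$time), x$dt, max(x$time)))
  cat(sprintf("  pressure %g..%g cmH2O, volume 0..%.1f mL\n",
              min(x$pressure), max(x$pressure), 1000 * max(x$volume)))
  invisible(x)
}

#' @export
as.data.frame.breath_waveform <- function(x, ...) {
  data.frame(time_s = x$time, paw_cmH2O = x$pressure,
             flow_lps = x$flow, vol_l = x$volume)
}

# cumulative trapezoid with uniform step
cumtrapz <- function(y, dt) {
  n <- length(y)
  c(0, cumsum((y[-1] + y[-n]) / 2) * dt)
}
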