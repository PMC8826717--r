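#' Simulate a single-compartment lung under pressure-control ventilation
#'
#' Integrates the single-compartment linear lung model
#' \deqn{P(t) = E V(t) + R \dot V(t) + P_0}
#' driven by the PC-mode pressure waveform of `settings`. The driving
#' pressure is held constant over each sample interval (zero-order hold),
#' which makes the exponential per-step update exact for the ideal square
#' wave; ramp segments are resolved at `O(dt)` accuracy. Volume starts from
#' the end-expiratory baseline `V(0) = 0`; flow is recovered from the model
#' at every sample, `flow = (P - P0 - E V)/R`.
#'
#' @param patient A [patient_mechanics()] object.
#' @param settings A [vent_settings()] object.
#' @param P0 Baseline pressure, cmH2O. Defaults to PEEP (no intrinsic PEEP).
#' @param dt Integration/sampling step, seconds (default 0.001).
#' @param n_cycles Number of breaths to simulate (default 10).
#' @param v0 Initial volume above baseline, L (default 0).
#' @return A [breath_waveform()] covering `n_cycles` breaths.
#' @examples
#' p <- patient_mechanics("P1", 20, 10, 65)
#' s <- vent_settings(17, 7, 15, "1:2")
#' wf <- simulate_scm(p, s, n_cycles = 3)
#' max(wf$volume) * 1000  # end-inspiratory volume, mL
#' @export
simulate_scm <- function(patient, settings, P0 = settings$PEEP,
                         dt = 0.001, n_cycles = 10L, v0 = 0) {
  stopifnot(inherits(patient, "patient_mechanics"), inherits(settings, "vent_settings"))
  pw <- pressure_waveform(settings, dt = dt, n_cycles = n_cycles)
  V <- scm_volume_zoh(pw$pressure, patient$E, patient$R, P0, dt, v0)
  if (anyNA(V) || any(!is.finite(V)))
    stop("non-finite volume in SCM integration (internal error)")
  flow <- (pw$pressure - P0 - patient$E * V) / patient$R
  breath_waveform(pw$time, pw$pressure, flow, V)
}

# Exact zero-order-hold update of dV/dt = (P - P0 - E V)/R as a linear
# recurrence V[k+1] = a V[k] + (1-a) (P[k]-P0)/E, a = exp(-E dt / R),
# computed with stats::filter (vectorised recursive filter).
scm_volume_zoh <- function(pressure, E, R, P0, dt, v0 = 0) {
  a <- exp(-E * dt / R)
  b <- (1 - a) * (pressure - P0) / E
  # V[k] is the volume at the *end* of interval k; prepend v0 for t = 0
  v <- stats::filter(b, a, method = "recursive", init = v0)
  c(v0, as.numeric(v))[seq_along(pressure)]
}

#' Closed-form cyclic-steady-state tidal volume of the SCM
#'
#' For an ideal square pressure wave (no rise time) the single-compartment
#' model admits an exact cyclic-steady-state solution. With time constant
#' `tau = R/E` and driving pressure `dP = PIP - PEEP`:
#' \deqn{VT = \frac{\Delta P}{E}\,
#'   \frac{(1 - e^{-Ti/\tau})(1 - e^{-Te/\tau})}{1 - e^{-T/\tau}}}
#' This serves as the analytic oracle the numeric integrator is validated
#' against.
#'
#' @param patient A [patient_mechanics()] object (or anything with `E`, `R`).
#' @param settings A [vent_settings()] object with `rise_time = 0`.
#' @return Tidal volume in litres.
#' @examples
#' scm_vt_closed_form(patient_mechanics("P1", 20, 10, 65),
#'                    vent_settings(17, 7, 15, "1:2"))
#' @export
scm_vt_closed_form <- function(patient, settings) {
  stopifnot(inherits(settings, "vent_settings"))
  if (settings$rise_time != 0)
    stop("closed form is only valid for the ideal square wave (rise_time = 0)")
  tm <- breath_timing(settings)
  vt_closed_form_num(patient$E, patient$R, settings$PIP - settings$PEEP,
                     tm[["Ti"]], tm[["Te"]])
}

# vectorised core of the closed form (used by the R-E grid)
vt_closed_form_num <- function(E, R, dP, Ti, Te) {
  tau <- R / E
  (dP / E) * (1 - exp(-Ti / tau)) * (1 - exp(-Te / tau)) / (1 - exp(-(Ti + Te) / tau))
}

#' Steady-state tidal-volume prediction for one patient
#'
#' Simulates the single-compartment model breath by breath until the
#' tidal volume (end-inspiratory minus end-expiratory volume) changes by
#' less than `tol` between successive breaths, then reports the converged VT
#' in litres and in mL per kg of the patient's body weight.
#'
#' @param patient A [patient_mechanics()] object.
#' @param settings A [vent_settings()] object.
#' @param P0 Baseline pressure, cmH2O; defaults to PEEP.
#' @param dt Integration step, seconds (default 0.001).
#' @param tol Relative successive-cycle VT change declaring cyclic steady
#'   state (default 1e-4, i.e. 0.01%).
#' @param max_cycles Safety cap on the number of simulated breaths.
#' @return Object of class `vt_prediction`: list with `vt_L`,
#'   `vt_ml_per_kg`, `patient_id`, `settings`, `steady_state_cycles`.
#' @examples
#' scm_tidal_volume(patient_mechanics("P1", 20, 10, 65),
#'                  vent_settings(17, 7, 15, "1:2"))
#' @export
scm_tidal_volume <- function(patient, settings, P0 = settings$PEEP,
                             dt = 0.001, tol = 1e-4, max_cycles = 200L) {
  stopifnot(inherits(patient, "patient_mechanics"), inherits(settings, "vent_settings"))
  pw1 <- pressure_waveform(settings, dt = dt, n_cycles = 1L)
  n <- pw1$n_per_cycle
  k_insp <- pw1$n_insp
  v0 <- 0
  vt_prev <- NA_real_
  cycles <- 0L
  repeat {
    V <- scm_volume_zoh(pw1$pressure, patient$E, patient$R, P0, dt, v0)
    cycles <- cycles + 1L
    v_end_insp <- V[k_insp + 1L]   # volume at t = Ti (peak of the cycle)
    v_end_exp <- tail_volume_zoh(V[n], pw1$pressure[n], patient, P0, dt)
    vt <- v_end_insp - v_end_exp
    if (!is.na(vt_prev) && abs(vt - vt_prev) <= tol * max(vt, .Machine$double.eps))
      break
    if (cycles >= max_cycles) {
      warning("steady state not reached within max_cycles; returning last VT")
      break
    }
    vt_prev <- vt
    v0 <- v_end_exp
  }
  structure(
    list(vt_L = vt, vt_ml_per_kg = 1000 * vt / patient$weight,
         patient_id = patient$id, settings = settings,
         steady_state_cycles = cycles),
    class = "vt_prediction"
  )
}

# advance the last in-cycle sample one ZOH step to the exact cycle end
tail_volume_zoh <- function(v, p, patient, P0, dt) {
  a <- exp(-patient$E * dt / patient$R)
  a * v + (1 - a) * (p - P0) / patient$E
}

#' @export
print.vt_prediction <- function(x, ...) {
  cat(sprintf("<vt_prediction> %s: VT = %.1f mL (%.2f mL/kg), steady after %d cycles\n",
              x$patient_id, 1000 * x$vt_L, x$vt_ml_per_kg, x$steady_state_cycles))
  invisible(x)
}

#' Identify respiratory mechanics from a breath waveform
#'
#' Estimates elastance `E`, resistance `R` and (optionally) the baseline
#' pressure `P0` of the single-compartment model from a measured or simulated
#' breath by multiple linear regression of airway pressure on volume and
#' flow: `P = E V + R V' + P0`. Ordinary least squares, no regularisation.
#' If the waveform carries no volume channel it is integrated from flow.
#'
#' @param waveform A [breath_waveform()] object (>= 10 samples with
#'   non-degenerate flow).
#' @param fix_P0 If given, `P0` is fixed at this value (cmH2O) and only
#'   `E`, `R` are estimated; otherwise the intercept is estimated.
#' @return Object of class `identified_mechanics`: list with `E_hat`,
#'   `R_hat`, `P0_hat`, `residual_rms` (cmH2O) and `n_samples`.
#' @examples
#' p <- patient_mechanics("P1", 20, 10, 65)
#' wf <- simulate_scm(p, vent_settings(17, 7, 15, "1:2"), n_cycles = 2)
#' identify_mechanics(wf)
#' @export
identify_mechanics <- function(waveform, fix_P0 = NULL) {
  stopifnot(inherits(waveform, "breath_waveform"))
  n <- length(waveform$time)
  if (n < 10L) stop("need at least 10 samples to identify mechanics")
  V <- waveform$volume
  Vdot <- waveform$flow
  P <- waveform$pressure
  if (stats::var(Vdot) <= .Machine$double.eps || stats::var(V) <= .Machine$double.eps)
    stop("non-identifiable: flow/volume carry no variation")
  if (is.null(fix_P0)) {
    X <- cbind(1, V, Vdot)
    y <- P
  } else {
    X <- cbind(V, Vdot)
    y <- P - fix_P0
  }
  qr_X <- qr(X)
  if (qr_X$rank < ncol(X))
    stop("non-identifiable: rank-deficient regression design (collinear volume and flow)")
  beta <- qr.coef(qr_X, y)
  res <- y - X %*% beta
  if (is.null(fix_P0)) {
    out <- list(E_hat = unname(beta[2]), R_hat = unname(beta[3]),
                P0_hat = unname(beta[1]))
  } else {
    out <- list(E_hat = unname(beta[1]), R_hat = unname(beta[2]), P0_hat = fix_P0)
  }
  out$residual_rms <- sqrt(mean(res^2))
  out$n_samples <- n
  structure(out, class = "identified_mechanics")
}

#' @export
print.identified_mechanics <- function(x, ...) {
  cat(sprintf("<identified_mechanics> E = %.3f cmH2O/L, R = %.3f cmH2O.s/L, P0 = %.3f cmH2O\n",
              x$E_hat, x$R_hat, x$P0_hat))
  cat(sprintf("  residual RMS %.4g cmH2O over %d samples\n", x$residual_rms, x$n_samples))
  invisible(x)
}
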