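#' Two-patient shared-ventilator circuit
#'
#' Describes an in-parallel co-ventilation (Co-MV) circuit: two patients,
#' each a single lung compartment, fed through a common circuit resistance
#' `Rc` from one ventilator. `Rc` models the extra tubing shared upstream of
#' the junction where the two patient limbs split; the pressure at that
#' junction is `PJ = P_vent - Rc (V'1 + V'2)`.
#'
#' @param patient1,patient2 [patient_mechanics()] objects.
#' @param Rc Common circuit resistance, cmH2O.s/L (>= 0). Default 8, a
#'   representative value for the lengthened shared circuit.
#' @param P0 Baseline pressure, cmH2O, or `NULL` to default to the PEEP of
#'   whatever settings are simulated.
#' @return Object of class `co_vent_circuit`.
#' @examples
#' cohort <- preset_cohort()
#' co_vent_circuit(cohort$P1, cohort$C, Rc = 8)
#' @export
co_vent_circuit <- function(patient1, patient2, Rc = 8, P0 = NULL) {
  stopifnot(inherits(patient1, "patient_mechanics"),
            inherits(patient2, "patient_mechanics"))
  if (!is.finite(Rc) || Rc < 0) stop("Rc must be >= 0 cmH2O.s/L")
  structure(list(patient1 = patient1, patient2 = patient2,
                 Rc = as.numeric(Rc), P0 = P0),
            class = "co_vent_circuit")
}

#' @export
print.co_vent_circuit <- function(x, ...) {
  cat(sprintf("<co_vent_circuit> %s + %s, Rc = %g cmH2O.s/L\n",
              x$patient1$id, x$patient2$id, x$Rc))
  invisible(x)
}

# state-space matrices of the coupled two-compartment system:
# M %*% flows = (P - P0 - E_i V_i), M = [[R1+Rc, Rc], [Rc, R2+Rc]]
dcm_matrices <- function(circuit) {
  R1 <- circuit$patient1$R; R2 <- circuit$patient2$R; Rc <- circuit$Rc
  E <- c(circuit$patient1$E, circuit$patient2$E)
  M <- matrix(c(R1 + Rc, Rc, Rc, R2 + Rc), 2, 2)
  list(M = M, Minv = solve(M), E = E, A = -solve(M) %*% diag(E))
}

# 2x2 matrix exponential by scaled Taylor series (spectral radius ~E dt/R << 1)
expm2 <- function(A) {
  S <- diag(2); X <- diag(2)
  for (k in 1:30) {
    X <- X %*% A / k
    S <- S + X
    if (max(abs(X)) < 1e-18) break
  }
  S
}

# Exact zero-order-hold volume recurrence of the coupled system,
# V[k+1] = Vss_k + Phi (V[k] - Vss_k), Phi = expm(A dt),
# decoupled through the eigenbasis of A so both coordinates run as
# vectorised recursive filters. Returns volumes at the sample times plus the
# volume one step past the end (for cycle chaining).
dcm_volumes <- function(pressure, circuit, P0, dt, v0 = c(0, 0)) {
  mats <- dcm_matrices(circuit)
  Phi <- expm2(mats$A * dt)
  invE <- 1 / mats$E
  g <- as.numeric((diag(2) - Phi) %*% invE)  # (I-Phi) Vss per unit (P-P0)
  pd <- pressure - P0
  eg <- eigen(mats$A)
  use_eigen <- all(abs(Im(eg$values)) < 1e-12) &&
    is.finite(kappa(Re(eg$vectors))) && kappa(Re(eg$vectors)) < 1e8
  N <- length(pressure)
  if (use_eigen) {
    Q <- Re(eg$vectors); Qinv <- solve(Q)
    d <- exp(Re(eg$values) * dt)
    h <- as.numeric(Qinv %*% g)
    w0 <- as.numeric(Qinv %*% v0)
    w1 <- stats::filter(h[1] * pd, d[1], method = "recursive", init = w0[1])
    w2 <- stats::filter(h[2] * pd, d[2], method = "recursive", init = w0[2])
    W <- rbind(c(w0[1], as.numeric(w1)), c(w0[2], as.numeric(w2)))  # times 0..N*dt
    V <- Q %*% W
  } else {
    # defective eigensystem (repeated time constants): plain stepping
    V <- matrix(0, 2, N + 1L)
    V[, 1] <- v0
    for (k in seq_len(N)) V[, k + 1L] <- Phi %*% V[, k] + g * pd[k]
  }
  list(V = V[, seq_len(N), drop = FALSE], v_end = V[, N + 1L])
}

#' Simulate the double-compartment co-ventilation circuit
#'
#' Integrates the coupled two-patient system under an arbitrary sampled
#' ventilator pressure trace. Each patient obeys
#' `PJ = E_i V_i + R_i V'_i + P0` with the shared junction pressure
#' `PJ = P_vent - Rc (V'1 + V'2)`; at every step the two flows solve a 2x2
#' linear system, and the volume update uses the exact matrix-exponential
#' step of the resulting linear state-space model (zero-order hold on the
#' pressure).
#'
#' @param circuit A [co_vent_circuit()] object.
#' @param pressure Sampled ventilator pressure, cmH2O (uniform grid).
#' @param dt Sample interval, seconds.
#' @param P0 Baseline pressure, cmH2O. Defaults to the circuit's `P0`, which
#'   must then be set.
#' @param v0 Initial per-patient volumes, L (default both 0).
#' @return Object of class `co_vent_trace`: list with `dt`, `time`,
#'   `p_vent`, `p_joint`, `flow1`, `flow2`, `vol1`, `vol2`, `vol_total`.
#' @examples
#' cohort <- preset_cohort()
#' circ <- co_vent_circuit(cohort$P1, cohort$C, Rc = 8)
#' pw <- pressure_waveform(vent_settings(17, 7, 15, "1:2"), n_cycles = 2)
#' tr <- simulate_dcm(circ, pw$pressure, pw$dt, P0 = 7)
#' max(tr$vol_total)
#' @export
simulate_dcm <- function(circuit, pressure, dt, P0 = circuit$P0, v0 = c(0, 0)) {
  stopifnot(inherits(circuit, "co_vent_circuit"), dt > 0)
  if (is.null(P0)) stop("P0 must be given (or set on the circuit)")
  res <- dcm_volumes(pressure, circuit, P0, dt, v0)
  V <- res$V
  if (anyNA(V) || any(!is.finite(V)))
    stop("non-finite volume in DCM integration (internal error)")
  mats <- dcm_matrices(circuit)
  rhs1 <- pressure - P0 - mats$E[1] * V[1, ]
  rhs2 <- pressure - P0 - mats$E[2] * V[2, ]
  flow1 <- mats$Minv[1, 1] * rhs1 + mats$Minv[1, 2] * rhs2
  flow2 <- mats$Minv[2, 1] * rhs1 + mats$Minv[2, 2] * rhs2
  p_joint <- pressure - circuit$Rc * (flow1 + flow2)
  structure(
    list(dt = dt, time = (seq_along(pressure) - 1L) * dt,
         p_vent = pressure, p_joint = p_joint,
         flow1 = flow1, flow2 = flow2,
         vol1 = V[1, ], vol2 = V[2, ], vol_total = V[1, ] + V[2, ],
         v_end = res$v_end, P0 = P0),
    class = "co_vent_trace"
  )
}

#' @export
print.co_vent_trace <- function(x, ...) {
  cat(sprintf("<co_vent_trace> %d samples at dt = %g s\n", length(x$time), x$dt))
  cat(sprintf("  vent pressure %g..%g cmH2O, volumes up to %.1f + %.1f mL\n",
              min(x$p_vent), max(x$p_vent),
              1000 * max(x$vol1), 1000 * max(x$vol2)))
  invisible(x)
}

#' @export
as.data.frame.co_vent_trace <- function(x, ...) {
  data.frame(time_s = x$time, pvent_cmH2O = x$p_vent, pj_cmH2O = x$p_joint,
             flow1_lps = x$flow1, flow2_lps = x$flow2,
             vol1_l = x$vol1, vol2_l = x$vol2)
}

#' Per-patient steady-state tidal volumes under a shared square wave
#'
#' Runs the double-compartment simulation breath by breath until both
#' patients' tidal volumes change by less than `tol` between successive
#' breaths, then reports each patient's converged VT.
#'
#' @param circuit A [co_vent_circuit()] object.
#' @param settings A [vent_settings()] object (the shared square wave).
#' @param P0 Baseline pressure; defaults to the circuit's `P0` or, if unset,
#'   the settings' PEEP.
#' @param dt Integration step, s.
#' @param tol Relative successive-cycle VT change declaring steady state.
#' @param max_cycles Cap on simulated breaths.
#' @return List with `vt_L` (length 2), `vt_ml_per_kg` (length 2),
#'   `cycles`, and `trace` (the final steady cycle as a `co_vent_trace`).
#' @export
dcm_tidal_volume <- function(circuit, settings, P0 = NULL, dt = 0.001,
                             tol = 1e-4, max_cycles = 200L) {
  stopifnot(inherits(circuit, "co_vent_circuit"), inherits(settings, "vent_settings"))
  if (is.null(P0)) P0 <- if (!is.null(circuit$P0)) circuit$P0 else settings$PEEP
  pw <- pressure_waveform(settings, dt = dt, n_cycles = 1L)
  k_insp <- pw$n_insp
  v0 <- c(0, 0)
  vt_prev <- c(NA_real_, NA_real_)
  cycles <- 0L
  repeat {
    res <- dcm_volumes(pw$pressure, circuit, P0, dt, v0)
    cycles <- cycles + 1L
    # volume at t = Ti is sample k_insp+1 of the padded series
    v_insp <- if (k_insp + 1L <= ncol(res$V)) res$V[, k_insp + 1L] else res$v_end
    vt <- v_insp - res$v_end
    if (!anyNA(vt_prev) &&
        all(abs(vt - vt_prev) <= tol * pmax(vt, .Machine$double.eps)))
      break
    if (cycles >= max_cycles) {
      warning("DCM steady state not reached within max_cycles")
      break
    }
    vt_prev <- vt
    v0 <- res$v_end
  }
  weights <- c(circuit$patient1$weight, circuit$patient2$weight)
  trace <- simulate_dcm(circuit, pw$pressure, dt, P0 = P0, v0 = v0)
  list(vt_L = vt, vt_ml_per_kg = 1000 * vt / weights,
       cycles = cycles, trace = trace)
}

# one steady-state SCM cycle (volume converged), used for the ideal pressure
scm_steady_cycle <- function(patient, settings, P0 = settings$PEEP, dt = 0.001,
                             tol = 1e-4, max_cycles = 200L) {
  pw <- pressure_waveform(settings, dt = dt, n_cycles = 1L)
  v0 <- 0
  for (i in seq_len(max_cycles)) {
    V <- scm_volume_zoh(pw$pressure, patient$E, patient$R, P0, dt, v0)
    v_end <- tail_volume_zoh(V[length(V)], pw$pressure[length(V)], patient, P0, dt)
    if (abs(v_end - v0) <= tol * max(abs(v_end), .Machine$double.eps)) break
    v0 <- v_end
  }
  V <- scm_volume_zoh(pw$pressure, patient$E, patient$R, P0, dt, v0)
  flow <- (pw$pressure - P0 - patient$E * V) / patient$R
  breath_waveform(pw$time, pw$pressure, flow, V)
}

#' Ideal ventilator pressure for a co-ventilated pair
#'
#' Computes the ventilator pressure that would deliver each patient exactly
#' the tidal volume they receive when ventilated alone on the shared
#' settings. If the junction pressure reproduces the original square wave,
#' each patient's flow is their single-compartment steady-state flow, so the
#' ventilator must supply
#' `P_ideal(t) = P_square(t) + Rc (V'1(t) + V'2(t))`. Because the summed
#' flow decays within each phase, this is an "inverse ramp": it overshoots
#' PIP at inspiration onset and can dip below PEEP - even below zero - in
#' expiration. Values are not clamped; implausible excursions are flagged.
#'
#' @param circuit A [co_vent_circuit()] object.
#' @param settings The index patient's validated [vent_settings()].
#' @param dt Sampling step, s.
#' @return Object of class `ideal_pressure`: list with `time`, `pressure`
#'   (the ideal trace over one steady-state cycle), `square` (the underlying
#'   square wave), `flow1`, `flow2`, `n_insp`, `dt`, and flags
#'   `exceeds_pip`, `negative`.
#' @examples
#' cohort <- preset_cohort()
#' circ <- co_vent_circuit(cohort$P1, cohort$C, Rc = 8)
#' ip <- ideal_joint_pressure(circ, vent_settings(17, 7, 15, "1:2"))
#' max(ip$pressure)  # inspiratory-onset overshoot above PIP
#' @export
ideal_joint_pressure <- function(circuit, settings, dt = 0.001) {
  stopifnot(inherits(circuit, "co_vent_circuit"), inherits(settings, "vent_settings"))
  P0 <- if (!is.null(circuit$P0)) circuit$P0 else settings$PEEP
  w1 <- scm_steady_cycle(circuit$patient1, settings, P0 = P0, dt = dt)
  w2 <- scm_steady_cycle(circuit$patient2, settings, P0 = P0, dt = dt)
  p_ideal <- w1$pressure + circuit$Rc * (w1$flow + w2$flow)
  structure(
    list(time = w1$time, pressure = p_ideal, square = w1$pressure,
         flow1 = w1$flow, flow2 = w2$flow,
         n_insp = pressure_waveform(settings, dt = dt)$n_insp, dt = dt,
         settings = settings,
         exceeds_pip = max(p_ideal) > settings$PIP,
         negative = min(p_ideal) < 0),
    class = "ideal_pressure"
  )
}

#' @export
print.ideal_pressure <- function(x, ...) {
  cat(sprintf("<ideal_pressure> %g..%g cmH2O over one cycle%s%s\n",
              min(x$pressure), max(x$pressure),
              if (x$exceeds_pip) ", overshoots PIP" else "",
              if (x$negative) ", dips below zero (implausible to deliver)" else ""))
  invisible(x)
}

#' Starting PIP estimate from the ideal pressure trace
#'
#' A square-wave ventilator cannot deliver the inverse-ramp ideal pressure;
#' as a starting approximation the inspiratory phase of the ideal trace is
#' averaged to a single PIP level.
#'
#' @param ideal An `ideal_pressure` object from [ideal_joint_pressure()].
#' @return Estimated PIP, cmH2O (time-average of the ideal pressure over the
#'   inspiratory phase of the steady-state cycle).
#' @export
estimate_pip <- function(ideal) {
  stopifnot(inherits(ideal, "ideal_pressure"))
  mean(ideal$pressure[seq_len(ideal$n_insp)])
}

#' Iterative PIP tuning for co-ventilation
#'
#' Searches for the shared square-wave PIP that best recovers each patient's
#' desired tidal volume under the coupled two-patient circuit, with PEEP,
#' rate and I:E held at the index setting. Starting from the averaged ideal
#' pressure ([estimate_pip()]) rounded to the step, candidate PIPs are
#' explored in `step` increments (one probe downward first, then in the
#' improving direction) until the objective - the mean of the two patients'
#' relative tidal-volume errors - stops improving, or the `pip_max` safety
#' cap is reached.
#'
#' @param circuit A [co_vent_circuit()] object.
#' @param settings The index patient's [vent_settings()] (PEEP/RR/I:E kept).
#' @param desired_vt_L Per-patient target tidal volumes in litres; defaults
#'   to each patient's own single-compartment steady-state VT under
#'   `settings`.
#' @param step PIP increment, cmH2O (default 0.5).
#' @param pip_max Upper PIP bound, cmH2O (default 35, the plateau-pressure
#'   safety limit).
#' @param dt Integration step, s.
#' @return Object of class `tuning_result`: list with `pip_est`,
#'   `pip_final`, `iterations` (DCM evaluations), `ideal_vt_L`,
#'   `actual_vt_L`, `ideal_vt_ml_per_kg`, `actual_vt_ml_per_kg`,
#'   `percent_error` (per patient), `objective`, `cap_reached`, `history`
#'   (data frame of candidate PIPs and objectives) and `settings_final`.
#' @examples
#' \donttest{
#' cohort <- preset_cohort()
#' circ <- co_vent_circuit(cohort$P1, cohort$C, Rc = 8)
#' tune_pip(circ, vent_settings(17, 7, 15, "1:2"))
#' }
#' @export
tune_pip <- function(circuit, settings, desired_vt_L = NULL, step = 0.5,
                     pip_max = 35, dt = 0.001) {
  stopifnot(inherits(circuit, "co_vent_circuit"), inherits(settings, "vent_settings"),
            step > 0, pip_max > settings$PEEP)
  P0 <- if (!is.null(circuit$P0)) circuit$P0 else settings$PEEP
  if (is.null(desired_vt_L)) {
    desired_vt_L <- c(
      scm_tidal_volume(circuit$patient1, settings, P0 = P0, dt = dt)$vt_L,
      scm_tidal_volume(circuit$patient2, settings, P0 = P0, dt = dt)$vt_L
    )
  }
  stopifnot(length(desired_vt_L) == 2L, all(desired_vt_L > 0))
  ideal <- ideal_joint_pressure(circuit, settings, dt = dt)
  pip_est <- estimate_pip(ideal)

  cache <- new.env(parent = emptyenv())
  evaluate <- function(pip) {
    key <- sprintf("%.6f", pip)
    if (!is.null(cache[[key]])) return(cache[[key]])
    s <- vent_settings(pip, settings$PEEP, settings$RR, settings$ie_e)
    vt <- dcm_tidal_volume(circuit, s, P0 = P0, dt = dt)
    res <- list(pip = pip, vt_L = vt$vt_L,
                objective = mean(abs(vt$vt_L - desired_vt_L) / desired_vt_L))
    cache[[key]] <- res
    res
  }

  start <- max(round(pip_est / step) * step, settings$PEEP + step)
  start <- min(start, pip_max)
  history <- list()
  record <- function(res) history[[length(history) + 1L]] <<- res
  cap_reached <- FALSE

  best <- evaluate(start); record(best)
  # probe one step downward first, then walk in the improving direction
  down_ok <- start - step > settings$PEEP
  if (down_ok) {
    down <- evaluate(start - step); record(down)
    dir <- if (down$objective < best$objective) -step else step
    if (dir < 0) best <- down
  } else {
    dir <- step
  }
  repeat {
    nxt_pip <- best$pip + dir
    if (nxt_pip > pip_max) { cap_reached <- TRUE; break }
    if (nxt_pip <= settings$PEEP) break
    nxt <- evaluate(nxt_pip); record(nxt)
    if (nxt$objective < best$objective) best <- nxt else break
  }

  hist_df <- do.call(rbind, lapply(history, function(h)
    data.frame(pip = h$pip, objective = h$objective,
               vt1_mL = 1000 * h$vt_L[1], vt2_mL = 1000 * h$vt_L[2])))
  hist_df <- hist_df[order(hist_df$pip), , drop = FALSE]
  rownames(hist_df) <- NULL

  weights <- c(circuit$patient1$weight, circuit$patient2$weight)
  actual <- best$vt_L
  structure(
    list(pip_est = pip_est, pip_final = best$pip,
         iterations = length(history),
         ideal_vt_L = desired_vt_L, actual_vt_L = actual,
         ideal_vt_ml_per_kg = 1000 * desired_vt_L / weights,
         actual_vt_ml_per_kg = 1000 * actual / weights,
         percent_error = 100 * abs(actual - desired_vt_L) / desired_vt_L,
         objective = best$objective, cap_reached = cap_reached,
         history = hist_df,
         settings_final = vent_settings(best$pip, settings$PEEP,
                                        settings$RR, settings$ie_e)),
    class = "tuning_result"
  )
}

#' @export
print.tuning_result <- function(x, ...) {
  cat(sprintf("<tuning_result> PIP_EST %.2f -> final PIP %.1f cmH2O (%d DCM runs%s)\n",
              x$pip_est, x$pip_final, x$iterations,
              if (x$cap_reached) ", cap reached" else ""))
  cat(sprintf("  patient 1: ideal %.1f mL, actual %.1f mL (%.2f%% error)\n",
              1000 * x$ideal_vt_L[1], 1000 * x$actual_vt_L[1], x$percent_error[1]))
  cat(sprintf("  patient 2: ideal %.1f mL, actual %.1f mL (%.2f%% error)\n",
              1000 * x$ideal_vt_L[2], 1000 * x$actual_vt_L[2], x$percent_error[2]))
  invisible(x)
}

#' Co-ventilation summary report
#'
#' Collects the tuned setting and the per-patient delivered tidal volumes
#' into a per-patient table (mL and mL/kg, ideal vs actual, percent error)
#' plus a safety check of the finalised setting.
#'
#' @param tuning A `tuning_result` from [tune_pip()].
#' @param circuit The [co_vent_circuit()] that was tuned.
#' @param limits [safety_limits()] for the final-settings check.
#' @return Object of class `co_mv_report`: list with `patients` (data
#'   frame), `pip_est`, `pip_final`, `driving_pressure`, `settings_final`,
#'   `violations` (from [validate_settings()]), `cap_reached`.
#' @export
co_mv_report <- function(tuning, circuit, limits = safety_limits()) {
  stopifnot(inherits(tuning, "tuning_result"), inherits(circuit, "co_vent_circuit"))
  pts <- list(circuit$patient1, circuit$patient2)
  tab <- data.frame(
    id = vapply(pts, `[[`, character(1), "id"),
    E = vapply(pts, `[[`, numeric(1), "E"),
    R = vapply(pts, `[[`, numeric(1), "R"),
    weight_kg = vapply(pts, `[[`, numeric(1), "weight"),
    ideal_vt_mL = 1000 * tuning$ideal_vt_L,
    actual_vt_mL = 1000 * tuning$actual_vt_L,
    ideal_vt_mlkg = tuning$ideal_vt_ml_per_kg,
    actual_vt_mlkg = tuning$actual_vt_ml_per_kg,
    percent_error = tuning$percent_error,
    stringsAsFactors = FALSE
  )
  structure(
    list(patients = tab, pip_est = tuning$pip_est, pip_final = tuning$pip_final,
         driving_pressure = tuning$pip_final - tuning$settings_final$PEEP,
         settings_final = tuning$settings_final,
         violations = validate_settings(tuning$settings_final, limits),
         cap_reached = tuning$cap_reached),
    class = "co_mv_report"
  )
}

#' @export
print.co_mv_report <- function(x, ...) {
  cat(sprintf("<co_mv_report> final PIP %.1f / PEEP %g cmH2O (driving pressure %.1f)\n",
              x$pip_final, x$settings_final$PEEP, x$driving_pressure))
  print(x$patients, row.names = FALSE, digits = 4)
  if (nrow(x$violations) == 0L) {
    cat("  final settings satisfy all safety criteria\n")
  } else {
    cat("  SAFETY VIOLATIONS:\n"); print(x$violations, row.names = FALSE)
  }
  invisible(x)
}
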