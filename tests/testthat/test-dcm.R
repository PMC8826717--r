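test_that("with zero common resistance the two compartments decouple to SCM", {
  set.seed(21)
  for (i in 1:5) {
    p1 <- draw_patient(i)
    p2 <- draw_patient(i + 100)
    s <- draw_settings()
    pw <- pressure_waveform(s, dt = 0.001, n_cycles = 3)
    tr <- simulate_dcm(co_vent_circuit(p1, p2, Rc = 0), pw$pressure, pw$dt,
                       P0 = s$PEEP)
    w1 <- simulate_scm(p1, s, n_cycles = 3)
    w2 <- simulate_scm(p2, s, n_cycles = 3)
    expect_lt(max(abs(tr$vol1 - w1$volume)), 1e-6)
    expect_lt(max(abs(tr$vol2 - w2$volume)), 1e-6)
  }
})

test_that("identical patients share the circuit symmetrically", {
  p <- ref_cohort$P1
  twin <- patient_mechanics("twin", p$E, p$R, p$weight)
  pw <- pressure_waveform(ref_settings, n_cycles = 3)
  tr <- simulate_dcm(co_vent_circuit(p, twin, Rc = 8), pw$pressure, pw$dt,
                     P0 = 7)
  expect_lt(max(abs(tr$vol1 - tr$vol2)), 1e-12)
})

test_that("volume and junction-pressure conservation hold at every sample", {
  pw <- pressure_waveform(ref_settings, n_cycles = 2)
  circ <- co_vent_circuit(ref_cohort$P1, ref_cohort$C, Rc = 8)
  tr <- simulate_dcm(circ, pw$pressure, pw$dt, P0 = 7)
  expect_equal(tr$vol_total, tr$vol1 + tr$vol2, tolerance = 1e-12)
  expect_equal(tr$p_joint, tr$p_vent - 8 * (tr$flow1 + tr$flow2),
               tolerance = 1e-12)
  # each compartment obeys its own pressure balance against the junction
  expect_lt(max(abs(tr$p_joint - 7 - 20 * tr$vol1 - 10 * tr$flow1)), 1e-9)
  expect_lt(max(abs(tr$p_joint - 7 - 18 * tr$vol2 - 9 * tr$flow2)), 1e-9)
})

test_that("simulated traces satisfy the second-order total-volume equation", {
  # smooth driving pressure so the derivatives in the second-order form exist
  set.seed(31)
  dt <- 0.001
  t <- seq(0, 8, by = dt)
  for (i in 1:5) {
    p1 <- draw_patient(i)
    p2 <- draw_patient(i + 200)
    Rc <- stats::runif(1, 0, 12)
    P0 <- 7
    P <- 12 + 4 * sin(2 * pi * t / 4) + 2 * sin(2 * pi * t / 1.3)
    tr <- simulate_dcm(co_vent_circuit(p1, p2, Rc = Rc), P, dt, P0 = P0)
    V <- tr$vol_total
    n <- length(t)
    mid <- 3:(n - 2)
    dP <- (P[mid + 1] - P[mid - 1]) / (2 * dt)
    dV <- (V[mid + 1] - V[mid - 1]) / (2 * dt)
    ddV <- (V[mid + 1] - 2 * V[mid] + V[mid - 1]) / dt^2
    lhs <- (p1$R + p2$R) * dP + (p1$E + p2$E) * (P[mid] - P0)
    rhs <- (p1$R * p2$R + Rc * (p1$R + p2$R)) * ddV +
      ((Rc + p2$R) * p1$E + (Rc + p1$R) * p2$E) * dV +
      p1$E * p2$E * V[mid]
    i0 <- mid > 2000  # past the initial transient
    expect_lt(sqrt(mean((lhs - rhs)[i0]^2)) / sqrt(mean(rhs[i0]^2)), 0.01)
  }
})

test_that("the ideal joint pressure is an inverse ramp that restores SCM volumes", {
  circ <- co_vent_circuit(ref_cohort$P1, ref_cohort$C, Rc = 8)
  ip <- ideal_joint_pressure(circ, ref_settings)
  # onset overshoot: PIP + Rc * (dP/R1 + dP/R2), small end-expiratory correction
  expect_equal(max(ip$pressure), 17 + 8 * (10 / 10 + 10 / 9), tolerance = 0.02)
  expect_true(ip$exceeds_pip)
  expect_true(min(ip$pressure) < ref_settings$PEEP)
  # round trip: driving the coupled circuit with the ideal pressure
  # reproduces each patient's independent steady-state volume trace
  n_rep <- 6
  tr <- simulate_dcm(circ, rep(ip$pressure, n_rep), ip$dt, P0 = 7)
  last <- (length(ip$pressure) * (n_rep - 1) + 1):(length(ip$pressure) * n_rep)
  w1 <- coventr:::scm_steady_cycle(ref_cohort$P1, ref_settings)
  w2 <- coventr:::scm_steady_cycle(ref_cohort$C, ref_settings)
  expect_lt(max(abs(tr$vol1[last] - w1$volume)) / max(w1$volume), 0.005)
  expect_lt(max(abs(tr$vol2[last] - w2$volume)) / max(w2$volume), 0.005)
})

test_that("ideal pressure and PIP estimate collapse to the square wave at Rc = 0", {
  circ0 <- co_vent_circuit(ref_cohort$P1, ref_cohort$C, Rc = 0)
  ip0 <- ideal_joint_pressure(circ0, ref_settings)
  expect_equal(max(abs(ip0$pressure - ip0$square)), 0, tolerance = 1e-12)
  expect_equal(estimate_pip(ip0), 17)
  # positive Rc adds a positive inspiratory term
  circ8 <- co_vent_circuit(ref_cohort$P1, ref_cohort$C, Rc = 8)
  expect_gt(estimate_pip(ideal_joint_pressure(circ8, ref_settings)), 17)
})

test_that("each patient's steady VT is increasing in PIP (unimodal tuning objective)", {
  circ <- co_vent_circuit(ref_cohort$P1, ref_cohort$C, Rc = 8)
  pips <- c(18, 20, 22, 24)
  vts <- vapply(pips, function(p) {
    dcm_tidal_volume(circ, vent_settings(p, 7, 15, "1:2"))$vt_L
  }, numeric(2))
  expect_true(all(diff(vts[1, ]) > 0))
  expect_true(all(diff(vts[2, ]) > 0))
})

test_that("VT splits in inverse proportion to elastance when resistances match", {
  # elastance-proportional sharing holds once each breath phase fully
  # equilibrates (phase times >> time constants), where VT -> dP/E
  p1 <- patient_mechanics("a", E = 20, R = 10, weight = 65)
  p2 <- patient_mechanics("b", E = 32, R = 10, weight = 65)
  slow <- vent_settings(17, 7, RR = 2, IE = "1:1")
  vt <- dcm_tidal_volume(co_vent_circuit(p1, p2, Rc = 0), slow)$vt_L
  expect_equal(vt[1] / vt[2], 32 / 20, tolerance = 1e-5)
})

test_that("PIP tuning is a no-op for a decoupled circuit", {
  circ <- co_vent_circuit(ref_cohort$P1, ref_cohort$C, Rc = 0)
  tr <- tune_pip(circ, ref_settings)
  expect_equal(tr$pip_final, 17)
  expect_lt(max(tr$percent_error), 0.05)
})

test_that("tuning the reference pair recovers the worked-example settings", {
  circ <- co_vent_circuit(ref_cohort$P1, ref_cohort$C, Rc = 8)
  tr <- tune_pip(circ, ref_settings, step = 0.5)
  expect_gt(tr$pip_est, 17)           # the shared circuit demands extra pressure
  expect_equal(tr$pip_final, 23.0)    # one 0.5 step from the reported 22.5
  expect_false(tr$cap_reached)
  # realised volumes sit within a step-quantised residual of the targets
  expect_lt(max(tr$percent_error), 2)
  # the discrete optimum beats its neighbours in the recorded history
  h <- tr$history
  expect_true(all(h$objective >= h$objective[h$pip == tr$pip_final]))
  rep <- co_mv_report(tr, circ)
  expect_equal(nrow(rep$violations), 0)
  expect_equal(rep$driving_pressure, tr$pip_final - 7)
})

test_that("tuning respects the plateau-pressure cap", {
  # stiff pair through a huge shared resistance cannot reach its targets
  p1 <- patient_mechanics("s1", E = 45, R = 30, weight = 65)
  p2 <- patient_mechanics("s2", E = 45, R = 30, weight = 65)
  circ <- co_vent_circuit(p1, p2, Rc = 40)
  tr <- tune_pip(circ, ref_settings, pip_max = 25)
  expect_lte(tr$pip_final, 25)
  expect_true(tr$cap_reached)
})
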