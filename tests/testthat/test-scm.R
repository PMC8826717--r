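test_that("numeric steady-state VT matches the closed-form oracle to <0.1%", {
  set.seed(101)
  for (i in 1:100) {
    p <- draw_patient(i)
    s <- draw_settings()
    vt_num <- scm_tidal_volume(p, s)$vt_L
    vt_cf <- scm_vt_closed_form(p, s)
    expect_lt(abs(vt_num - vt_cf) / vt_cf, 1e-3)
  }
})

test_that("simulated volume and flow are mutually consistent", {
  p <- ref_cohort$P1
  wf <- simulate_scm(p, ref_settings, n_cycles = 3)
  # volume re-integrated from flow tracks the state trajectory; the flow
  # steps at phase transitions bound the trapezoid error to O(dt) per jump
  v_re <- cumsum(c(0, (wf$flow[-1] + wf$flow[-length(wf$flow)]) / 2 * wf$dt))
  expect_lt(max(abs(v_re - wf$volume)), 2e-3)
  expect_true(all(wf$volume > -1e-12))
  # the model identity holds at every sample
  resid <- wf$pressure - 7 - p$E * wf$volume - p$R * wf$flow
  expect_lt(max(abs(resid)), 1e-10)
})

test_that("an independent general-purpose ODE solver reproduces the simulation", {
  skip_if_not_installed("deSolve")
  p <- ref_cohort$P1
  s <- ref_settings
  pw <- pressure_waveform(s, dt = 0.001, n_cycles = 5)
  pfun <- stats::approxfun(pw$time, pw$pressure, method = "constant",
                           rule = 2, f = 0)
  sol <- deSolve::lsoda(
    y = c(V = 0), times = pw$time,
    func = function(t, y, parms) list((pfun(t) - 7 - p$E * y[1]) / p$R),
    rtol = 1e-9, atol = 1e-12
  )
  wf <- simulate_scm(p, s, n_cycles = 5)
  expect_lt(max(abs(sol[, "V"] - wf$volume)), 5e-4)
})

test_that("VT is linear in driving pressure and monotone in E and R", {
  s1 <- vent_settings(17, 7, 15, "1:2")
  s2 <- vent_settings(27, 7, 15, "1:2")  # doubled driving pressure
  p <- ref_cohort$P1
  expect_equal(2 * scm_vt_closed_form(p, s1), scm_vt_closed_form(p, s2),
               tolerance = 1e-12)
  set.seed(7)
  for (i in 1:10) {
    p <- draw_patient(i)
    s <- draw_settings()
    up_E <- patient_mechanics("e", p$E * 1.2, p$R, p$weight)
    up_R <- patient_mechanics("r", p$E, p$R * 1.2, p$weight)
    expect_lt(scm_vt_closed_form(up_E, s), scm_vt_closed_form(p, s))
    expect_lt(scm_vt_closed_form(up_R, s), scm_vt_closed_form(p, s))
  }
})

test_that("limiting behaviour: zero resistance and long phases", {
  s <- ref_settings
  # R -> 0: end-inspiratory volume approaches dP/E
  p <- patient_mechanics("fast", E = 20, R = 0.01, weight = 65)
  expect_equal(max(simulate_scm(p, s, n_cycles = 2)$volume), 10 / 20,
               tolerance = 1e-3)
  # Ti, Te >> tau: VT -> dP/E
  slow <- vent_settings(17, 7, RR = 0.5, IE = "1:1")
  p <- patient_mechanics("p", 20, 10, 65)
  expect_equal(scm_vt_closed_form(p, slow), 0.5, tolerance = 1e-6)
  # volume returns to baseline when expiration is long relative to tau
  wf <- simulate_scm(p, slow, n_cycles = 2)
  expect_lt(wf$volume[length(wf$volume)], 1e-6)
})

test_that("mechanics identification inverts the simulator exactly without noise", {
  set.seed(11)
  for (i in 1:5) {
    p <- draw_patient(i)
    s <- draw_settings()
    wf <- simulate_scm(p, s, P0 = s$PEEP, n_cycles = 2)
    f <- identify_mechanics(wf)
    expect_equal(f$E_hat, p$E, tolerance = 1e-8)
    expect_equal(f$R_hat, p$R, tolerance = 1e-8)
    expect_equal(f$P0_hat, s$PEEP, tolerance = 1e-8)
    expect_lt(f$residual_rms, 1e-8)
    # with the baseline pinned, E and R alone are recovered
    f2 <- identify_mechanics(wf, fix_P0 = s$PEEP)
    expect_equal(f2$E_hat, p$E, tolerance = 1e-8)
    expect_equal(f2$R_hat, p$R, tolerance = 1e-8)
  }
})

test_that("identification under pressure noise stays inside the frozen spread band", {
  # bands are ~5 sd of a 200-replicate run at noise_sd = 0.5 cmH2O
  p <- ref_cohort$P1
  for (i in 1:20) {
    wf <- noisy_waveform(p, ref_settings, noise_sd = 0.5, seed = 2000 + i)
    f <- identify_mechanics(wf)
    expect_lt(abs(f$E_hat - 20), 0.15)
    expect_lt(abs(f$R_hat - 10), 0.07)
    expect_lt(abs(f$P0_hat - 7), 0.035)
  }
})

test_that("degenerate waveforms are rejected as non-identifiable", {
  t <- seq(0, 1, by = 0.01)
  expect_error(
    identify_mechanics(breath_waveform(t, rep(10, length(t)),
                                       rep(0.3, length(t)),
                                       rep(0.2, length(t)))),
    "non-identifiable")
  wf <- simulate_scm(ref_cohort$P1, ref_settings, n_cycles = 1)
  short <- breath_waveform(wf$time[1:5], wf$pressure[1:5], wf$flow[1:5],
                           wf$volume[1:5])
  expect_error(identify_mechanics(short), "at least 10 samples")
})
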