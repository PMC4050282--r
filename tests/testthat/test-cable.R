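test_that("passive step response matches the closed-form RC charging curve", {
  m <- rc_cell(g_leak = 1e-4, e_leak = -80)
  area <- m$comp$area_cm2
  amp_pA <- 50
  tr <- run_simulation(m, protocol_current_step(amp_pA, onset_ms = 0,
                                                duration_ms = 100, rise_ms = 0),
                       solver_config(duration_ms = 100, settle_ms = 50))
  tau <- 1 / (1e-4) * 1e-3                      # R_m C_m in ms (C_m = 1 uF/cm2)
  rin <- 1 / (1e-4 * area)                      # Ohm
  dv_inf <- amp_pA * 1e-12 * rin * 1e3          # mV
  pred <- -80 + dv_inf * (1 - exp(-tr$time / tau))
  expect_lt(max(abs(tr$v[, 1] - pred)), 0.001 * dv_inf)
  # steady depolarization = I * R_in
  expect_equal(tr$v[nrow(tr$v), 1] + 80, dv_inf, tolerance = 1e-3)
})

test_that("zero-amplitude protocol leaves every compartment at rest", {
  m <- small_model()
  tr <- run_simulation(m, protocol_current_step(0),
                       solver_config(duration_ms = 40, settle_ms = 100))
  expect_lt(max(abs(tr$v - m$resting_potential_mV)), 0.5)
})

test_that("simulations are deterministic and respect the voltage bounds", {
  m <- small_model()
  cfg <- solver_config(duration_ms = 30, settle_ms = 50)
  p <- protocol_current_step(200, onset_ms = 5, duration_ms = 20)
  t1 <- run_simulation(m, p, cfg)
  t2 <- run_simulation(m, p, cfg)
  expect_identical(t1$v, t2$v)
  expect_error(
    run_simulation(m, protocol_current_step(80000, onset_ms = 1, duration_ms = 20), cfg),
    "solver failure")
})

test_that("synaptic trains scale with intensity and match the double-exponential", {
  t <- seq(0, 200, by = 0.01)
  expect_equal(protocol_current(make_synaptic_train(0), t), rep(0, length(t)))
  p1 <- make_synaptic_train(1, n_events = 1, unit_peak_pA = 40)
  w <- protocol_current(p1, t)
  expect_rel(max(w), 40, 0.01)                  # single event peaks at the set value
  # stronger train leads at every subthreshold level (monotone scaling)
  w2 <- protocol_current(make_synaptic_train(2, n_events = 1, unit_peak_pA = 40), t)
  expect_true(all(w2 >= w))
  expect_error(make_synaptic_train(1, rise_ms = -1), "positive")
})

test_that("forced-spike trains have the stated pulse timing", {
  p5 <- forced_spike_protocol(5, 20, onset_ms = 0)
  expect_equal(p5$onsets_ms, c(0, 50, 100, 150, 200))
  expect_equal(p5$baseline_pA, 0)               # hold at rest
  p100 <- forced_spike_protocol(100, 50, onset_ms = 0)
  expect_equal(length(p100$onsets_ms), 100)
  expect_equal(max(p100$onsets_ms), 1980)       # 2-s train
  pd <- forced_spike_protocol(5, 20, hold_at_rest = FALSE, depo_pA = 110)
  expect_equal(pd$baseline_pA, 110)
})

test_that("charge is conserved in the passive limit", {
  m <- build_granule_cell(list(resting_potential_mV = -80),
                          channels = passive_channels())
  p <- protocol_current_step(50, onset_ms = 5, duration_ms = 80, rise_ms = 0)
  tr <- run_simulation(m, p, solver_config(duration_ms = 120, settle_ms = 50))
  dt <- tr$dt_record
  q_in <- sum(protocol_current(p, tr$time) / 1000 * dt)            # pC
  cap <- m$cm_uF_cm2 * m$comp$area_cm2 * 1e3                       # nF
  q_cap <- sum(cap * (tr$v[nrow(tr$v), ] - tr$v[1, ]))
  q_leak <- sum(vapply(seq_len(ncol(tr$v)), function(j)
    sum(m$gleak_uS[j] * (tr$v[, j] - m$eleak_mV[j])) * dt, 0))
  expect_lt(abs(q_in - q_cap - q_leak) / q_in, 0.005)
})

test_that("halving dt shifts spike times by less than 10 us", {
  m <- small_model()
  sp <- function(dt) {
    tr <- run_simulation(m, protocol_current_step(150, onset_ms = 5, duration_ms = 40),
                         solver_config(dt = dt, duration_ms = 50, settle_ms = 100))
    detect_spikes(tr$v[, 1], tr$dt_record)$onset_ms[1]
  }
  expect_lt(abs(sp(0.01) - sp(0.005)) * 1000, 10)
})

test_that("ideal voltage clamp pins the somatic voltage to the command", {
  m <- small_model()
  tr <- run_simulation(m, protocol_voltage_clamp(-75, 10, onset_ms = 5, duration_ms = 5),
                       solver_config(duration_ms = 30, settle_ms = 50))
  i_on <- tr$time >= 5.1 & tr$time < 9.9
  expect_lt(max(abs(tr$v[i_on, 1] - 10)), 1e-6)
  expect_lt(max(abs(tr$v[tr$time < 4.9, 1] + 75)), 1e-6)
  # the step fires the axon (escape action current)
  ax <- site_index(tr, 100)
  expect_gte(nrow(detect_spikes(tr$v[, ax], tr$dt_record)), 1)
})
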