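test_that("spike detection recovers constructed onsets and ignores flat traces", {
  dt <- 0.05
  t <- seq(0, 50, by = dt)
  expect_equal(nrow(detect_spikes(rep(-70, length(t)), dt)), 0)
  expect_equal(nrow(detect_spikes(numeric(0), dt)), 0)
  # Gaussian-shaped dV/dt centred at 20 ms -> onset at the centre
  centre <- 20
  v <- -70 + 80 * pnorm(t, centre, 0.3)
  ev <- detect_spikes(v, dt)
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$onset_ms - centre), dt)
  expect_gt(ev$max_dvdt, 20)
  # two spikes separated beyond the refractory window
  v2 <- v + 80 * pnorm(t, 35, 0.3)
  expect_equal(nrow(detect_spikes(v2, dt)), 2)
})

test_that("latency profile reproduces a constant-conduction-velocity line", {
  dt <- 0.05
  t <- seq(0, 40, by = dt)
  x0 <- 25; vel <- 0.3                           # initiation site um, um/us
  mk <- function(tc) -70 + 80 * pnorm(t, tc, 0.25)
  soma_t <- 15 + x0 / vel / 1000                 # backpropagation to the soma
  dists <- c(25, 100, 200, 300)
  ax <- sapply(dists, function(x) mk(15 + abs(x - x0) / vel / 1000))
  prof <- latency_profile(mk(soma_t), ax, dists, dt, spike_indices = 1)
  expected <- (abs(dists - x0) - x0) / vel       # us
  expect_equal(prof$latency_us, expected, tolerance = 0.05)
  # identical site -> zero latency
  p0 <- latency_profile(mk(15), list(mk(15)), 0, dt, spike_indices = 1)
  expect_lt(abs(p0$latency_us), 1)
})

test_that("initiation site follows a relocated Na+ hotspot", {
  cfg <- default_channel_config()
  pr <- cfg$channels$Na_axonal$density$axon_main
  pr$center <- 60
  cfg$channels$Na_axonal$density$axon_main <- pr
  m <- small_model(channels = cfg)
  tr <- run_simulation(m, protocol_current_step(150, onset_ms = 5, duration_ms = 80),
                       solver_config(duration_ms = 100, settle_ms = 200))
  site <- initiation_site(tr, 1)
  expect_gte(site, 55)
  expect_lte(site, 65)
})

test_that("latency-shift regression matches constructed oracles", {
  d <- rep(seq(10, 190, by = 20), each = 2)
  prof <- data.frame(distance_um = rep(d, 2),
                     spike = rep(c(1L, 3L), each = length(d)),
                     latency_us = 0, trial = rep(seq_along(d), 2))
  class(prof) <- c("latency_profile", "data.frame")
  r0 <- latency_shift_regression(prof)
  expect_equal(r0$slope_us_per_um, 0)
  expect_equal(r0$p, 1)
  # exact line: change = -2 * x
  prof$latency_us[prof$spike == 3] <- -2 * d
  r1 <- latency_shift_regression(prof)
  expect_equal(r1$slope_us_per_um, -2, tolerance = 1e-9)
  expect_lt(r1$p, 1e-10)
  expect_error(latency_shift_regression(prof[prof$distance_um < 31, ]), "3 distinct")
})

test_that("spiking threshold criteria behave on constructed and simulated traces", {
  dt <- 0.02
  t <- seq(0, 60, by = dt)
  vstar <- -45
  ramp <- -75 + 0.75 * t                        # 0.75 mV/ms subthreshold ramp
  v <- ifelse(ramp < vstar, ramp, vstar + (ramp - vstar) * 200)  # spike takes off at V*
  v <- pmin(v, 30)
  th <- spiking_threshold(v, dt, criterion = "dvdt_crossing", dvdt_cross = 10)
  expect_lt(abs(th$threshold_mV - vstar), 1)
  run <- default_step_run()
  soma <- run$trace$v[, 1]
  for (crit in c("second_derivative_extremum", "dvdt_crossing")) {
    th <- spiking_threshold(soma, run$trace$dt_record, criterion = crit)
    expect_gt(th$threshold_mV, -79)
    expect_lt(th$threshold_mV, max(soma))
  }
  expect_error(spiking_threshold(rep(-70, 1000), dt), "no spike")
})

test_that("waveform distance-decay fit recovers a known length constant", {
  d <- seq(5, 250, by = 25)
  first <- data.frame(distance_um = d, amplitude = 100, rise_ms = 0.2)
  third <- first
  # identical waveforms -> zero change, fit not applicable
  w0 <- waveform_change_vs_distance(first, third)
  expect_true(all(w0$per_site$amp_change_pct == 0))
  expect_false(w0$fits$amplitude$applicable)
  # amplitude change -30% * exp(-x / 50)
  third$amplitude <- 100 * (1 - 0.30 * exp(-d / 50))
  third$rise_ms <- 0.2 * (1 + 0.90 * exp(-d / 50))
  w <- waveform_change_vs_distance(first, third)
  expect_rel(w$fits$amplitude$lambda_um, 50, 0.01)
  expect_rel(w$fits$amplitude$A_pct, -30, 0.01)
  expect_rel(w$fits$rise$lambda_um, 50, 0.01)
  expect_true(w$fits$rise$applicable)
})

test_that("propagation fidelity counts matched spikes", {
  dt <- 0.05
  t <- seq(0, 200, by = dt)
  mk <- function(times) {
    v <- rep(-70, length(t))
    for (tc in times) v <- v + 80 * pnorm(t, tc, 0.3)
    v
  }
  soma <- mk(seq(20, 160, by = 20))
  expect_equal(propagation_fidelity(soma, soma, dt), 1)
  axon <- mk(seq(20, 160, by = 40) + 0.4)       # every 2nd spike missing
  expect_equal(propagation_fidelity(soma, axon, dt), 0.5)
})

test_that("latency and regression outputs are invariant to loose-patch mixing", {
  run <- default_step_run()
  tr <- run$trace
  fs <- 20
  pure <- make_loose_patch_trace(tr, 100, loose_patch_mix(alpha = 0, beta = 1), fs_khz = fs)
  mixed <- make_loose_patch_trace(tr, 100, loose_patch_mix(alpha = 0.05, beta = 1), fs_khz = fs)
  e1 <- detect_spikes(pure$signal, 1 / fs, gate = 30)
  e2 <- detect_spikes(mixed$signal, 1 / fs, gate = 30)
  expect_equal(nrow(e1), nrow(e2))
  expect_lt(max(abs(e1$onset_ms - e2$onset_ms)), 1 / fs)   # within one sample
})
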