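test_that("Gaussian influx pulses integrate to the per-spike Na+ entry", {
  t <- seq(0, 40, by = 0.001)
  j <- gaussian_influx(t, t0 = 20, sigma = 0.5, dna_tot = 0.4)
  expect_lt(abs(sum(j) * 0.001 - 0.4), 1e-4)
  expect_lt(gaussian_influx(26, 20, 0.5, 0.4), 1e-12)       # |t - t0| > 10 sigma
  # doubling sigma halves the peak at fixed total entry
  expect_rel(gaussian_influx(20, 20, 1.0, 0.4) / gaussian_influx(20, 20, 0.5, 0.4),
             0.5, 1e-9)
})

test_that("the Na+/SBFI system respects equilibrium and mass conservation", {
  p0 <- na_kinetic_params(dna_per_spike = 0)
  s0 <- simulate_na_system(p0, 100, dt = 0.01)
  expect_equal(max(abs(s0$na - p0$Na_rest)), 0)
  # bound:free ratio at equilibrium equals Na_rest / K_D
  expect_equal(s0$nasbfi[1] / s0$sbfi_free[1], p0$Na_rest / p0$K_D, tolerance = 1e-12)

  p <- na_kinetic_params(t0_ms = sbfi_protocol_times("5AP20Hz"))
  s <- simulate_na_system(p, 600, dt = 0.01)
  # indicator conservation is structural; total-Na balance to 1e-6 mM
  expect_lt(max(abs(s$sbfi_free + s$nasbfi - p$SBFI_total)), 1e-12)
  bal <- s$entered - s$removed - (s$na - s$na[1]) - (s$nasbfi - s$nasbfi[1])
  expect_lt(max(abs(bal)), 1e-6)
  expect_error(simulate_na_system(p, 10, dt = 1), "stability")
})

test_that("post-pulse indicator relaxation matches the linearized rate", {
  p <- na_kinetic_params(P_Na = 0, D_Na = 0, t0_ms = 10)
  s <- simulate_na_system(p, 150, dt = 0.01)
  # linearized relaxation rate: kon [Na] + koff (~ 1/14 ms at the defaults)
  i <- s$time_ms > 15 & s$time_ms < 50
  dev <- s$nasbfi[length(s$nasbfi)] - s$nasbfi
  fit <- lm(log(dev[i]) ~ s$time_ms[i])
  rate_meas <- -coef(fit)[2]
  rate_theory <- p$kon_mM_ms * mean(s$na[i]) + p$k_off
  expect_rel(rate_meas, rate_theory, 0.1)
  expect_rel(1 / rate_theory, 14, 0.15)
})

test_that("the explicit scheme agrees with an independent adaptive integrator", {
  library(deSolve)
  p <- na_kinetic_params(t0_ms = 20)
  rhs <- function(t, y, parms) {
    j <- gaussian_influx(t, 20, p$sigma, p$dna_per_spike)
    sb <- p$SBFI_total - y[2]
    bind <- p$kon_mM_ms * y[1] * sb - p$k_off * y[2]
    list(c(j - bind - (p$P_Na + p$D_Na_ms) * (y[1] - p$Na_rest), bind))
  }
  y0 <- c(na = p$Na_rest,
          nasb = p$SBFI_total * p$Na_rest / (p$Na_rest + p$K_D))
  ode <- lsoda(y0, seq(0, 300, 0.5), rhs, NULL, rtol = 1e-10, atol = 1e-12)
  mine <- simulate_na_system(p, 300.5, dt = 0.005)
  na_i <- approx(mine$time_ms, mine$na, xout = ode[, 1])$y
  nasb_i <- approx(mine$time_ms, mine$nasbfi, xout = ode[, 1])$y
  expect_lt(max(abs(na_i - ode[, "na"])), 1e-3)
  expect_lt(max(abs(nasb_i - ode[, "nasb"])), 1e-3)
})

test_that("SBFI fluorescence is negative-going and staircase-like during a train", {
  p <- na_kinetic_params(t0_ms = sbfi_protocol_times("5AP20Hz"))
  s <- simulate_na_system(p, 400, dt = 0.01, record_every = 5)
  fl <- sbfi_fluorescence(s, brightness_ratio = 0.5)
  expect_equal(fl$dff[1], 0)
  expect_lt(min(fl$dff), -0.01)                  # a few-% negative transient
  # staircase: the level shortly after each spike lies below the previous one
  lev <- vapply(p$t0_ms, function(t0) fl$dff[which.min(abs(fl$time_ms - (t0 + 20)))], 0)
  expect_true(all(diff(lev) < 0))
  # no binding change -> flat
  s0 <- simulate_na_system(na_kinetic_params(dna_per_spike = 0), 100, dt = 0.01)
  expect_true(all(sbfi_fluorescence(s0)$dff == 0))
})

test_that("k_on is recovered from noiseless and noisy step-response traces", {
  gen <- function(kon) make_sbfi_fixture(
    na_kinetic_params(k_on = kon, P_Na = 0, D_Na = 0), protocol = "step")
  for (kon in c(2.0, 1.0)) {
    ts <- gen(kon)
    fit <- fit_kon(ts$time_ms, ts$dff, t0_ms = 20)
    expect_rel(fit$k_on, kon, 0.01)
  }
  # 5% Gaussian noise on dF/F, 20 repeats: median within 10%
  ts <- gen(2.0)
  amp <- max(abs(ts$dff))
  ests <- vapply(1:20, function(i) {
    noisy <- ts$dff + with_seed(1000 + i, rnorm(length(ts$dff), 0, 0.05 * amp))
    fit_kon(ts$time_ms, noisy, t0_ms = 20)$k_on
  }, 0)
  expect_rel(median(ests), 2.0, 0.1)
})

test_that("the two-protocol joint fit recovers entry and extrusion parameters", {
  t5 <- make_sbfi_fixture(protocol = "5AP20Hz")
  t100 <- make_sbfi_fixture(protocol = "100AP50Hz")
  fit <- fit_dna_pna(t5, t100)
  expect_rel(fit$dna_mM, 0.4, 0.02)
  expect_rel(fit$pna_ms, 0.0022, 0.02)
  expect_false(fit$at_bounds)
  expect_true(fit$pna_identifiable)
  # degenerate: no entry -> entry fitted at zero, extrusion flagged
  p0 <- na_kinetic_params(dna_per_spike = 0)
  z5 <- make_sbfi_fixture(p0, protocol = "5AP20Hz")
  z100 <- make_sbfi_fixture(p0, protocol = "100AP50Hz")
  fz <- fit_dna_pna(z5, z100)
  expect_lt(fz$dna_mM, 1e-4)
  expect_false(fz$pna_identifiable)
})

test_that("recovery holds across a grid of generating parameters", {
  for (dna in c(0.2, 0.4, 0.8)) {
    for (pna in c(0.001, 0.0022, 0.005)) {
      p <- na_kinetic_params(dna_per_spike = dna, P_Na = pna)
      t5 <- make_sbfi_fixture(p, protocol = "5AP20Hz")
      t100 <- make_sbfi_fixture(p, protocol = "100AP50Hz")
      fit <- fit_dna_pna(t5, t100, n_starts = 2)
      expect_rel(fit$dna_mM, dna, 0.05)
      expect_rel(fit$pna_ms, pna, 0.05)
    }
  }
})

test_that("fitted parameters are insensitive to the influx half-width", {
  base <- fit_dna_pna(make_sbfi_fixture(protocol = "5AP20Hz"),
                      make_sbfi_fixture(protocol = "100AP50Hz"), n_starts = 2)
  p2 <- na_kinetic_params(sigma = 1.0)
  wide <- fit_dna_pna(make_sbfi_fixture(p2, protocol = "5AP20Hz"),
                      make_sbfi_fixture(p2, protocol = "100AP50Hz"), n_starts = 2)
  expect_rel(wide$dna_mM, base$dna_mM, 0.03)
  expect_rel(wide$pna_ms, base$pna_ms, 0.03)
})

test_that("entry and extrusion act on nearly orthogonal features of the signal", {
  peak_of <- function(dna, pna) {
    p <- na_kinetic_params(dna_per_spike = dna, P_Na = pna,
                           t0_ms = sbfi_protocol_times("5AP20Hz"))
    fl <- sbfi_fluorescence(simulate_na_system(p, 800, dt = 0.02, record_every = 10))
    # first-spike increment: the amplitude feature the entry parameter scales
    list(peak = -fl$dff[which.min(abs(fl$time_ms - 50))],
         decay = {
           i <- fl$time_ms > 260
           dev <- -fl$dff[i]
           -coef(lm(log(dev) ~ fl$time_ms[i]))[2]
         })
  }
  b <- peak_of(0.4, 0.0022)
  dp <- peak_of(0.44, 0.0022)      # +10% entry
  dq <- peak_of(0.4, 0.00242)      # +10% extrusion
  # relative sensitivities: diagonal terms dominate by > 10x
  peak_dna <- abs(dp$peak / b$peak - 1)
  peak_pna <- abs(dq$peak / b$peak - 1)
  dec_dna <- abs(dp$decay / b$decay - 1)
  dec_pna <- abs(dq$decay / b$decay - 1)
  expect_gt(peak_dna / max(peak_pna, 1e-12), 10)
  expect_gt(dec_pna / max(dec_dna, 1e-12), 10)
})

test_that("a 20 pmol flux in a half-micron axon translates to 1.6 mM/s", {
  expect_equal(membrane_flux_to_rate(20, 0.5), 1.6, tolerance = 1e-12)
  expect_equal(membrane_flux_to_rate(40, 0.5), 3.2, tolerance = 1e-12)
  expect_equal(membrane_flux_to_rate(20, 1), 0.8, tolerance = 1e-12)
})
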