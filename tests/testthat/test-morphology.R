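test_that("section and tree validation reject malformed morphologies", {
  expect_error(section("a", NA, 0, 1, 100, 1, "soma"), "length")
  expect_error(section("a", NA, 10, -1, 100, 1, "soma"), "diameter")
  expect_error(
    validate_sections(list(section("soma", NA, 10, 10, 100, 1, "soma"),
                           section("soma", "soma", 5, 1, 100, 1, "axon_main"))),
    "duplicate")
  # cycle / missing parent
  expect_error(
    validate_sections(list(section("soma", NA, 10, 10, 100, 1, "soma"),
                           section("ax", "nope", 5, 1, 100, 1, "axon_main"))),
    "unknown parent")
  expect_error(
    validate_sections(list(section("a", "b", 10, 10, 100, 1, "soma"),
                           section("b", "a", 5, 1, 100, 1, "axon_main"))),
    "exactly one root")
})

test_that("density profiles evaluate as specified", {
  u <- density_profile("uniform", baseline = 0.03)
  expect_equal(density_at(u, c(0, 10, 500)), rep(0.03, 3))
  g <- density_profile("gaussian_hotspot", baseline = 0.01, peak = 0.4,
                       center = 25, width = 10)
  expect_equal(density_at(g, 25), 0.41)
  # one width from the centre: baseline + peak * exp(-1/2)
  g0 <- density_profile("gaussian_hotspot", baseline = 0, peak = 0.2,
                        center = 25, width = 10)
  expect_equal(density_at(g0, 35), 0.2 * exp(-0.5), tolerance = 1e-12)
  pw <- density_profile("piecewise_linear", x = c(0, 100), y = c(0.1, 0.3))
  expect_equal(density_at(pw, c(0, 50, 100, 200)), c(0.1, 0.2, 0.3, 0.3))
  expect_error(density_at(u, -5), "distance")
  expect_error(density_profile("gaussian_hotspot", baseline = -1), ">= 0")
})

test_that("gating curves are monotone and depolarization removes availability", {
  cfg <- default_channel_config()
  v <- seq(-100, 60, by = 2)
  for (ch in cfg$channels) {
    for (g in ch$gates) {
      if (g$exponent == 0) next
      x <- gate_steady(g, v)
      if (g$slope > 0) expect_true(all(diff(x) > 0)) else
        expect_true(all(diff(x) < 0))
      expect_true(all(gate_tau(g, v) > 0))
    }
  }
  na_ax <- cfg$channels$Na_axonal
  # the mechanistic premise: holding at -40 mV leaves fewer available channels
  expect_lt(channel_availability(na_ax, -40), channel_availability(na_ax, -79))
  expect_gt(channel_availability(na_ax, -79), 0.5)
})

test_that("leak-only model rests at the leak reversal and the default model is balanced", {
  m0 <- build_granule_cell(list(resting_potential_mV = -80),
                           channels = passive_channels())
  expect_equal(unique(round(m0$eleak_mV, 9)), -80)
  tr <- run_simulation(m0, protocol_current_step(0),
                       solver_config(duration_ms = 30, settle_ms = 100))
  expect_lt(max(abs(tr$v + 80)), 0.5)

  m <- default_step_run()$model
  # net membrane current at -79 mV below 1e-3 mA/cm2 in every compartment
  expect_lt(max(abs(resting_current_density(m))), 1e-3)
  expect_equal(m$resting_potential_mV, -79)
  # leak battery stays within ~1.5 mV of its -80 mV nominal value
  expect_lt(max(abs(m$eleak_mV + 80)), 1.5)
})

test_that("morphology invariants of the default cell hold", {
  m <- build_granule_cell()
  ax <- m$comp[m$comp$kind == "axon_main", ]
  expect_gte(max(ax$distance_um), 500)
  expect_true(all(ax$length_um[ax$distance_um <= 200] <= 5))
  # axonal Na density profile attains its maximum in the 20-25 um band
  prof <- m$channels$channels$Na_axonal$density$axon_main
  xg <- seq(0, 200, by = 0.5)
  expect_true(xg[which.max(density_at(prof, xg))] >= 15 &&
              xg[which.max(density_at(prof, xg))] <= 25)
  expect_error(build_granule_cell(list(axon_length_um = 300)), ">= 500")
})

test_that("SWC round trip preserves geometry and kinds", {
  m <- build_granule_cell(list(collaterals = TRUE))
  f <- tempfile(fileext = ".swc")
  coll <- write_swc(m, f)
  secs <- read_swc(f, collateral_ids = coll)
  expect_equal(sum(sapply(secs, `[[`, "length_um")),
               sum(sapply(m$sections, `[[`, "length_um")), tolerance = 1e-6)
  kinds <- table(sapply(secs, `[[`, "kind"))
  expect_equal(unname(kinds["axon_collateral"]), 2)
  expect_equal(unname(kinds["soma"]), 1)
  d_ax <- sapply(secs, function(s) if (s$kind == "axon_main") s$diameter_um else NA)
  expect_equal(unique(round(stats::na.omit(d_ax), 6)), 0.5)
  # the re-imported morphology assembles into a working model
  m2 <- cable_model(secs, default_channel_config())
  expect_s3_class(m2, "cable_model")
})
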