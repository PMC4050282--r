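# Shared fixtures. Expensive simulations are computed once per test session
# and cached; every fixture is built in code from the package's own
# generators.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Default granule-cell model under the 130-pA depolarizing step
# ("Depo+Spikes": suprathreshold somatic depolarization).
default_step_run <- function() cached("step_run", {
  m <- build_granule_cell()
  list(model = m,
       trace = run_simulation(
         m, protocol_current_step(130, onset_ms = 10, duration_ms = 220),
         solver_config(duration_ms = 250, settle_ms = 300)))
})

# "Spikes only": brief suprathreshold pulses from rest, 5 at 20 Hz.
spikes_only_run <- function() cached("spikes_only", {
  m <- default_step_run()$model
  run_simulation(m, forced_spike_protocol(5, 20, hold_at_rest = TRUE),
                 solver_config(duration_ms = 250, settle_ms = 300))
})

# Reduced morphology for cheap solver tests (same proximal resolution).
small_model <- function(channels = default_channel_config(), ...) {
  build_granule_cell(modifyList(list(axon_length_um = 500, distal_dx_um = 20,
                                     dend_length_um = 150), list(...)),
                     channels = channels)
}

# Purely passive variant of a channel configuration (all densities zeroed).
passive_channels <- function() {
  cfg <- default_channel_config()
  for (nm in names(cfg$channels)) {
    for (kd in names(cfg$channels[[nm]]$density)) {
      pr <- cfg$channels[[nm]]$density[[kd]]
      pr$baseline <- 0
      pr$peak <- 0
      if (!is.null(pr$y)) pr$y <- 0 * pr$y
      cfg$channels[[nm]]$density[[kd]] <- pr
    }
  }
  cfg
}

# Single-compartment passive cell for closed-form RC checks.
rc_cell <- function(g_leak = 1e-4, e_leak = -80) {
  cfg <- passive_channels()
  cfg$leak$g_S_cm2[] <- g_leak
  cfg$leak$erev <- e_leak
  secs <- list(section("soma", NA, 20, 20, 150, 1L, "soma"))
  cable_model(secs, cfg, resting_potential = e_leak, balance_leak = FALSE)
}

expect_rel <- function(object, expected, tol) {
  expect_lt(abs(object / expected - 1), tol)
}
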