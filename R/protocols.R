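new_protocol <- function(kind, site, ...) {
  structure(c(list(kind = kind, site = site), list(...)), class = "stim_protocol")
}

#' Somatic current-step protocol
#'
#' @param amplitude_pA step amplitude, pA.
#' @param onset_ms,duration_ms step timing, ms.
#' @param rise_ms linear command rise time, ms (finite electrode/amplifier
#'   slew; avoids an unphysical instantaneous capacitive transient).
#' @param site list(section, pos) of the injection site (defaults to the soma).
#' @return a `stim_protocol`.
#' @export
protocol_current_step <- function(amplitude_pA, onset_ms = 10, duration_ms = 200,
                                  rise_ms = 1,
                                  site = list(section = "soma", pos = 0.5)) {
  if (duration_ms <= 0 || onset_ms < 0) stop("step timing must be nonnegative with duration > 0")
  new_protocol("current_step", site, amplitude_pA = amplitude_pA,
               onset_ms = onset_ms, duration_ms = duration_ms, rise_ms = rise_ms)
}

#' Brief-pulse train protocol, with or without holding depolarization
#'
#' Trains of brief suprathreshold pulses force time-locked spikes. With
#' `baseline_pA = 0` ("spikes only") the membrane sits at rest between pulses;
#' a positive baseline superimposes a constant subthreshold depolarizing
#' current ("depolarization + spikes").
#'
#' @param n_pulses,rate_hz train geometry.
#' @param pulse_pA,pulse_ms pulse amplitude (pA) and width (ms).
#' @param baseline_pA constant holding current between pulses, pA.
#' @param onset_ms time of the first pulse, ms.
#' @param baseline_from_ms onset of the holding current, ms.
#' @inheritParams protocol_current_step
#' @return a `stim_protocol`.
#' @export
protocol_pulse_train <- function(n_pulses, rate_hz, pulse_pA = 2000, pulse_ms = 0.5,
                                 baseline_pA = 0, onset_ms = 20, baseline_from_ms = 5,
                                 site = list(section = "soma", pos = 0.5)) {
  if (n_pulses < 1 || rate_hz <= 0) stop("n_pulses and rate must be positive")
  if (pulse_ms <= 0) stop("pulse width must be > 0")
  onsets <- onset_ms + (seq_len(n_pulses) - 1) * 1000 / rate_hz
  new_protocol("pulse_train", site, pulse_pA = pulse_pA, pulse_ms = pulse_ms,
               baseline_pA = baseline_pA, onsets_ms = onsets,
               baseline_from_ms = baseline_from_ms)
}

#' Forced-spike protocol ("Spikes only" vs "Depo+Spikes")
#'
#' Convenience wrapper around [protocol_pulse_train()] using 0.5-ms
#' suprathreshold pulses. `hold_at_rest = TRUE` keeps the inter-pulse baseline
#' current at zero so spikes occur without sustained depolarization;
#' `hold_at_rest = FALSE` adds the constant subthreshold `depo_pA`.
#'
#' @param n_spikes,rate_hz train geometry (e.g. 5 at 20 Hz, 100 at 50 Hz).
#' @param hold_at_rest logical, see above.
#' @param depo_pA holding current used when `hold_at_rest = FALSE`, pA.
#' @param pulse_pA pulse amplitude, pA.
#' @param onset_ms first pulse time, ms.
#' @return a `stim_protocol`.
#' @export
forced_spike_protocol <- function(n_spikes, rate_hz, hold_at_rest = TRUE,
                                  depo_pA = 110, pulse_pA = 3000, onset_ms = 20) {
  if (n_spikes < 1 || rate_hz <= 0) stop("n_spikes and rate must be positive")
  protocol_pulse_train(n_spikes, rate_hz, pulse_pA = pulse_pA, pulse_ms = 0.5,
                       baseline_pA = if (hold_at_rest) 0 else depo_pA,
                       onset_ms = onset_ms, baseline_from_ms = 5)
}

#' Synaptic-train protocol of configurable intensity
#'
#' Sum of double-exponential current events (each
#' `peak * (exp(-t/decay) - exp(-t/rise))`, normalized so a single event
#' reaches `intensity * unit_peak_pA`), mimicking a train of dendrosomatic
#' synaptic discharges. Varying `intensity` over ~1-8 spans somatic
#' depolarization rise times from a few ms to well over 100 ms.
#'
#' @param intensity dimensionless scale on the per-event peak (0 allowed).
#' @param n_events,rate_hz event train geometry (default 10 events at 100 Hz).
#' @param rise_ms,decay_ms event kinetics, ms (must be positive, rise < decay).
#' @param unit_peak_pA per-event peak at intensity 1, pA.
#' @param onset_ms first event time, ms.
#' @inheritParams protocol_current_step
#' @return a `stim_protocol`.
#' @export
make_synaptic_train <- function(intensity, n_events = 10, rate_hz = 100,
                                rise_ms = 1, decay_ms = 20, unit_peak_pA = 25,
                                onset_ms = 10,
                                site = list(section = "soma", pos = 0.5)) {
  if (n_events < 1) stop("n_events must be >= 1")
  if (rise_ms <= 0 || decay_ms <= 0) stop("kinetic constants must be positive")
  if (rise_ms >= decay_ms) stop("rise must be shorter than decay")
  if (intensity < 0) stop("intensity must be >= 0")
  onsets <- onset_ms + (seq_len(n_events) - 1) * 1000 / rate_hz
  new_protocol("synaptic_train", site, intensity = intensity,
               rise_ms = rise_ms, decay_ms = decay_ms,
               unit_peak_pA = unit_peak_pA, onsets_ms = onsets)
}

#' Ideal somatic voltage-step clamp protocol
#'
#' Clamps one site to `v_hold`, stepping to `v_step` during
#' `[onset, onset + duration]` (the protocol used to evoke a brief pulse of
#' Na+ entry through rapidly inactivating channels, e.g. -75 to +10 mV).
#'
#' @param v_hold_mV,v_step_mV holding and step voltage, mV.
#' @param onset_ms,duration_ms step timing, ms.
#' @inheritParams protocol_current_step
#' @return a `stim_protocol`.
#' @export
protocol_voltage_clamp <- function(v_hold_mV = -75, v_step_mV = 10,
                                   onset_ms = 10, duration_ms = 5,
                                   site = list(section = "soma", pos = 0.5)) {
  if (duration_ms <= 0 || onset_ms < 0) stop("step timing must be nonnegative with duration > 0")
  new_protocol("voltage_step_clamp", site, v_hold_mV = v_hold_mV,
               v_step_mV = v_step_mV, onset_ms = onset_ms, duration_ms = duration_ms)
}

#' Evaluate a protocol's current waveform on a time grid
#'
#' @param protocol a `stim_protocol` (current-based kinds only).
#' @param t time grid, ms.
#' @return injected current in pA at each time.
#' @export
protocol_current <- function(protocol, t) {
  switch(protocol$kind,
    current_step = {
      r <- protocol$rise_ms %||% 0
      u <- t - protocol$onset_ms
      on <- u >= 0 & u < protocol$duration_ms
      ramp <- if (r > 0) pmin(u / r, 1) else 1
      ifelse(on, protocol$amplitude_pA * ramp, 0)
    },
    pulse_train = {
      i <- ifelse(t >= protocol$baseline_from_ms, protocol$baseline_pA, 0)
      for (on in protocol$onsets_ms)
        i <- i + ifelse(t >= on & t < on + protocol$pulse_ms, protocol$pulse_pA, 0)
      i
    },
    synaptic_train = {
      r <- protocol$rise_ms; d <- protocol$decay_ms
      tp <- r * d / (d - r) * log(d / r)
      norm <- 1 / (exp(-tp / d) - exp(-tp / r))
      i <- numeric(length(t))
      for (on in protocol$onsets_ms) {
        u <- t - on
        act <- u > 0
        i[act] <- i[act] + protocol$intensity * protocol$unit_peak_pA * norm *
          (exp(-u[act] / d) - exp(-u[act] / r))
      }
      i
    },
    stop("protocol kind '", protocol$kind, "' has no current waveform"))
}
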