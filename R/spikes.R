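# Sub-sample refinement of a discrete extremum by parabolic interpolation.
# Returns list(offset in samples within [-0.5, 0.5], refined value).
parabolic_refine <- function(y, i) {
  n <- length(y)
  if (i <= 1L || i >= n) return(list(offset = 0, value = y[i]))
  den <- y[i - 1] - 2 * y[i] + y[i + 1]
  if (abs(den) < .Machine$double.eps) return(list(offset = 0, value = y[i]))
  off <- 0.5 * (y[i - 1] - y[i + 1]) / den
  off <- max(-0.5, min(0.5, off))
  list(offset = off, value = y[i] - 0.25 * (y[i - 1] - y[i + 1]) * off)
}

#' Detect spikes in a single-site trace by its rate of rise
#'
#' Spike onsets are timed at the maximum of the first derivative,
#' (dV/dt)max: events are local maxima of dV/dt exceeding `gate`, separated
#' by at least `refractory_ms`, with sub-sample timing by parabolic
#' interpolation. Works on membrane voltage and on loose-patch-style signals
#' alike (units then arbitrary). A flat or empty trace yields zero events.
#'
#' @param v sampled signal (mV or a.u.).
#' @param dt sampling interval, ms.
#' @param gate detection threshold on dV/dt, V s^-1 (signal units/ms).
#' @param refractory_ms minimum event separation, ms.
#' @param rise_bounds fractional amplitudes defining the rise time
#'   (default 20-80% of baseline-to-peak).
#' @param t0_ms time of the first sample, ms.
#' @return data.frame of spike events: `spike` (index within train),
#'   `onset_ms` (time of (dV/dt)max), `peak_ms`, `peak`, `baseline`,
#'   `amplitude`, `max_dvdt` (V s^-1), `rise_ms`.
#' @export
detect_spikes <- function(v, dt, gate = 20, refractory_ms = 2,
                          rise_bounds = c(0.2, 0.8), t0_ms = 0) {
  stopifnot(gate > 0, dt > 0)
  empty <- data.frame(spike = integer(), onset_ms = numeric(), peak_ms = numeric(),
                      peak = numeric(), baseline = numeric(), amplitude = numeric(),
                      max_dvdt = numeric(), rise_ms = numeric())
  n <- length(v)
  if (n < 5) return(empty)
  dv <- trace_dvdt(v, dt)
  cand <- which(dv > gate)
  cand <- cand[cand > 1 & cand < n]
  cand <- cand[dv[cand] >= dv[cand - 1] & dv[cand] >= dv[cand + 1]]
  if (!length(cand)) return(empty)
  # enforce refractory window, keeping the larger peak
  keep <- integer(0)
  for (i in cand) {
    if (length(keep) && (i - keep[length(keep)]) * dt < refractory_ms) {
      if (dv[i] > dv[keep[length(keep)]]) keep[length(keep)] <- i
    } else keep <- c(keep, i)
  }
  win <- max(1L, round(refractory_ms / dt))
  ev <- lapply(seq_along(keep), function(k) {
    i <- keep[k]
    ref <- parabolic_refine(dv, i)
    onset <- t0_ms + (i - 1 + ref$offset) * dt
    hi <- if (k < length(keep)) keep[k + 1] - 1L else n
    hi <- min(hi, i + max(win, round(10 / dt)))
    jpk <- i + which.max(v[i:hi]) - 1L
    pk <- parabolic_refine(v, jpk)
    lo <- max(1L, i - win)
    base <- min(v[lo:i])
    amp <- pk$value - base
    th <- base + rise_bounds * amp
    seg <- v[lo:jpk]
    tt <- t0_ms + (seq.int(lo, jpk) - 1) * dt
    cross <- vapply(th, function(h) {
      j <- which(seg >= h)[1]
      if (is.na(j) || j == 1L) return(tt[1])
      tt[j - 1] + dt * (h - seg[j - 1]) / (seg[j] - seg[j - 1])
    }, 0)
    data.frame(spike = k, onset_ms = onset,
               peak_ms = t0_ms + (jpk - 1 + pk$offset) * dt,
               peak = pk$value, baseline = base, amplitude = amp,
               max_dvdt = ref$value, rise_ms = max(cross[2] - cross[1], dt / 100))
  })
  do.call(rbind, ev)
}

#' Soma-axon spike latency profile
#'
#' For each axonal recording site, pairs axonal with somatic spikes by index
#' (with a conduction-window sanity check) and reports the latency
#' `t_a - t_s` in microseconds, both spikes timed at their (dV/dt)max.
#' Negative latencies mean the axonal spike leads the somatic one.
#'
#' @param soma_v somatic voltage samples, mV.
#' @param axon_v matrix (samples x sites) or list of axonal signals.
#' @param distances_um axial distance of each axonal site, um.
#' @param dt sampling interval, ms.
#' @param spike_indices which spikes of the train to report.
#' @param gate,axon_gate detection thresholds for soma / axon signals.
#' @param trial trial identifier stored with the records.
#' @param pair_window_ms maximum |t_a - t_s| accepted as the same spike, ms.
#' @return data.frame (class `latency_profile`): `distance_um`, `spike`,
#'   `latency_us`, `trial`. Sites whose spike count does not cover a requested
#'   index are dropped with a warning.
#' @export
latency_profile <- function(soma_v, axon_v, distances_um, dt,
                            spike_indices = c(1, 3), gate = 20,
                            axon_gate = gate, trial = 1L, pair_window_ms = 2) {
  if (is.matrix(axon_v)) axon_v <- lapply(seq_len(ncol(axon_v)), function(j) axon_v[, j])
  stopifnot(length(axon_v) == length(distances_um))
  se <- detect_spikes(soma_v, dt, gate = gate)
  recs <- list(); dropped <- character(0)
  for (j in seq_along(axon_v)) {
    ae <- detect_spikes(axon_v[[j]], dt, gate = axon_gate)
    for (k in spike_indices) {
      if (nrow(se) < k || nrow(ae) < k) {
        dropped <- c(dropped, sprintf("%g um (spike %d)", distances_um[j], k))
        next
      }
      lat <- ae$onset_ms[k] - se$onset_ms[k]
      if (abs(lat) > pair_window_ms) {
        dropped <- c(dropped, sprintf("%g um (spike %d: pairing window)", distances_um[j], k))
        next
      }
      recs[[length(recs) + 1L]] <- data.frame(
        distance_um = distances_um[j], spike = k, latency_us = lat * 1000,
        trial = trial)
    }
  }
  if (length(dropped))
    warning("latency records dropped at: ", paste(dropped, collapse = "; "))
  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(distance_um = numeric(), spike = integer(),
               latency_us = numeric(), trial = integer())
  class(out) <- c("latency_profile", "data.frame")
  out
}

#' Latency profile of a simulated run, over all main-axon compartments
#'
#' @param trace a `state_trace` from [run_simulation()].
#' @param max_distance_um restrict to axonal sites within this distance
#'   (the experimental recording range; also keeps conduction delays inside
#'   the pairing window).
#' @inheritParams latency_profile
#' @return see [latency_profile()].
#' @export
model_latency_profile <- function(trace, spike_indices = c(1, 3), gate = 20,
                                  max_distance_um = 400, pair_window_ms = 2) {
  soma <- trace$v[, site_index(trace, 0, kind = "soma")]
  sel <- which(trace$comp$kind == "axon_main" &
               trace$comp$distance_um <= max_distance_um)
  latency_profile(soma, trace$v[, sel, drop = FALSE],
                  trace$comp$distance_um[sel], trace$dt_record,
                  spike_indices = spike_indices, gate = gate,
                  pair_window_ms = pair_window_ms)
}

#' Summarize a latency profile per (distance, spike index)
#'
#' @param profile a [latency_profile()].
#' @return data.frame with mean, s.d. and n of `latency_us`.
#' @export
summarize_latency <- function(profile) {
  sp <- split(profile, list(profile$distance_um, profile$spike), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) data.frame(
    distance_um = d$distance_um[1], spike = d$spike[1],
    mean_us = mean(d$latency_us),
    sd_us = if (nrow(d) > 1) sd(d$latency_us) else NA_real_, n = nrow(d))))
  rownames(out) <- NULL
  out[order(out$spike, out$distance_um), ]
}

#' Locate the action-potential initiation site of a simulated spike
#'
#' The initiation site is the compartment (soma or main axon) whose
#' (dV/dt)max for the given spike index occurs earliest; its axial distance
#' is returned (0 for the soma by convention, also for a model without
#' axonal compartments).
#'
#' @param trace a `state_trace` with all compartments recorded.
#' @param spike_index which spike of the train.
#' @param gate detection threshold, V s^-1.
#' @return distance from the soma-axon junction, um.
#' @export
initiation_site <- function(trace, spike_index = 1, gate = 20) {
  sel <- which(trace$comp$kind %in% c("soma", "axon_main"))
  if (!any(trace$comp$kind == "axon_main")) return(0)
  onsets <- rep(NA_real_, length(sel))
  for (j in seq_along(sel)) {
    ev <- detect_spikes(trace$v[, sel[j]], trace$dt_record, gate = gate)
    if (nrow(ev) >= spike_index) onsets[j] <- ev$onset_ms[spike_index]
  }
  if (anyNA(onsets)) {
    miss <- trace$comp$distance_um[sel[is.na(onsets)]]
    stop("spike ", spike_index, " not detected at site(s): ",
         paste(sprintf("%.1f um", utils::head(miss, 5)), collapse = ", "),
         if (sum(is.na(onsets)) > 5) " ..." else "")
  }
  d <- trace$comp$distance_um[sel]
  d[is.na(d)] <- 0
  d[which.min(onsets)]
}

#' Spiking threshold of a somatic trace
#'
#' Extracts the somatic voltage at spike onset using either the extremum of
#' the second derivative within the pre-peak window (ending at the
#' (dV/dt)max; the `extremum` argument selects min -- as conventionally
#' printed with threshold-from-onset plots -- or max), or the voltage at
#' which dV/dt first crosses a fixed value.
#'
#' @param v somatic voltage, mV.
#' @param dt sampling interval, ms.
#' @param criterion `"second_derivative_extremum"` or `"dvdt_crossing"`.
#' @param spike spike index within the train.
#' @param gate spike-detection threshold, V s^-1.
#' @param dvdt_cross crossing level for `"dvdt_crossing"`, V s^-1.
#' @param extremum `"min"` or `"max"` of d2V/dt2 for the derivative criterion.
#' @return list: `threshold_mV`, `criterion`, `time_ms`, `spike`,
#'   `depol_rise_ms` (time from leaving the pre-stimulus baseline to
#'   threshold).
#' @export
spiking_threshold <- function(v, dt,
                              criterion = c("second_derivative_extremum", "dvdt_crossing"),
                              spike = 1, gate = 20, dvdt_cross = 10,
                              extremum = c("min", "max")) {
  criterion <- match.arg(criterion)
  extremum <- match.arg(extremum)
  ev <- detect_spikes(v, dt, gate = gate)
  if (nrow(ev) < spike) stop("no spike at index ", spike)
  ipk <- max(2L, round(ev$onset_ms[spike] / dt) + 1L)   # sample of (dV/dt)max
  dv <- trace_dvdt(v, dt)
  # pre-peak window: from take-off (dv below 2% of max, or prev spike) to peak
  lo <- if (spike > 1) round(ev$peak_ms[spike - 1] / dt) + 1L else 1L
  takeoff <- which(dv[lo:ipk] < max(1, 0.02 * ev$max_dvdt[spike]))
  wlo <- if (length(takeoff)) lo + takeoff[length(takeoff)] - 1L else lo
  wlo <- max(2L, wlo)
  if (criterion == "dvdt_crossing") {
    j <- which(dv[wlo:ipk] >= dvdt_cross)[1]
    if (is.na(j)) j <- ipk - wlo + 1L
    i <- wlo + j - 1L
    if (i > 1 && dv[i] != dv[i - 1]) {
      f <- (dvdt_cross - dv[i - 1]) / (dv[i] - dv[i - 1])
      thr <- v[i - 1] + f * (v[i] - v[i - 1])
      tthr <- (i - 2 + f) * dt
    } else { thr <- v[i]; tthr <- (i - 1) * dt }
  } else {
    d2 <- trace_dvdt(dv, dt)
    seg <- d2[wlo:ipk]
    j <- if (extremum == "min") which.min(seg) else which.max(seg)
    i <- wlo + j - 1L
    ref <- parabolic_refine(d2, i)
    thr <- v[i]
    tthr <- (i - 1 + ref$offset) * dt
  }
  base <- v[1]
  dep <- which(abs(v[seq_len(max(1L, i))] - base) < 1)
  rise <- tthr - (if (length(dep)) (dep[length(dep)] - 1) * dt else 0)
  list(threshold_mV = thr, criterion = criterion, time_ms = tthr,
       spike = spike, depol_rise_ms = rise)
}

#' Regression of the first-to-third-spike latency change on axonal distance
#'
#' Computes the per-site latency change between two spike indices
#' (third minus first by default), restricts to a proximal distance range,
#' and fits an ordinary least-squares line; the p-value is the two-sided
#' Student's t-test on the slope.
#'
#' @param profile a [latency_profile()] containing both spike indices (or the
#'   first-spike profile, with `profile_third` giving the second).
#' @param profile_third optional second profile.
#' @param range_um distance range included, um.
#' @param spike_indices the pair of spike indices compared.
#' @return list: `slope_us_per_um`, `se`, `p`, `n`, `intercept_us`.
#' @export
latency_shift_regression <- function(profile, profile_third = NULL,
                                     range_um = c(0, 200), spike_indices = c(1, 3)) {
  if (!is.null(profile_third)) {
    profile_third$spike <- spike_indices[2]
    profile$spike <- spike_indices[1]
    profile <- rbind(as.data.frame(profile), as.data.frame(profile_third))
  }
  a <- profile[profile$spike == spike_indices[1], ]
  b <- profile[profile$spike == spike_indices[2], ]
  m <- merge(a, b, by = c("distance_um", "trial"), suffixes = c("_1", "_3"))
  m <- m[m$distance_um >= range_um[1] & m$distance_um <= range_um[2], ]
  if (length(unique(m$distance_um)) < 3)
    stop("need >= 3 distinct distances within the range")
  x <- m$distance_um
  y <- m$latency_us_3 - m$latency_us_1
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit))$coefficients   # exact fits are legitimate here
  slope <- unname(sm["x", "Estimate"])
  se <- unname(sm["x", "Std. Error"])
  p <- unname(sm["x", "Pr(>|t|)"])
  if (!is.finite(se) || se < 1e-12) {            # noiseless degenerate fits
    se <- 0
    p <- if (abs(slope) < 1e-9) 1 else 0
  }
  list(slope_us_per_um = slope, se = se, p = p, n = nrow(m),
       intercept_us = unname(coef(fit)[1]))
}

#' Waveform changes of later vs first spikes along the axon
#'
#' Per-site percentage changes in amplitude and rise time between paired
#' first- and third-spike events, with mono-exponential distance-decay fits
#' `y(x) = A exp(-x / lambda)` (lambda constrained positive). A fit on
#' non-decaying or flat data is reported as not applicable rather than an
#' error.
#'
#' @param events_first,events_third data.frames with one row per site and
#'   columns `distance_um`, `amplitude`, `rise_ms` (as from
#'   [detect_spikes()], one site per row).
#' @return list: `per_site` data.frame with `amp_change_pct`,
#'   `rise_change_pct`; `fits$amplitude` and `fits$rise`, each
#'   `list(A_pct, lambda_um, applicable)`.
#' @export
waveform_change_vs_distance <- function(events_first, events_third) {
  stopifnot(nrow(events_first) == nrow(events_third))
  m <- data.frame(
    distance_um = events_first$distance_um,
    amp_change_pct = 100 * (events_third$amplitude / events_first$amplitude - 1),
    rise_change_pct = 100 * (events_third$rise_ms / events_first$rise_ms - 1))
  fit1 <- function(y) {
    if (all(abs(y) < 1e-9) || length(y) < 3)
      return(list(A_pct = NA_real_, lambda_um = NA_real_, applicable = FALSE))
    df <- data.frame(x = m$distance_um, y = y)
    f <- tryCatch(
      minpack.lm::nlsLM(y ~ A * exp(-x / lambda), data = df,
                        start = list(A = y[which.min(df$x)], lambda = 50),
                        lower = c(A = -Inf, lambda = 1e-3),
                        upper = c(A = Inf, lambda = 1e6),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(f)) return(list(A_pct = NA_real_, lambda_um = NA_real_, applicable = FALSE))
    co <- coef(f)
    decaying <- abs(y[which.min(df$x)]) > abs(y[which.max(df$x)])
    list(A_pct = unname(co["A"]), lambda_um = unname(co["lambda"]),
         applicable = decaying && is.finite(co["lambda"]))
  }
  list(per_site = m,
       fits = list(amplitude = fit1(m$amp_change_pct),
                   rise = fit1(m$rise_change_pct)))
}

#' Fraction of somatic spikes that propagate to a distal axonal site
#'
#' Somatic and axonal spikes are matched by conduction delay: an axonal event
#' within `window_ms` of (somatic onset + median delay) counts as propagated.
#'
#' @param soma_v,axon_v voltage/signal traces from the same run.
#' @param dt sampling interval, ms.
#' @param gate,axon_gate detection thresholds.
#' @param window_ms matching half-window, ms.
#' @return fraction in `[0, 1]` (1 when no somatic spikes).
#' @export
propagation_fidelity <- function(soma_v, axon_v, dt, gate = 20,
                                 axon_gate = gate, window_ms = 2) {
  se <- detect_spikes(soma_v, dt, gate = gate)
  if (!nrow(se)) return(1)
  ae <- detect_spikes(axon_v, dt, gate = axon_gate)
  if (!nrow(ae)) return(0)
  # conduction delay: the nearest-pair delay that supports the most matches
  del <- vapply(se$onset_ms, function(t) ae$onset_ms[which.min(abs(ae$onset_ms - t))] - t, 0)
  nmatch <- vapply(del, function(d0)
    sum(vapply(se$onset_ms, function(t)
      any(abs(ae$onset_ms - t - d0) <= window_ms), TRUE)), 0)
  d0 <- del[which.max(nmatch)]
  mean(vapply(se$onset_ms, function(t)
    any(abs(ae$onset_ms - t - d0) <= window_ms), TRUE))
}
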