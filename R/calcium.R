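#' Construct a fluorescence trace with background and pre-stimulus markers
#'
#' @param time_ms sample times, ms.
#' @param f fluorescence, a.u.
#' @param f0 background fluorescence (no indicator), a.u.
#' @param f_pre pre-stimulus fluorescence; must exceed `f0`, otherwise the
#'   baseline normalization is undefined.
#' @return a `fluo_trace`.
#' @export
fluo_trace <- function(time_ms, f, f0, f_pre) {
  stopifnot(length(time_ms) == length(f))
  if (f_pre <= f0) stop("F_pre must exceed F_0 (quantification undefined)")
  structure(list(time_ms = time_ms, f = f, f0 = f0, f_pre = f_pre),
            class = "fluo_trace")
}

#' Baseline-normalized fluorescence increment dF/F_B
#'
#' Applies `dF/F_B = (F - F_pre) / (F_pre - F_0)`, the background-subtracted
#' pre-stimulus normalization used for Fluo-4 Ca2+ transients.
#'
#' @param trace a [fluo_trace()].
#' @return numeric vector, the dF/F_B series.
#' @export
fluo4_dff <- function(trace) {
  stopifnot(inherits(trace, "fluo_trace"))
  (trace$f - trace$f_pre) / (trace$f_pre - trace$f0)
}

#' Late-to-early fluorescence increment ratio of a stimulus response
#'
#' Mean background-subtracted fluorescence increments over the early
#' (0-40 ms post onset) and late (40-200 ms) windows, returned as
#' `(F_late - F_B) / (F_early - F_B)` with `F_B` the pre-stimulus baseline.
#' With jittered, depolarization-evoked spike trains this ratio reports
#' whether Ca2+ entry is sustained (ratio high) or progressively suppressed
#' (ratio low) over the train.
#'
#' @param trace a [fluo_trace()].
#' @param onset_ms stimulus onset, ms; the trace must cover onset + 200 ms.
#' @param windows_ms early/late window edges post onset, ms.
#' @return scalar ratio.
#' @export
early_late_ratio <- function(trace, onset_ms, windows_ms = c(0, 40, 200)) {
  stopifnot(inherits(trace, "fluo_trace"))
  t <- trace$time_ms
  if (max(t) < onset_ms + windows_ms[3]) stop("trace must cover onset + 200 ms")
  early <- t >= onset_ms + windows_ms[1] & t < onset_ms + windows_ms[2]
  late <- t >= onset_ms + windows_ms[2] & t <= onset_ms + windows_ms[3]
  fe <- mean(trace$f[early]) - trace$f_pre     # background cancels against F_B
  fl <- mean(trace$f[late]) - trace$f_pre
  if (abs(fe) < .Machine$double.eps) stop("F_early equals the baseline; ratio undefined")
  fl / fe
}

#' Per-spike fluorescence increment ratio dF3/dF1
#'
#' For time-locked spikes, measures each spike's fluorescence increment as the
#' difference between a short post-spike mean and the local pre-spike baseline
#' extrapolated to the same window (a line fitted over the pre-window, so that
#' slow trends -- indicator decay, sustained depolarization-driven entry -- do
#' not bias the step estimate), and returns the third-to-first ratio.
#'
#' @param trace a [fluo_trace()].
#' @param spike_times_ms spike onset times (>= 3 required).
#' @param spikes pair of spike indices to compare (default third vs first).
#' @param win_ms averaging window on each side of a spike, ms.
#' @return list: `ratio`, `increments` (per spike, dF/F_B units).
#' @export
dff_spike_ratio <- function(trace, spike_times_ms, spikes = c(1, 3), win_ms = 5) {
  stopifnot(inherits(trace, "fluo_trace"))
  if (length(spike_times_ms) < 3) stop("need at least 3 time-locked spikes")
  dff <- fluo4_dff(trace)
  t <- trace$time_ms
  inc <- vapply(spike_times_ms, function(ts) {
    pre <- t >= ts - win_ms & t < ts
    post <- t > ts + 1 & t <= ts + win_ms
    if (sum(pre) < 2 || !any(post)) return(NA_real_)
    bl <- lm(y ~ x, data = data.frame(x = t[pre], y = dff[pre]))
    mean(dff[post]) - mean(predict(bl, data.frame(x = t[post])))
  }, 0)
  list(ratio = inc[spikes[2]] / inc[spikes[1]], increments = inc)
}

#' Per-spike ionic-charge increments along the axon
#'
#' Integrates a recorded channel current density over each spike window at
#' every axonal compartment, after subtracting the local pre-spike holding
#' current, giving the spike-evoked charge entry per membrane area. Spike
#' windows are derived from the somatic spike train; overlapping windows are
#' an error naming the offending spikes.
#'
#' @param trace a `state_trace` with the channel current recorded.
#' @param channel recorded channel name (default the generic Ca2+ channel).
#' @param spike_onsets_ms somatic spike onsets; detected from the somatic
#'   voltage when `NULL`.
#' @param window_ms integration window after each onset, ms.
#' @param pre_ms lead time before the onset included in the window, ms.
#' @param baseline_ms pre-window span defining the holding-current baseline, ms.
#' @param gate somatic spike-detection threshold, V s^-1.
#' @return data.frame (class `ca_increment_profile`): `distance_um`, `spike`,
#'   `increment_nC_cm2` (>= 0).
#' @export
per_spike_ca_increment <- function(trace, channel = "Ca_generic",
                                   spike_onsets_ms = NULL, window_ms = 8,
                                   pre_ms = 0.5, baseline_ms = 2, gate = 20) {
  if (!channel %in% names(trace$currents))
    stop("channel '", channel, "' was not recorded in this trace")
  if (is.null(spike_onsets_ms)) {
    soma <- trace$v[, site_index(trace, 0, kind = "soma")]
    ev <- detect_spikes(soma, trace$dt_record, gate = gate)
    if (!nrow(ev)) stop("no somatic spikes detected")
    spike_onsets_ms <- ev$onset_ms
  }
  starts <- spike_onsets_ms - pre_ms
  ends <- spike_onsets_ms + window_ms
  if (any(starts[-1] < ends[-length(ends)])) {
    bad <- which(starts[-1] < ends[-length(ends)])
    stop("overlapping spike windows for spikes ",
         paste(bad, bad + 1, sep = "/", collapse = ", "),
         "; reduce window_ms")
  }
  im <- trace$currents[[channel]]
  t <- trace$time_ms %||% trace$time
  sel <- which(trace$comp$kind == "axon_main")
  dt <- trace$dt_record
  recs <- list()
  for (k in seq_along(spike_onsets_ms)) {
    win <- t >= starts[k] & t <= ends[k]
    base <- t >= starts[k] - baseline_ms & t < starts[k]
    for (j in sel) {
      i_in <- -im[win, j]                               # inward current positive
      i_b <- if (any(base)) mean(-im[base, j]) else 0
      q <- sum(i_in - i_b) * dt * 1e3                   # mA/cm2 * ms -> uC/cm2 -> nC/cm2
      recs[[length(recs) + 1L]] <- data.frame(
        distance_um = trace$comp$distance_um[j], spike = k,
        increment_nC_cm2 = max(q, 0))
    }
  }
  out <- do.call(rbind, recs)
  class(out) <- c("ca_increment_profile", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ratio of spike-evoked Ca2+ increments along the axon
#'
#' @param profile a [per_spike_ca_increment()] result.
#' @param spikes pair of spike indices (default third vs first).
#' @return data.frame `distance_um`, `ratio` (defined only where the
#'   first-spike increment is positive).
#' @export
ca_increment_ratio <- function(profile, spikes = c(1, 3)) {
  a <- profile[profile$spike == spikes[1], ]
  b <- profile[profile$spike == spikes[2], ]
  m <- merge(a, b, by = "distance_um", suffixes = c("_1", "_3"))
  m <- m[m$increment_nC_cm2_1 > 0, ]
  data.frame(distance_um = m$distance_um,
             ratio = m$increment_nC_cm2_3 / m$increment_nC_cm2_1)
}
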