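#' Noise specification for synthetic recordings
#'
#' Additive Gaussian noise scaled to the signal baseline, with an optional
#' multiplicative (shot-noise-like) component; a stand-in for photon noise.
#'
#' @param additive_sd s.d. of additive noise as a fraction of the baseline
#'   signal magnitude (default 5%).
#' @param shot_scale scale of multiplicative noise (0 = none).
#' @param seed RNG seed.
#' @return a `noise_spec`.
#' @export
noise_spec <- function(additive_sd = 0.05, shot_scale = 0, seed = 1) {
  if (additive_sd < 0 || shot_scale < 0) stop("noise scales must be >= 0")
  structure(list(additive_sd = additive_sd, shot_scale = shot_scale, seed = seed),
            class = "noise_spec")
}

apply_noise <- function(y, noise, baseline = NULL) {
  if (is.null(noise) || (noise$additive_sd == 0 && noise$shot_scale == 0)) return(y)
  b <- if (is.null(baseline)) max(abs(y), .Machine$double.eps) else baseline
  with_seed(noise$seed, {
    out <- y + rnorm(length(y), 0, noise$additive_sd * b)
    if (noise$shot_scale > 0)
      out <- out * (1 + rnorm(length(y), 0, noise$shot_scale))
    out
  })
}

#' Write / read a two-column trace with provenance header
#'
#' Delimited-text container for time series: `#`-prefixed header lines carry
#' provenance key-value pairs, followed by a comma-separated table. Files
#' round-trip bit-exactly through these functions.
#'
#' @param x data.frame to write.
#' @param path file path.
#' @param provenance named list written into the header.
#' @return `read_trace_csv`: the data.frame with attribute `provenance`.
#' @export
write_trace_csv <- function(x, path, provenance = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(provenance))
    writeLines(sprintf("# %s: %s", nm, paste(format(provenance[[nm]], digits = 17),
                                             collapse = " ")), con)
  writeLines(paste(names(x), collapse = ","), con)
  writeLines(do.call(paste, c(lapply(x, format, digits = 17), sep = ",")), con)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  prov <- list()
  for (l in lines[hdr]) {
    kv <- sub("^#\\s*", "", l)
    k <- sub(":.*$", "", kv)
    v <- trimws(sub("^[^:]*:", "", kv))
    num <- suppressWarnings(as.numeric(strsplit(v, " +")[[1]]))
    prov[[k]] <- if (anyNA(num)) v else num
  }
  body <- lines[!hdr]
  df <- read.table(text = body, header = TRUE, sep = ",")
  attr(df, "provenance") <- prov
  df
}

#' Generate a synthetic SBFI fluorescence trace file
#'
#' Forward-simulates the Na+/SBFI kinetic model under one of the standard
#' protocols, adds measurement noise, and (optionally) writes a delimited
#' trace with provenance (parameters and seed) embedded. Sampling emulates a
#' 2-kHz linescan.
#'
#' @param params a [na_kinetic_params()]; its `t0_ms` is replaced by the
#'   protocol's spike times.
#' @param protocol `"step"`, `"5AP20Hz"` or `"100AP50Hz"`.
#' @param noise a [noise_spec()] or `NULL` for noiseless output.
#' @param path optional output file.
#' @param fs_khz sampling rate, kHz.
#' @param post_ms recording continued after the last spike, ms.
#' @param brightness_ratio bound:free SBFI brightness.
#' @param dt simulation step, ms.
#' @return data.frame `time_ms`, `dff` with attribute `provenance`.
#' @export
make_sbfi_fixture <- function(params = na_kinetic_params(),
                              protocol = c("step", "5AP20Hz", "100AP50Hz"),
                              noise = NULL, path = NULL, fs_khz = 2,
                              post_ms = NULL, brightness_ratio = 0.5,
                              dt = 0.01) {
  protocol <- match.arg(protocol)
  t0 <- sbfi_protocol_times(protocol)
  params <- modifyList(params, list(t0_ms = t0))
  class(params) <- "na_kinetic_params"
  if (is.null(post_ms))
    post_ms <- switch(protocol, step = 150, "5AP20Hz" = 800, "100AP50Hz" = 1500)
  dur <- max(t0) + post_ms
  sim <- simulate_na_system(params, dur, dt = dt,
                            record_every = max(1L, round(1 / (fs_khz * dt))))
  fl <- sbfi_fluorescence(sim, brightness_ratio)
  df <- data.frame(time_ms = fl$time_ms,
                   dff = apply_noise(fl$dff, noise, baseline = 1))
  prov <- list(protocol = protocol, k_on = params$k_on, K_D = params$K_D,
               P_Na = params$P_Na, D_Na = params$D_Na,
               SBFI_total = params$SBFI_total, Na_rest = params$Na_rest,
               dna_per_spike = params$dna_per_spike, sigma = params$sigma,
               brightness_ratio = brightness_ratio, fs_khz = fs_khz,
               seed = if (is.null(noise)) NA else noise$seed)
  attr(df, "provenance") <- prov
  if (!is.null(path)) write_trace_csv(df, path, prov)
  df
}

#' Loose-patch mixing weights
#'
#' A loose-patch axonal recording is modelled as
#' `alpha * V(t) + beta * dV/dt(t)` plus noise -- predominantly the first
#' derivative of membrane voltage.
#'
#' @param alpha weight of V.
#' @param beta weight of dV/dt.
#' @param noise a [noise_spec()] or `NULL`.
#' @return a `loose_patch_mix`.
#' @export
loose_patch_mix <- function(alpha = 0.1, beta = 1, noise = NULL) {
  if (alpha == 0 && beta == 0) stop("alpha and beta cannot both be zero")
  structure(list(alpha = alpha, beta = beta, noise = noise),
            class = "loose_patch_mix")
}

#' Synthesize a loose-patch axonal recording from a simulated trace
#'
#' Extracts one recorded site, forms the V / dV/dt mixture and resamples to
#' the acquisition rate (20 kHz default, matching dual-patch recordings).
#'
#' @param trace a `state_trace`.
#' @param distance_um axonal site to record, um.
#' @param mix a [loose_patch_mix()].
#' @param fs_khz output sampling rate.
#' @return data.frame `time_ms`, `signal` (a.u.) with attribute
#'   `distance_um`.
#' @export
make_loose_patch_trace <- function(trace, distance_um, mix = loose_patch_mix(),
                                   fs_khz = 20) {
  i <- site_index(trace, distance_um)
  v <- trace$v[, i]
  dv <- trace_dvdt(v, trace$dt_record)
  sig <- mix$alpha * v + mix$beta * dv
  tt <- seq(min(trace$time), max(trace$time), by = 1 / fs_khz)
  out <- data.frame(time_ms = tt,
                    signal = apply_noise(approx(trace$time, sig, xout = tt)$y,
                                         mix$noise))
  attr(out, "distance_um") <- trace$comp$distance_um[i]
  out
}

#' Synthetic Fluo-4 fluorescence from simulated Ca2+ currents
#'
#' Linear-indicator forward model: the Ca2+-dependent fluorescence increment
#' is proportional to cumulative Ca2+ influx convolved with a
#' single-exponential indicator decay (no saturation, matching the absence of
#' distance-dependent saturation in the recordings).
#'
#' @param trace a `state_trace` with the Ca2+ current recorded.
#' @param distance_um axonal site, um.
#' @param tau_ms indicator decay time constant, ms.
#' @param gain fluorescence units per unit cumulative charge.
#' @param f0,f_pre background and pre-stimulus fluorescence, a.u.
#' @param noise a [noise_spec()] or `NULL`.
#' @param fs_khz output sampling rate (2 kHz linescan-equivalent).
#' @return a [fluo_trace()].
#' @export
make_fluo_trace <- function(trace, distance_um, tau_ms = 150, gain = 2000,
                            f0 = 10, f_pre = 30, noise = NULL, fs_khz = 2) {
  if (!"Ca_generic" %in% names(trace$currents))
    stop("trace lacks a recorded Ca2+ current")
  i <- site_index(trace, distance_um)
  ica <- -trace$currents$Ca_generic[, i]          # inward positive, mA/cm2
  ica <- pmax(ica - mean(ica[seq_len(max(2, round(2 / trace$dt_record)))]), 0)
  dt <- trace$dt_record
  # cumulative influx with exponential indicator decay (discrete convolution)
  decay <- exp(-dt / tau_ms)
  df <- numeric(length(ica))
  for (k in 2:length(ica)) df[k] <- df[k - 1] * decay + ica[k] * dt
  tt <- seq(min(trace$time), max(trace$time), by = 1 / fs_khz)
  f <- f_pre + gain * (f_pre - f0) * approx(trace$time, df, xout = tt)$y
  f <- apply_noise(f, noise, baseline = f_pre - f0)
  fluo_trace(tt, f, f0 = f0, f_pre = f_pre)
}

#' Write a Monte Carlo latency dataset to a delimited file
#'
#' Delegates to [simulate_latency_dataset()] and stores the dataset with its
#' config and seed in the provenance header.
#'
#' @param config an [mc_latency_config()].
#' @param path output file.
#' @return the dataset, invisibly.
#' @export
make_latency_fixture <- function(config, path) {
  ds <- simulate_latency_dataset(config)
  cfg <- attr(ds, "config")
  prov <- cfg[vapply(cfg, function(x) is.numeric(x) || is.character(x), TRUE)]
  write_trace_csv(as.data.frame(ds), path, provenance = prov)
  invisible(ds)
}
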