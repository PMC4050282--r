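# Evaluate a function with a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Configuration of the stochastic initiation-zone latency model
#'
#' Monte Carlo model of soma-axon spike latencies when the initiation site is
#' drawn from an axonal zone: for each trial an initiation site `x*` is drawn
#' from the zone of the given spike index, and the measured latency at a
#' recording position `x` is the travel time between `x*` and `x` at the
#' local conduction velocity, minus the somatic arrival term, plus Gaussian
#' measurement noise. Somatic activation is electrotonically driven and is
#' modelled as a constant delay plus the *excess* proximal travel time
#' incurred when conduction is decelerated (`T(x*) - x*/v`; zero at baseline
#' velocity), so use-dependent proximal slow-down delays the somatic spike as
#' well. The first spike uses a short zone (5 um centred at 22.5 um); the
#' third spike an expanded zone (110 um starting at 20 um, the observed
#' 100-120 um spread) and a proximally decelerated velocity
#' `v(x) = v / (1 + decel_factor exp(-x / decel_lambda_um))` (local spike
#' slow-down, strongest near the soma).
#'
#' @param zone_center_first_um,zone_length_first_um first-spike zone, um.
#' @param zone_start_third_um,zone_length_third_um third-spike zone, um.
#' @param distribution initiation-site distribution within the zone:
#'   `"uniform"` or `"truncated_gaussian"` (s.d. = length/4).
#' @param v_um_ms baseline conduction velocity, um ms^-1.
#' @param decel_factor proximal deceleration of the third spike (0 = none).
#' @param decel_lambda_um deceleration length constant, um.
#' @param soma_delay_ms constant somatic arrival delay, ms.
#' @param rec_range_um recording-position sampling range, um.
#' @param noise_sd_us measurement noise s.d., us.
#' @param n_points number of simulated (distance, latency) pairs.
#' @param seed RNG seed recorded in the output provenance.
#' @return an `mc_latency_config`.
#' @export
mc_latency_config <- function(zone_center_first_um = 22.5, zone_length_first_um = 5,
                              zone_start_third_um = 20, zone_length_third_um = 110,
                              distribution = c("uniform", "truncated_gaussian"),
                              v_um_ms = 180, decel_factor = 1,
                              decel_lambda_um = 43, soma_delay_ms = 0.125,
                              rec_range_um = c(10, 350), noise_sd_us = 50,
                              n_points = 1000, seed = 1) {
  distribution <- match.arg(distribution)
  if (zone_length_first_um < 0 || zone_length_third_um < 0) stop("zone lengths must be >= 0")
  if (v_um_ms <= 0) stop("conduction velocity must be > 0")
  if (decel_factor < 0) stop("decel_factor must be >= 0")
  if (noise_sd_us < 0) stop("noise s.d. must be >= 0")
  if (n_points < 1) stop("n_points must be >= 1")
  structure(as.list(environment()), class = "mc_latency_config")
}

# Cumulative travel time T(x) (ms) on a fine grid for velocity profile v(x).
travel_time_fun <- function(v_um_ms, decel_factor, decel_lambda_um, x_max) {
  x <- seq(0, x_max, by = 0.25)
  slow <- 1 / (v_um_ms / (1 + decel_factor * exp(-x / decel_lambda_um)))
  tt <- c(0, cumsum((slow[-1] + slow[-length(slow)]) / 2 * diff(x)))
  function(q) approx(x, tt, xout = q, rule = 2)$y
}

draw_sites <- function(n, lo, hi, distribution) {
  if (hi <= lo) return(rep(lo, n))
  if (distribution == "uniform") return(runif(n, lo, hi))
  mid <- (lo + hi) / 2; s <- (hi - lo) / 4
  x <- rnorm(n, mid, s)
  while (any(bad <- x < lo | x > hi)) x[bad] <- rnorm(sum(bad), mid, s)
  x
}

#' Simulate a stochastic initiation-zone latency dataset
#'
#' For each trial, draws a recording position and, for spike indices 1 and 3,
#' an initiation site from the respective zone; latencies are computed as
#' described in [mc_latency_config()]. Bit-exactly reproducible from
#' (config, seed).
#'
#' @param config an [mc_latency_config()].
#' @return data.frame (classes `latency_dataset`, `latency_profile`):
#'   `distance_um`, `spike`, `latency_us`, `trial`; the config is attached as
#'   attribute `config`.
#' @export
simulate_latency_dataset <- function(config) {
  stopifnot(inherits(config, "mc_latency_config"))
  with_seed(config$seed, {
    n <- config$n_points
    x <- runif(n, config$rec_range_um[1], config$rec_range_um[2])
    z1 <- config$zone_center_first_um + c(-0.5, 0.5) * config$zone_length_first_um
    z3 <- config$zone_start_third_um + c(0, config$zone_length_third_um)
    xmax <- max(config$rec_range_um, z1, z3) + 1
    T1 <- travel_time_fun(config$v_um_ms, 0, config$decel_lambda_um, xmax)
    T3 <- travel_time_fun(config$v_um_ms, config$decel_factor,
                          config$decel_lambda_um, xmax)
    s1 <- draw_sites(n, z1[1], z1[2], config$distribution)
    s3 <- draw_sites(n, z3[1], z3[2], config$distribution)
    # somatic arrival: constant electrotonic delay + excess proximal travel
    # time over the baseline velocity (zero for the non-decelerated spike)
    soma1 <- config$soma_delay_ms + (T1(s1) - s1 / config$v_um_ms)
    soma3 <- config$soma_delay_ms + (T3(s3) - s3 / config$v_um_ms)
    lat1 <- (abs(T1(x) - T1(s1)) - soma1) * 1000 + rnorm(n, 0, config$noise_sd_us)
    lat3 <- (abs(T3(x) - T3(s3)) - soma3) * 1000 + rnorm(n, 0, config$noise_sd_us)
    out <- rbind(
      data.frame(distance_um = x, spike = 1L, latency_us = lat1, trial = seq_len(n)),
      data.frame(distance_um = x, spike = 3L, latency_us = lat3, trial = seq_len(n)))
    attr(out, "config") <- config
    class(out) <- c("latency_dataset", "latency_profile", "data.frame")
    out
  })
}

#' Regression test for initiation-zone expansion on a Monte Carlo dataset
#'
#' Per-trial latency change (third minus first spike) regressed on recording
#' distance within the proximal range; two-sided t-test on the slope. Zone
#' expansion predicts a negative slope.
#'
#' @param dataset a [simulate_latency_dataset()] result.
#' @param range_um distance range, um.
#' @return list: `slope_us_per_um`, `se`, `p`, `n`.
#' @export
mc_regression_test <- function(dataset, range_um = c(0, 200)) {
  latency_shift_regression(dataset, range_um = range_um)
}

#' Latency standard deviation per spike index
#'
#' @param dataset a latency dataset/profile.
#' @param breaks_um optional distance-bin edges for per-bin s.d.
#' @return data.frame `spike` (and `bin` when binned), `sd_us`, `n`;
#'   singleton groups are skipped with a warning.
#' @export
latency_sd_by_spike <- function(dataset, breaks_um = NULL) {
  g <- if (is.null(breaks_um)) list(spike = dataset$spike) else
    list(spike = dataset$spike,
         bin = cut(dataset$distance_um, breaks_um, include.lowest = TRUE))
  sp <- split(seq_len(nrow(dataset)), g, drop = TRUE)
  small <- vapply(sp, length, 0L) < 2
  if (any(small)) {
    warning("singleton group(s) skipped: ", paste(names(sp)[small], collapse = ", "))
    sp <- sp[!small]
  }
  out <- do.call(rbind, lapply(names(sp), function(nm) {
    i <- sp[[nm]]
    d <- data.frame(spike = dataset$spike[i][1], sd_us = sd(dataset$latency_us[i]),
                    n = length(i))
    if (!is.null(breaks_um)) d$bin <- sub("^[0-9]+\\.", "", nm)
    d
  }))
  rownames(out) <- NULL
  out
}
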