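#' Define a gating variable for a Hodgkin-Huxley-type channel
#'
#' Steady state is a Boltzmann function of voltage,
#' `x_inf(V) = 1 / (1 + exp((vhalf - V)/slope))`: a positive `slope` gives an
#' activation gate (increasing with depolarization), a negative slope an
#' inactivation gate. The time constant is either constant, a Gaussian bump of
#' voltage (`tau = p1 + p2 exp(-(V - p3)^2 / (2 p4^2))`), or a descending
#' sigmoid (`tau = p1 + p2 / (1 + exp((V - p3)/p4))`, large when
#' hyperpolarized) used for slow inactivation whose recovery at rest takes
#' hundreds of milliseconds.
#'
#' @param name gate label (e.g. "m", "h", "n", "s").
#' @param exponent integer power in the open-probability product; 0 disables
#'   the gate.
#' @param vhalf half-activation voltage, mV.
#' @param slope Boltzmann slope, mV (non-zero; sign sets act./inact.).
#' @param tau list with `kind` in `c("constant", "gaussian", "sigmoid")` and
#'   parameters `p1..p4` in ms / mV as above.
#' @return a `gate` object.
#' @export
gate <- function(name, exponent, vhalf, slope, tau) {
  if (slope == 0) stop("gate '", name, "': slope must be non-zero")
  kinds <- c(constant = 0L, gaussian = 1L, sigmoid = 2L)
  if (!tau$kind %in% names(kinds)) stop("unknown tau kind: ", tau$kind)
  tau <- modifyList(list(p1 = 0, p2 = 0, p3 = 0, p4 = 1), tau)
  g <- list(name = name, exponent = exponent, vhalf = vhalf, slope = slope,
            taukind = unname(kinds[tau$kind]), p1 = tau$p1, p2 = tau$p2,
            p3 = tau$p3, p4 = tau$p4)
  # time constants must stay positive over the simulated voltage range
  v <- seq(-100, 60, by = 1)
  if (any(gate_tau(g, v) <= 0)) stop("gate '", name, "': tau <= 0 within [-100, 60] mV")
  structure(g, class = "gate")
}

#' Steady-state open fraction of a gate
#' @param g a [gate()].
#' @param v voltage, mV (vectorized).
#' @return open fraction in (0, 1).
#' @export
gate_steady <- function(g, v) 1 / (1 + exp((g$vhalf - v) / g$slope))

#' Voltage-dependent time constant of a gate
#' @inheritParams gate_steady
#' @return time constant, ms.
#' @export
gate_tau <- function(g, v) {
  tau <- switch(g$taukind + 1L,
    rep(g$p1, length(v)),
    g$p1 + g$p2 * exp(-0.5 * ((v - g$p3) / g$p4)^2),
    g$p1 + g$p2 / (1 + exp((v - g$p3) / g$p4)))
  pmax(tau, 1e-4)
}

#' Distance-dependent conductance density profile
#'
#' @param kind `"uniform"`, `"gaussian_hotspot"` or `"piecewise_linear"`.
#' @param baseline baseline density, S cm^-2.
#' @param peak added peak density for `gaussian_hotspot`, S cm^-2.
#' @param center peak position, um from the soma-axon junction.
#' @param width Gaussian width, um.
#' @param x,y breakpoints for `piecewise_linear` (densities interpolated,
#'   constant beyond the range).
#' @return a `density_profile` object.
#' @export
density_profile <- function(kind = c("uniform", "gaussian_hotspot", "piecewise_linear"),
                            baseline = 0, peak = 0, center = 0, width = 1,
                            x = NULL, y = NULL) {
  kind <- match.arg(kind)
  if (baseline < 0 || peak < 0) stop("densities must be >= 0")
  if (kind == "gaussian_hotspot" && width <= 0) stop("hotspot width must be > 0")
  if (kind == "piecewise_linear") {
    if (is.null(x) || is.null(y) || length(x) != length(y) || length(x) < 2)
      stop("piecewise_linear requires matching breakpoints x, y")
    if (any(y < 0)) stop("densities must be >= 0")
  }
  structure(list(kind = kind, baseline = baseline, peak = peak, center = center,
                 width = width, x = x, y = y), class = "density_profile")
}

#' Evaluate a density profile at axial distances from the soma
#'
#' `gaussian_hotspot` returns `baseline + peak * exp(-(x - center)^2 / (2 width^2))`.
#'
#' @param profile a [density_profile()].
#' @param distance_um distances, um (>= 0; vectorized).
#' @return conductance densities, S cm^-2.
#' @export
density_at <- function(profile, distance_um) {
  if (any(distance_um < 0)) stop("distance must be >= 0")
  switch(profile$kind,
    uniform = rep(profile$baseline, length(distance_um)),
    gaussian_hotspot = profile$baseline +
      profile$peak * exp(-0.5 * ((distance_um - profile$center) / profile$width)^2),
    piecewise_linear = approx(profile$x, profile$y, xout = distance_um,
                              rule = 2)$y,
    stop("unknown profile kind: ", profile$kind))
}

#' Default channel complement of the granule-cell model
#'
#' Generic Hodgkin-Huxley stand-ins for the granule-cell channel set (the
#' original rate functions are not redistributable), fully configurable:
#'
#' * `Na_somatic` (m^3 h): transient Na+, E = 58 mV.
#' * `Na_axonal` (m^3 h s): activates ~5 mV lower and fast-inactivates ~10 mV
#'   more hyperpolarized than the somatic variant, plus a slow inactivation
#'   gate `s` whose recovery at rest takes hundreds of ms -- the gate through
#'   which sustained somatic depolarization removes axonal availability.
#' * `K_dr` (n^4): delayed rectifier, E = -95 mV, with an optional
#'   depolarization-dependent inactivation gate (exponent 0 by default) used
#'   as a direction-of-effect control.
#' * `Ca_generic` (m^2): high-threshold VGCC, E = 120 mV, uniform low density
#'   (1e-7 S cm^-2 as printed, i.e. "100 nS cm^-2"); an inactivation gate
#'   exists in the formalism but is disabled because the Ca2+ readout logic
#'   assumes non-inactivating Ca2+ channels.
#' * leak: E = -80 mV, per-kind densities (1/R_m).
#'
#' Densities: axonal Na+ is a Gaussian hotspot peaking 20 um from the soma
#' (within the 20-25 um initiation band); collaterals carry uniform 0.012 / 0.003
#' S cm^-2 Na+/K+.
#'
#' @param slow_inactivation include the slow axonal Na+ inactivation gate.
#' @param k_inactivation exponent of the K_dr inactivation gate (0 = absent).
#' @param ca_density uniform Ca2+ channel density, S cm^-2.
#' @return channel configuration list for [cable_model()].
#' @export
default_channel_config <- function(slow_inactivation = TRUE, k_inactivation = 0,
                                   ca_density = 1e-7) {
  tau_m <- list(kind = "gaussian", p1 = 0.03, p2 = 0.12, p3 = -40, p4 = 18)
  tau_h_som <- list(kind = "gaussian", p1 = 0.35, p2 = 4, p3 = -55, p4 = 16)
  tau_h_ax <- list(kind = "gaussian", p1 = 0.3, p2 = 3, p3 = -63, p4 = 16)
  tau_s <- list(kind = "sigmoid", p1 = 15, p2 = 485, p3 = -65, p4 = 6)
  tau_n <- list(kind = "gaussian", p1 = 0.5, p2 = 2.2, p3 = -50, p4 = 25)
  tau_kin <- list(kind = "sigmoid", p1 = 60, p2 = 540, p3 = -55, p4 = 9)

  na_som_gates <- list(
    gate("m", 3, vhalf = -36, slope = 6, tau = tau_m),
    gate("h", 1, vhalf = -54, slope = -7, tau = tau_h_som))
  na_ax_gates <- list(
    gate("m", 3, vhalf = -41, slope = 6, tau = tau_m),
    gate("h", 1, vhalf = -64, slope = -7, tau = tau_h_ax),
    gate("s", if (slow_inactivation) 1 else 0, vhalf = -57, slope = -8, tau = tau_s))
  k_gates <- list(
    gate("n", 4, vhalf = -30, slope = 10, tau = tau_n),
    gate("k", k_inactivation, vhalf = -50, slope = -10, tau = tau_kin))
  ca_gates <- list(
    gate("m", 2, vhalf = -12, slope = 9,
         tau = list(kind = "constant", p1 = 1.5)),
    gate("h", 0, vhalf = -45, slope = -9,
         tau = list(kind = "constant", p1 = 300)))

  list(
    leak = list(erev = -80,
                g_S_cm2 = c(soma = 1e-4, dendrite = 1e-4,
                            axon_main = 1e-4, axon_collateral = 1e-4)),
    channels = list(
      Na_somatic = list(
        variant = "Na_somatic", erev = 58, gates = na_som_gates,
        density = list(soma = density_profile("uniform", baseline = 0.08),
                       dendrite = density_profile("uniform", baseline = 0.004))),
      Na_axonal = list(
        variant = "Na_axonal", erev = 58, gates = na_ax_gates,
        density = list(
          axon_main = density_profile("gaussian_hotspot", baseline = 0.12,
                                      peak = 0.55, center = 20, width = 10),
          axon_collateral = density_profile("uniform", baseline = 0.012))),
      K_dr = list(
        variant = "K_dr", erev = -95, gates = k_gates,
        density = list(soma = density_profile("uniform", baseline = 0.04),
                       dendrite = density_profile("uniform", baseline = 0.01),
                       axon_main = density_profile("uniform", baseline = 0.06),
                       axon_collateral = density_profile("uniform", baseline = 0.003))),
      Ca_generic = list(
        variant = "Ca_generic", erev = 120, gates = ca_gates,
        density = list(soma = density_profile("uniform", baseline = ca_density),
                       dendrite = density_profile("uniform", baseline = ca_density),
                       axon_main = density_profile("uniform", baseline = ca_density),
                       axon_collateral = density_profile("uniform", baseline = ca_density)))
    ))
}

#' Steady-state availability of a channel at a holding voltage
#'
#' Product of the steady states of all inactivation gates (negative-slope
#' gates), i.e. the fraction of channels not inactivated after holding at `v`
#' long enough for all gates to equilibrate. Holding a granule-cell axon at
#' -40 mV leaves far fewer available Na+ channels than holding at rest.
#'
#' @param channel one entry of `default_channel_config()$channels`.
#' @param v holding voltage, mV (vectorized).
#' @return availability in (0, 1).
#' @export
channel_availability <- function(channel, v) {
  out <- rep(1, length(v))
  for (g in channel$gates) {
    if (g$exponent == 0 || g$slope > 0) next
    out <- out * gate_steady(g, v)^g$exponent
  }
  out
}
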