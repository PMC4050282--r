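#' Solver configuration for [run_simulation()]
#'
#' The integrator is Crank-Nicolson on the cable term with an exponential
#' (Rush-Larsen) gating update; `settle_ms` of stimulus-free settling from the
#' steady-state initialization precedes every run and the state at stimulus
#' onset is the first recorded sample. Analyses operate on the *recorded* grid
#' (`dt * record_every`), mirroring sampled experimental traces.
#'
#' @param dt time step, ms (in `[0.001, 0.05]`).
#' @param duration_ms simulated (recorded) duration after settling, ms.
#' @param record_every record every this many steps.
#' @param settle_ms settling time at zero stimulus, ms.
#' @param record_currents channel names whose current densities to record.
#' @param record_availability channel whose inactivation-gate product
#'   (available fraction) to record per compartment, or `NULL`.
#' @param theta implicitness (0.5 = Crank-Nicolson).
#' @return a `solver_config`.
#' @export
solver_config <- function(dt = 0.01, duration_ms = 300, record_every = 1L,
                          settle_ms = 500,
                          record_currents = c("Ca_generic", "Na_axonal"),
                          record_availability = "Na_axonal",
                          theta = 0.5) {
  if (dt < 0.001 || dt > 0.05) stop("dt must lie in [0.001, 0.05] ms")
  if (duration_ms <= 0) stop("duration must be > 0")
  if (settle_ms < dt) stop("settle_ms must cover at least one step")
  structure(list(dt = dt, duration_ms = duration_ms,
                 record_every = as.integer(record_every),
                 settle_ms = settle_ms, record_currents = record_currents,
                 record_availability = record_availability,
                 theta = theta), class = "solver_config")
}

resolve_site <- function(model, site) {
  sel <- which(model$comp$section == site$section)
  if (!length(sel)) stop("protocol site refers to unknown section '", site$section, "'")
  n <- length(sel)
  sel[min(n, max(1L, ceiling(site$pos * n)))]
}

#' Integrate the cable model under a stimulation protocol
#'
#' Runs the branched-cable equation with the model's channel dynamics.
#' Gating states start at their steady state for the resting potential; the
#' model then settles stimulus-free for `config$settle_ms` before the
#' stimulus window. Deterministic given identical inputs. Voltages leaving
#' `[-120, 80]` mV abort with a solver-failure error naming time and
#' compartment.
#'
#' @param model a `cable_model`.
#' @param protocol a `stim_protocol`.
#' @param config a [solver_config()].
#' @return a `state_trace`: recorded time grid (ms, 0 = stimulus onset),
#'   per-compartment voltage matrix `v` (mV), named list `currents` of
#'   recorded channel current densities (mA cm^-2), and the compartment table.
#' @export
run_simulation <- function(model, protocol, config = solver_config()) {
  stopifnot(inherits(model, "cable_model"), inherits(protocol, "stim_protocol"),
            inherits(config, "solver_config"))
  icomp <- resolve_site(model, protocol$site)
  nsteps <- as.integer(ceiling(config$duration_ms / config$dt))
  settle <- as.integer(round(config$settle_ms / config$dt))
  tgrid <- (seq_len(nsteps) - 1) * config$dt

  if (protocol$kind == "voltage_step_clamp") {
    vc <- ifelse(tgrid >= protocol$onset_ms &
                 tgrid < protocol$onset_ms + protocol$duration_ms,
                 protocol$v_step_mV, protocol$v_hold_mV)
    stim <- list(icomp = -1L, iamp_nA = numeric(0),
                 vccomp = icomp - 1L, vc_mV = vc)
  } else {
    iamp <- protocol_current(protocol, tgrid) / 1000   # pA -> nA
    stim <- list(icomp = icomp - 1L, iamp_nA = iamp,
                 vccomp = -1L, vc_mV = numeric(0))
  }

  chnames <- names(model$flat_channels)
  recch <- match(intersect(config$record_currents, chnames), chnames) - 1L
  flat <- list(parent = model$parent - 1L,
               area_cm2 = model$comp$area_cm2,
               cap_nF = model$cm_uF_cm2 * model$comp$area_cm2 * 1e3,
               gax_uS = model$gax_uS,
               gleak_uS = model$gleak_uS,
               eleak_mV = model$eleak_mV,
               channels = lapply(model$flat_channels, function(ch)
                 list(erev = ch$erev, gabs_uS = ch$gabs_uS,
                      gates = lapply(ch$gates, unclass))))
  availch <- if (is.null(config$record_availability)) -1L else
    match(config$record_availability, chnames) - 1L
  if (is.na(availch)) availch <- -1L
  sol <- list(dt = config$dt, nsteps = nsteps, settle_steps = settle,
              record_every = config$record_every, theta = config$theta,
              v0 = rep(model$resting_potential_mV, nrow(model$comp)),
              record_channels = as.integer(recch),
              record_avail_channel = as.integer(availch))

  out <- cable_run_cpp(flat, stim, sol)
  nrec <- out$nrec
  keep <- seq_len(nrec)
  currents <- setNames(lapply(out$currents, function(m) m[keep, , drop = FALSE]),
                       chnames[recch + 1L])
  structure(list(
    time = out$time[keep], v = out$v[keep, , drop = FALSE],
    currents = currents,
    availability = if (availch >= 0) out$availability[keep, , drop = FALSE],
    comp = model$comp,
    dt_record = config$dt * config$record_every,
    protocol = protocol, stim_comp = icomp,
    resting_potential_mV = model$resting_potential_mV),
    class = "state_trace")
}

#' @export
print.state_trace <- function(x, ...) {
  cat("<state_trace> ", length(x$time), " samples x ", ncol(x$v),
      " compartments, dt_record = ", x$dt_record, " ms\n", sep = "")
  cat("  protocol: ", x$protocol$kind, "; currents recorded: ",
      paste(names(x$currents), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Index of the recorded compartment nearest an axial distance
#'
#' @param trace a `state_trace`.
#' @param distance_um target arc-length distance from the soma-axon junction.
#' @param kind compartment kind(s) to search.
#' @return compartment index (column of `trace$v`).
#' @export
site_index <- function(trace, distance_um, kind = "axon_main") {
  sel <- which(trace$comp$kind %in% kind)
  if (!length(sel)) stop("no compartments of kind ", paste(kind, collapse = "/"))
  sel[which.min(abs(trace$comp$distance_um[sel] - distance_um))]
}

#' Time derivative of a recorded voltage trace
#'
#' Central differences on the recorded grid (forward/backward at the ends),
#' in V s^-1 (= mV ms^-1).
#'
#' @param v voltage samples, mV.
#' @param dt sampling interval, ms.
#' @return dV/dt, V s^-1.
#' @export
trace_dvdt <- function(v, dt) {
  n <- length(v)
  if (n < 3) return(rep(0, n))
  d <- numeric(n)
  d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * dt)
  d[1] <- (v[2] - v[1]) / dt
  d[n] <- (v[n] - v[n - 1]) / dt
  d
}
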