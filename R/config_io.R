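default_run_config <- function() {
  list(
    model = c(default_morphology_params(),
              list(slow_inactivation = TRUE, k_inactivation = 0,
                   ca_density = 1e-7)),
    protocol = list(kind = "current_step", amplitude_pA = 130, onset_ms = 10,
                    duration_ms = 200, n_pulses = 5, rate_hz = 20,
                    pulse_pA = 2000, pulse_ms = 0.5, baseline_pA = 0,
                    intensity = 1, n_events = 10, rise_ms = 0.5, decay_ms = 6,
                    unit_peak_pA = 30, v_hold_mV = -75, v_step_mV = 10,
                    site_section = "soma", site_pos = 0.5),
    solver = list(dt = 0.01, duration_ms = 300, record_every = 1,
                  settle_ms = 500),
    analysis = list(gate_V_s = 20, refractory_ms = 2, spike_indices = c(1, 3),
                    range_um = c(0, 200)),
    output_dir = ".", seed = 1, log_level = "info")
}

# Recursively collect unknown keys and merge over defaults.
merge_config <- function(defaults, user, prefix = "") {
  bad <- character(0)
  for (k in names(user)) {
    if (!k %in% names(defaults)) {
      bad <- c(bad, paste0(prefix, k))
    } else if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      sub <- merge_config(defaults[[k]], user[[k]], paste0(prefix, k, "$"))
      defaults[[k]] <- sub$value
      bad <- c(bad, sub$bad)
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  list(value = defaults, bad = bad)
}

check_positive <- function(cfg) {
  pos <- c("model$soma_length_um", "model$soma_diam_um", "model$dend_length_um",
           "model$dend_diam_um", "model$axon_length_um", "model$axon_diam_um",
           "model$ra_axon_ohm_cm", "model$ra_soma_ohm_cm", "model$cm_uF_cm2",
           "protocol$duration_ms", "protocol$pulse_ms", "protocol$rate_hz",
           "protocol$rise_ms", "protocol$decay_ms",
           "solver$dt", "solver$duration_ms", "analysis$gate_V_s")
  bad <- character(0)
  for (p in pos) {
    v <- cfg[[sub("\\$.*", "", p)]][[sub(".*\\$", "", p)]]
    if (!is.numeric(v) || any(v <= 0)) bad <- c(bad, p)
  }
  bad
}

#' Load and validate a structured-text run configuration
#'
#' Reads a YAML configuration, fills defaults, rejects unknown keys and
#' validates field constraints; all violations are reported together in one
#' error. The returned object carries every field normalized against the
#' defaults, so `dump_run_config(load_run_config(x))` is a normal form.
#'
#' @param path YAML file path, or a named list already parsed.
#' @return a validated `run_config` list.
#' @export
load_run_config <- function(path) {
  user <- if (is.character(path)) yaml::read_yaml(path) else path
  if (!is.list(user)) stop("configuration must parse to a named list")
  m <- merge_config(default_run_config(), user)
  errs <- character(0)
  if (length(m$bad)) errs <- c(errs, paste0("unknown key: ", m$bad))
  errs <- c(errs, vapply(check_positive(m$value),
                         function(p) paste0("must be > 0: ", p), ""))
  if (length(errs)) stop("invalid configuration:\n  ",
                         paste(errs, collapse = "\n  "))
  structure(m$value, class = "run_config")
}

#' Write a run configuration in its normal form
#'
#' @param cfg a `run_config`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
dump_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Build the protocol object described by a run configuration
#'
#' @param cfg a validated `run_config`.
#' @return a `stim_protocol`.
#' @export
config_protocol <- function(cfg) {
  p <- cfg$protocol
  site <- list(section = p$site_section, pos = p$site_pos)
  switch(p$kind,
    current_step = protocol_current_step(p$amplitude_pA, p$onset_ms,
                                         p$duration_ms, site),
    pulse_train = protocol_pulse_train(p$n_pulses, p$rate_hz, p$pulse_pA,
                                       p$pulse_ms, p$baseline_pA,
                                       p$onset_ms, site = site),
    synaptic_train = make_synaptic_train(p$intensity, p$n_events, p$rate_hz,
                                         p$rise_ms, p$decay_ms, p$unit_peak_pA,
                                         p$onset_ms, site),
    voltage_step_clamp = protocol_voltage_clamp(p$v_hold_mV, p$v_step_mV,
                                                p$onset_ms, p$duration_ms, site),
    stop("unknown protocol kind: ", p$kind))
}

# Polynomial hash of a deparsed object, for provenance stamping without
# timestamp-dependent bytes.
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Write a machine-readable analysis summary
#'
#' JSON document bundling analysis results with provenance (package version,
#' seed, configuration hash). Output is byte-identical across re-runs with
#' the same inputs and seed.
#'
#' @param results named list of analysis outputs (may be empty).
#' @param path output JSON path.
#' @param seed seed recorded in the provenance block.
#' @param config optional configuration object to hash into provenance.
#' @return `path`, invisibly.
#' @export
write_summary <- function(results = list(), path, seed = NA, config = NULL) {
  doc <- list(
    provenance = list(
      package = "apinit",
      version = as.character(utils::packageVersion("apinit")),
      seed = seed,
      config_hash = if (is.null(config)) NA else config_hash(config)),
    results = results)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}
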