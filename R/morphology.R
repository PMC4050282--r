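#' Define a cylindrical cable section
#'
#' Sections are unbranched cylinders discretized into `n_compartments` equal
#' segments. Connectivity must form a tree rooted at the soma; a section
#' attaches to its parent at relative position `connect_at` (arc-length
#' fraction along the parent, 1 = distal end).
#'
#' @param id character label, unique within a morphology.
#' @param parent label of the parent section, or `NA` for the root (soma).
#' @param length_um,diameter_um cylinder dimensions in micrometres.
#' @param ra_ohm_cm axial resistivity in Ohm cm.
#' @param n_compartments number of equal compartments (>= 1).
#' @param kind one of `"soma"`, `"axon_main"`, `"axon_collateral"`, `"dendrite"`.
#' @param connect_at attachment fraction along the parent (0, 1].
#' @return a `section` object (named list).
#' @export
section <- function(id, parent, length_um, diameter_um, ra_ohm_cm,
                    n_compartments, kind, connect_at = 1) {
  kind <- match.arg(kind, c("soma", "axon_main", "axon_collateral", "dendrite"))
  if (!is.character(id) || length(id) != 1L) stop("section 'id' must be a single label")
  if (length_um <= 0) stop("section '", id, "': length must be > 0")
  if (diameter_um <= 0) stop("section '", id, "': diameter must be > 0")
  if (ra_ohm_cm <= 0) stop("section '", id, "': axial resistivity must be > 0")
  n_compartments <- as.integer(n_compartments)
  if (n_compartments < 1L) stop("section '", id, "': n_compartments must be >= 1")
  if (connect_at <= 0 || connect_at > 1) stop("section '", id, "': connect_at must be in (0, 1]")
  structure(list(id = id, parent = if (is.na(parent)) NA_character_ else parent,
                 length_um = length_um, diameter_um = diameter_um,
                 ra_ohm_cm = ra_ohm_cm, n_compartments = n_compartments,
                 kind = kind, connect_at = connect_at),
            class = "section")
}

# Validate that sections form a tree rooted at a single soma section.
validate_sections <- function(sections) {
  ids <- vapply(sections, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate section ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  parents <- vapply(sections, function(s) ifelse(is.na(s$parent), NA_character_, s$parent), "")
  roots <- which(is.na(parents))
  if (length(roots) != 1L) stop("morphology must have exactly one root section")
  if (sections[[roots]]$kind != "soma") stop("root section must be the soma")
  known <- parents[!is.na(parents)]
  if (!all(known %in% ids)) stop("unknown parent section(s): ",
                                 paste(setdiff(known, ids), collapse = ", "))
  # cycle check: walk each section to the root
  for (i in seq_along(sections)) {
    seen <- character()
    j <- i
    while (!is.na(parents[j])) {
      if (ids[j] %in% seen) stop("section connectivity is not a tree (cycle at '", ids[j], "')")
      seen <- c(seen, ids[j])
      j <- match(parents[j], ids)
    }
  }
  invisible(sections)
}

#' Build the default simplified granule-cell morphology and channel complement
#'
#' Constructs a compartmental model of a dentate granule cell reduced to the
#' features the soma-to-axon coupling mechanism needs: a ~10 x 10 um soma, an
#' equivalent-cylinder dendrite, a 1,000-um unmyelinated main axon (0.5 um
#' diameter, axial resistivity 80 Ohm cm) discretized at <= 5 um in the
#' proximal 200 um, and (optionally) two thin collaterals (0.25 um diameter,
#' 300 Ohm cm, Na+/K+ maxima 0.012/0.003 S cm^-2). Channel kinetics and
#' distance-dependent densities come from [default_channel_config()]; the
#' axonal Na+ density profile peaks 25 um from the soma.
#'
#' Reversal potentials default to E_Na/E_K/E_leak = 58/-95/-80 mV and the
#' resting potential to -79 mV. With `balance_leak = TRUE` (default) each
#' compartment's leak battery is adjusted (NEURON's e_pas balancing, here by
#' <~1 mV) so the requested resting potential is an exact fixed point of the
#' assembled dynamics.
#'
#' @param params named list overriding morphology defaults, see
#'   [default_morphology_params()].
#' @param channels channel configuration, see [default_channel_config()].
#' @param balance_leak adjust per-compartment leak reversals so that
#'   `resting_potential` is a fixed point.
#' @return a `cable_model` object.
#' @export
build_granule_cell <- function(params = list(), channels = default_channel_config(),
                               balance_leak = TRUE) {
  p <- modifyList(default_morphology_params(), params)
  if (p$axon_length_um < 500) stop("axon length must be >= 500 um")
  prox <- min(200, p$axon_length_um)
  n_prox <- ceiling(prox / p$proximal_dx_um)
  if (prox / n_prox > 5) stop("proximal compartment length must be <= 5 um")
  secs <- list(
    section("soma", NA, p$soma_length_um, p$soma_diam_um, p$ra_soma_ohm_cm, 1L, "soma"),
    section("dend", "soma", p$dend_length_um, p$dend_diam_um, p$ra_soma_ohm_cm,
            max(1L, round(p$dend_length_um / 10)), "dendrite"),
    section("axon_prox", "soma", prox, p$axon_diam_um, p$ra_axon_ohm_cm,
            as.integer(n_prox), "axon_main")
  )
  if (p$axon_length_um > prox) {
    secs <- c(secs, list(
      section("axon_dist", "axon_prox", p$axon_length_um - prox, p$axon_diam_um,
              p$ra_axon_ohm_cm,
              max(1L, round((p$axon_length_um - prox) / p$distal_dx_um)), "axon_main")))
  }
  if (isTRUE(p$collaterals)) {
    att <- p$collateral_origin_um / prox
    secs <- c(secs, list(
      section("coll1", "axon_prox", p$collateral_length_um, 0.25, 300,
              max(1L, round(p$collateral_length_um / 10)), "axon_collateral",
              connect_at = min(1, att[1])),
      section("coll2", "axon_prox", p$collateral_length_um, 0.25, 300,
              max(1L, round(p$collateral_length_um / 10)), "axon_collateral",
              connect_at = min(1, att[2]))))
  }
  cable_model(secs, channels,
              membrane_capacitance = p$cm_uF_cm2,
              resting_potential = p$resting_potential_mV,
              temperature_C = p$temperature_C,
              balance_leak = balance_leak)
}

#' Default morphology parameters for [build_granule_cell()]
#' @return named list of morphology defaults (micrometres, Ohm cm, mV).
#' @export
default_morphology_params <- function() {
  list(
    soma_length_um = 10, soma_diam_um = 10,
    dend_length_um = 250, dend_diam_um = 5,
    axon_length_um = 1000, axon_diam_um = 0.5,
    proximal_dx_um = 5, distal_dx_um = 10,
    ra_axon_ohm_cm = 80, ra_soma_ohm_cm = 150,
    collaterals = FALSE, collateral_length_um = 100,
    collateral_origin_um = c(100, 200),
    cm_uF_cm2 = 1, resting_potential_mV = -79, temperature_C = 33
  )
}

#' Assemble a cable model from sections and a channel configuration
#'
#' Flattens the section tree into compartments (cylindrical segments), attaches
#' membrane channels with their distance-dependent densities, and (optionally)
#' balances the leak reversal so the requested resting potential is a fixed
#' point. Distances are arc length along the axon from the soma-axon junction;
#' the soma is at distance 0 and dendritic compartments carry `NA`.
#'
#' @param sections list of [section()] objects forming a tree rooted at a soma.
#' @param channels channel configuration as from [default_channel_config()].
#' @param membrane_capacitance specific capacitance, uF cm^-2.
#' @param resting_potential target resting potential, mV.
#' @param temperature_C metadata only (no Q10 scaling).
#' @param balance_leak see [build_granule_cell()].
#' @return `cable_model` with a compartment table (`$comp`) and flattened
#'   channel conductances.
#' @export
cable_model <- function(sections, channels, membrane_capacitance = 1,
                        resting_potential = -79, temperature_C = 33,
                        balance_leak = TRUE) {
  validate_sections(sections)
  ids <- vapply(sections, `[[`, "", "id")
  # order sections parent-first
  ord <- integer(0)
  repeat {
    ready <- which(!(seq_along(sections) %in% ord) &
                   vapply(sections, function(s)
                     is.na(s$parent) || match(s$parent, ids) %in% ord, TRUE))
    if (!length(ready)) break
    ord <- c(ord, ready)
  }
  sections <- sections[ord]
  ids <- ids[ord]

  comp <- list(); idx0 <- 0L
  first_of <- integer(length(sections)); names(first_of) <- ids
  for (si in seq_along(sections)) {
    s <- sections[[si]]
    n <- s$n_compartments
    dl <- s$length_um / n
    d_cm <- s$diameter_um * 1e-4
    l_cm <- dl * 1e-4
    area <- pi * d_cm * l_cm                       # cm^2 lateral area
    r_full <- s$ra_ohm_cm * l_cm / (pi * d_cm^2 / 4)   # Ohm, whole compartment
    first_of[si] <- idx0 + 1L
    for (ci in seq_len(n)) {
      comp[[idx0 + ci]] <- list(section = s$id, kind = s$kind,
                                pos = (ci - 0.5) / n,
                                length_um = dl, diam_um = s$diameter_um,
                                area_cm2 = area, r_axial_ohm = r_full)
    }
    idx0 <- idx0 + n
  }
  ncomp <- idx0
  parent <- rep(-1L, ncomp)
  for (si in seq_along(sections)) {
    s <- sections[[si]]
    f <- first_of[si]
    n <- s$n_compartments
    if (n > 1) parent[(f + 1L):(f + n - 1L)] <- (f):(f + n - 2L)
    if (!is.na(s$parent)) {
      ps <- match(s$parent, ids)
      pn <- sections[[ps]]$n_compartments
      pc <- first_of[ps] + min(pn - 1L, floor(s$connect_at * pn - 1e-9))
      parent[f] <- as.integer(pc)
    }
  }

  kind <- vapply(comp, `[[`, "", "kind")
  sec_of <- vapply(comp, `[[`, "", "section")
  # axial distance from the soma-axon junction, along the axon
  dist <- rep(NA_real_, ncomp)
  dist[kind == "soma"] <- 0
  for (i in seq_len(ncomp)) {
    if (kind[i] %in% c("axon_main", "axon_collateral")) {
      p <- parent[i]
      base <- if (p > 0 && !is.na(dist[p]) && kind[p] != "soma") {
        dist[p] + comp[[p]]$length_um / 2
      } else 0
      dist[i] <- base + comp[[i]]$length_um / 2
    }
  }

  # axial conductance compartment<->parent via series half-resistances (uS)
  gax <- numeric(ncomp)
  for (i in seq_len(ncomp)) {
    p <- parent[i]
    if (p < 1) next
    r <- comp[[i]]$r_axial_ohm / 2 + comp[[p]]$r_axial_ohm / 2
    gax[i] <- 1 / r * 1e6
  }

  comp_df <- data.frame(
    i = seq_len(ncomp), section = sec_of, kind = kind,
    parent = parent, distance_um = dist,
    length_um = vapply(comp, `[[`, 0, "length_um"),
    diam_um = vapply(comp, `[[`, 0, "diam_um"),
    area_cm2 = vapply(comp, `[[`, 0, "area_cm2"),
    stringsAsFactors = FALSE)

  m <- structure(list(
    sections = sections, comp = comp_df, parent = parent, gax_uS = gax,
    channels = channels, cm_uF_cm2 = membrane_capacitance,
    resting_potential_mV = resting_potential, temperature_C = temperature_C),
    class = "cable_model")
  m <- flatten_channels(m)
  if (balance_leak) m <- balance_leak_reversal(m) else {
    m$eleak_mV <- rep(m$channels$leak$erev, ncomp)
  }
  m
}

#' @export
print.cable_model <- function(x, ...) {
  cat("<cable_model> ", nrow(x$comp), " compartments, ",
      length(x$sections), " sections\n", sep = "")
  cat("  axon extent: ", round(max(x$comp$distance_um, na.rm = TRUE)),
      " um; resting potential ", x$resting_potential_mV, " mV; ",
      x$temperature_C, " C (metadata)\n", sep = "")
  invisible(x)
}

# Evaluate channel densities on every compartment and store absolute
# conductances (uS) ready for the C++ engine.
flatten_channels <- function(model) {
  comp <- model$comp
  ncomp <- nrow(comp)
  cfg <- model$channels
  model$gleak_uS <- cfg$leak$g_S_cm2[comp$kind] * comp$area_cm2 * 1e6
  if (anyNA(model$gleak_uS)) stop("leak density missing for some compartment kind")
  flat <- list()
  for (nm in names(cfg$channels)) {
    ch <- cfg$channels[[nm]]
    dens <- numeric(ncomp)
    for (kd in names(ch$density)) {
      sel <- comp$kind == kd
      if (!any(sel)) next
      prof <- ch$density[[kd]]
      x <- ifelse(is.na(comp$distance_um[sel]), 0, comp$distance_um[sel])
      dens[sel] <- density_at(prof, x)
    }
    flat[[nm]] <- list(name = nm, erev = ch$erev, dens_S_cm2 = dens,
                       gabs_uS = dens * comp$area_cm2 * 1e6, gates = ch$gates)
  }
  model$flat_channels <- flat
  model
}

# Net voltage-gated membrane current density (mA/cm^2) at steady state, per
# compartment, at voltage v. Excludes leak.
steady_current_density <- function(model, v) {
  out <- numeric(nrow(model$comp))
  for (ch in model$flat_channels) {
    open <- rep(1, length(out))
    for (g in ch$gates) {
      if (g$exponent == 0) next
      open <- open * gate_steady(g, v)^g$exponent
    }
    out <- out + ch$dens_S_cm2 * open * (v - ch$erev)   # S/cm2 * mV = mA/cm2
  }
  out
}

# NEURON-style e_pas balancing: choose per-compartment leak reversal so the
# target resting potential is an exact fixed point (axial currents vanish at a
# uniform potential).
balance_leak_reversal <- function(model) {
  vr <- model$resting_potential_mV
  gl <- model$gleak_uS / (model$comp$area_cm2 * 1e6)    # S/cm2
  iother <- steady_current_density(model, vr)
  model$eleak_mV <- vr + iother / gl
  model
}

#' Total steady-state membrane current density at a holding voltage
#'
#' Diagnostic used to verify the resting fixed point: at the model's resting
#' potential every compartment's net membrane current should be ~0.
#'
#' @param model a `cable_model`.
#' @param v holding voltage, mV (default: the model resting potential).
#' @return numeric vector, mA cm^-2 per compartment.
#' @export
resting_current_density <- function(model, v = model$resting_potential_mV) {
  gl <- model$gleak_uS / (model$comp$area_cm2 * 1e6)
  steady_current_density(model, v) + gl * (v - model$eleak_mV)
}
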