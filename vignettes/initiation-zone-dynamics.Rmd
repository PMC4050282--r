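---
title: "Modelling activity-dependent dynamics of the axonal spike-initiation zone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling activity-dependent dynamics of the axonal spike-initiation zone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Action potentials in hippocampal dentate granule cells initiate in the
proximal unmyelinated axon (the mossy fibre), roughly 20-25 um from the soma,
where Na+ channel density peaks. Because somatic depolarization spreads
electrotonically into the axon, sustained excitation can partially inactivate
axonal Na+ channels in a distance-dependent way: strongly near the soma,
weakly farther out. The hypothesis this package is built to explore is that
this graded inactivation *expands* the zone over which spikes can initiate,
decelerates local axonal spikes, raises the somatic spiking threshold when
excitation is slow, and suppresses spike-evoked Ca2+ entry preferentially in
proximal axonal segments.

`apinit` provides four interlocking pieces:

1. a compartmental cable model of a simplified granule cell with
   Hodgkin-Huxley-type channels, including a slow, depolarization-sensitive
   inactivation gate on the axonal Na+ channel (`build_granule_cell()`,
   `run_simulation()`);
2. spike, latency, threshold, waveform and Ca2+-entry analyses defined
   exactly as they are applied to dual-patch and imaging recordings
   (`detect_spikes()`, `latency_profile()`, `initiation_site()`,
   `spiking_threshold()`, `per_spike_ca_increment()`, ...);
3. a single-compartment kinetic model of axonal Na+ dynamics seen through the
   SBFI indicator, with the staged fitting procedure for the association
   rate, per-spike Na+ entry and extrusion rate (`simulate_na_system()`,
   `fit_kon()`, `fit_dna_pna()`);
4. a Monte Carlo model of stochastic spike initiation along an expanding
   zone, used to interpret latency statistics
   (`simulate_latency_dataset()`), plus generators for synthetic recordings
   (`make_sbfi_fixture()`, `make_loose_patch_trace()`, `make_fluo_trace()`).

# The compartmental model

## Morphology

The default cell (`build_granule_cell()`) is deliberately minimal: a 10 x 10
um soma, a 250 x 5 um dendritic equivalent cylinder (which also supplies the
proximal capacitive load a real dendritic tree presents to current
injection), and a 1,000-um main axon of 0.5 um diameter with axial
resistivity 80 Ohm cm, discretized at 5 um over the proximal 200 um and 10 um
beyond. Two optional collaterals (0.25 um, 300 Ohm cm, uniform Na+/K+ maxima
0.012/0.003 S cm^-2) can be attached. The only morphological property the
mechanism requires is the electrotonic soma-to-axon coupling, which this
reduction preserves; everything else about the original reconstructed cell
is out of scope. Morphologies round-trip through standard 7-column SWC text
(`write_swc()`, `read_swc()`).

Distance is arc length along the axon from the soma-axon junction, in um;
the soma is at distance 0 and dendritic compartments carry `NA`.

## Channels

The exact granule-cell rate functions are not redistributable, so the
channels are generic Boltzmann/HH stand-ins with every half-voltage, slope
and time-constant curve exposed in `default_channel_config()`:

* **Na_somatic** (m^3 h): activation half-voltage -36 mV, fast inactivation
  -54 mV.
* **Na_axonal** (m^3 h s): activates ~5 mV lower (-41 mV) and
  fast-inactivates ~10 mV more hyperpolarized (-64 mV) than the somatic
  variant, and carries the mechanistically central slow gate `s`
  (half-voltage -57 mV, slope 8 mV) whose time constant is ~15 ms when
  depolarized but ~500 ms at rest -- sustained subthreshold depolarization
  therefore removes availability that does not recover between spikes.
  Disable it with `default_channel_config(slow_inactivation = FALSE)`.
* **K_dr** (n^4): delayed rectifier; an optional inactivation gate
  (`k_inactivation = 1`) exists purely as a direction-of-effect control --
  K+ inactivation broadens spikes and *increases* late Ca2+ entry, the
  opposite signature to Na+ inactivation.
* **Ca_generic** (m^2): a high-threshold VGCC at uniform density 1e-7 S
  cm^-2 ("100 nS cm^-2" as printed; the unit is unusual, we implement the
  number literally and expose it as `ca_density`). Because Ca2+ buffering
  and extrusion are ignored, the density only scales increments linearly
  and all ratio read-outs are invariant to it. The activation gate
  (half-voltage -12 mV, slope 9 mV, tau 1.5 ms) is deliberately
  amplitude-sensitive at spike peaks so that Ca2+ entry reports the Na+
  availability of the underlying spike; an inactivation gate exists in the
  formalism but is disabled by default because the read-out logic assumes
  non-inactivating Ca2+ channels.

Reversal potentials are E_Na/E_K/E_leak = 58/-95/-80 mV. The axonal Na+
density profile is a Gaussian hotspot (baseline 0.12, peak +0.55 S cm^-2 at
20 um, width 10 um), placing both the density maximum and the first-spike
initiation site in the experimentally observed 20-25 um band.

These kinetics were calibrated once, against the qualitative constraints the
recordings impose (initiation at 20-25 um; a 130-pA somatic step firing a
handful of spikes; third-spike initiation strictly more distal; ~50%
proximal Ca2+-increment ratio rising with distance; availability loss on
holding at -40 mV), and then frozen. They are stand-ins, not measured rate
functions, and every parameter is configurable.

## Resting potential

The resting potential is -79 mV with a leak battery of -80 mV. With the
original channel set those are jointly consistent; with generic stand-in
kinetics the voltage-gated window current at -79 mV is far too small to
lift the rest 1 mV above the leak reversal. We therefore use the standard
NEURON-style initialization: each compartment's leak reversal is adjusted
(here by <~1 mV) so that the requested resting potential is an exact fixed
point (`balance_leak = TRUE`). What matters mechanistically is the operating
point -- the voltage from which depolarization drives inactivation -- not
the nominal battery value. With balancing disabled and all densities zero
the model rests exactly at E_leak.

## Numerics

The integrator (in C++) is Crank-Nicolson on the branched cable term with a
Hines-ordered direct solve and an exponential (Rush-Larsen) gating update;
`dt` defaults to 0.01 ms (allowed range 0.001-0.05 ms). Every run starts
from gating steady states at the resting potential, settles stimulus-free
(500 ms by default; the balanced rest makes this inexpensive), and records
from stimulus onset. Analyses operate on the *recorded* grid, mirroring how
sampled experimental traces are analysed. Voltage leaving [-120, 80] mV
aborts with a solver-failure error naming the time and compartment.
Convergence is verified in the test suite: halving `dt` moves spike times by
less than 10 us, halving the compartment length moves the detected
initiation site by ~1 um, and in the passive limit injected charge is
accounted for by capacitive plus leak charge to 0.5%.

Current steps carry a 1-ms linear command rise (`rise_ms`) representing
finite electrode/amplifier slew; an ideal instantaneous step produces an
unphysical capacitive `dV/dt` transient at the injection site that a
derivative-based spike detector would have to special-case.

## Protocols

* `protocol_current_step(130)` -- the suprathreshold somatic step
  ("Depo+Spikes"); with the defaults it elicits 4 spikes in 220 ms.
* `forced_spike_protocol(n, rate, hold_at_rest = TRUE)` -- brief 0.5-ms
  suprathreshold pulses from rest ("Spikes only"), or superimposed on a
  constant subthreshold current (`hold_at_rest = FALSE`), e.g. 5 at 20 Hz or
  100 at 50 Hz.
* `make_synaptic_train(intensity)` -- a 100-Hz train of 10 double-exponential
  synaptic currents; varying `intensity` moves the somatic depolarization
  rise time from a few ms (strong input) to tens-to-hundreds of ms near
  rheobase.
* `protocol_voltage_clamp(-75, 10)` -- the ideal somatic voltage step used
  for the SBFI association-rate protocol.

# Spike and latency analysis

Spikes are timed at the maximum rate of rise (dV/dt)max, detected as local
maxima of the first derivative above a gate (default 20 V/s, 2-ms refractory
window; both configurable since no detection threshold is prescribed by the
recordings), with parabolic sub-sample refinement. Latency is t_a - t_s in
us, axonal minus somatic onset, paired by spike index with a +/-2 ms
conduction-window sanity check; negative values mean the axon leads. The
initiation site is the compartment with the earliest (dV/dt)max -- by
construction it coincides with the minimum of the latency curve.

Rise time is 20-80% of baseline-to-peak (configurable to 10-90%). The
spiking threshold supports two criteria: the extremum of d2V/dt2 in the
pre-peak window (with both the minimum -- as printed alongside the
threshold-adaptation figure, possibly a sign slip -- and the conventional
maximum exposed; we take no position on the intended sign) and the voltage
at a fixed dV/dt crossing, which the tests use. Regression of the
first-to-third-spike latency change on distance uses OLS with a two-sided
Student's t-test on the slope and no multiple-testing correction (one test
per dataset). Waveform changes are summarised per site as percentage
amplitude and rise-time changes with a positivity-constrained
mono-exponential distance fit; non-decaying data are reported as
fit-not-applicable rather than an error.

# Ca2+ read-outs

`per_spike_ca_increment()` integrates the recorded Ca2+ current density over
a window after each somatic spike onset (default -0.5 to +8 ms), subtracting
the local pre-spike holding current, and reports charge per membrane area.
Fluo-4 quantifications follow the stated conventions: `fluo4_dff()` computes
(F - F_pre)/(F_pre - F_0); `early_late_ratio()` compares mean increments
0-40 ms vs 40-200 ms after onset; `dff_spike_ratio()` measures per-spike
increments as short post-spike means against a locally extrapolated
pre-spike baseline (a fitted line over the preceding 5 ms, so indicator
decay and sustained depolarization-driven entry do not bias the step). The
synthetic Fluo-4 forward model treats the indicator as linear: dF is
cumulative Ca2+ influx convolved with a 150-ms single-exponential decay, no
saturation. On noiseless synthetic fluorescence the dF3/dF1 ratio reproduces
the underlying dCa3/dCa1 within 2%.

For profile read-outs, "proximal" recording sites start at ~30 um: the
experimental proximal sites cluster there (and sites under 20 um are
excluded in the recordings because of the somatic diffusion sink), and below
~20 um the model's axonal waveform is dominated by the somatic spike, which
the imaging never sampled. Between ~30 and ~150 um the third-to-first
increment ratio rises monotonically from ~45%.

# The Na+/SBFI kinetic model

The single-compartment scheme couples a Gaussian influx pulse per spike
(half-width sigma = 0.5 ms, integral = per-spike entry dNa), binding to SBFI
(k_on, K_D ~ 25 mM, k_off = k_on K_D), first-order extrusion P_Na and a
first-order longitudinal diffusion-escape rate D_Na ~ 0.8 s^-1, with
indicator mass conservation. Removal acts on [Na]-Na_rest so the system is
at equilibrium pre-stimulus. Resting [Na+] is not printed anywhere; we
assume 10 mM and expose it. SBFI brightness uses a two-species model with a
bound:free ratio of 0.5 (the indicator dims on binding; the magnitude is
unprinted) -- all fits operate on relative dF/F, which is gain-invariant.

Integration is an explicit finite-difference scheme (forward Euler, dt
0.01 ms for simulation, 0.05 ms inside the two-protocol fit's forward
passes) with a hard stability precondition (`dt <= sigma/10` and
`dt <= 0.1/(k_on SBFI_tot + k_off)`); an independent adaptive ODE
integrator (`deSolve::lsoda`) agrees with it to better than 1e-3 mM in the
tests. Doubling sigma changes the fitted (dNa, P_Na) by under 3%.

The fitting procedure is staged as in the experiments:

1. **k_on** from the voltage-step protocol: a single brief entry pulse,
   fitting the 30-ms rising (binding) phase with extrusion neglected --
   justified because maximal Na+ efflux (tens of pmol cm^-2 s^-1, i.e.
   1.6-3.2 mM s^-1 in a 0.5-um axon, see `membrane_flux_to_rate()`) is
   negligible on the 20-30 ms binding timescale. The fit frees (k_on,
   pulse amplitude); the synthetic step fixture used to validate it is
   generated in the same no-extrusion regime, making the check an exact
   construction. The forward step inside this fit is 0.01 ms; a coarser
   0.05 ms leaves a visible (~0.7%) discretization bias on a 2%-tolerance
   check.
2. **(dNa, P_Na)** jointly from the 5 AP @ 20 Hz and 100 AP @ 50 Hz
   protocols with k_on, K_D and D_Na fixed: entry scales the (inverse)
   fluorescence increment while extrusion shapes the decay, so the two are
   nearly orthogonal (verified numerically: cross-sensitivities are an
   order of magnitude below the diagonal ones). Bounded trust-region least
   squares (`minpack.lm`) from five log-spaced starts; the restart ordering
   uses a fixed internal seed so results are reproducible. Noiseless
   recovery is within 2% and a 3 x 3 grid of generating pairs recovers to
   5%.

# The Monte Carlo latency model

The stochastic initiation model draws, per trial, an initiation site x* from
a zone (uniform by default, truncated Gaussian optional) and a recording
position x uniform on 10-350 um, and computes

    t_a - t_s = |T(x) - T(x*)| - [delta_s + (T(x*) - x*/v)] + noise

where T is travel time under v(x) = v / (1 + a exp(-x/lambda)) and the
somatic arrival term is a constant electrotonic delay delta_s (125 us)
plus the *excess* proximal travel time caused by deceleration (zero at
baseline velocity). That decomposition reflects how the soma is activated
-- electrotonically, essentially instantaneously at baseline -- while still
letting use-dependent proximal slow-down delay the somatic spike; it also
makes the distal latency s.d. of a uniform zone exactly L/(v sqrt(12)), the
closed form the tests verify (with L = 110 um and v = 176 um/ms this is the
180-us scale seen by the third spike).

Defaults, declared as assumptions because the original simulation details
are unavailable: first-spike zone 5 um centred at 22.5 um; third-spike zone
110 um starting at 20 um (the observed 100-120 um spread); v = 180 um/ms;
third-spike proximal deceleration factor 1 with a 43-um length constant
(the rise-time deceleration length constant, and a near-soma speed
reduction of about half, matching the ~100% proximal rise-time increase);
measurement noise s.d. 50 us; 1,000 points. Datasets are bit-exact
functions of (config, seed). With the defaults the third-minus-first
latency change regresses on distance (0-200 um) with a strongly negative
slope at p far below 0.001; with matched zones the regression behaves as a
null; with deceleration alone the change is most negative proximally and
relaxes toward zero distally.

# Synthetic data

All fixtures are generated by code. Loose-patch recordings are modelled as
alpha V(t) + beta dV/dt(t) plus noise (predominantly the derivative),
resampled to 20 kHz; voltage is recorded at up to 20 kHz-equivalent and
fluorescence at 2 kHz linescan-equivalent. Noise defaults to additive
Gaussian with s.d. 5% of baseline, a declared stand-in for photon noise.
Trace files are delimited text with `#`-prefixed provenance headers
(parameters and seed) and round-trip bit-exactly through
`write_trace_csv()`/`read_trace_csv()`.

What the generators do *not* emulate: electrode drift and seal instability,
pixel-level linescan structure, indicator saturation or bleaching,
temperature effects (temperature is metadata only; no Q10 machinery since
no Q10s are reported), and biological variability across cells. Passing
tests therefore demonstrate internal consistency of the methods and the
mechanism's qualitative signatures, not quantitative agreement with any
particular recorded cell.

# Problem sizes and reproducibility

The shipped analyses use the default cell (146 compartments), 250-300 ms
simulated windows at dt = 0.01 ms, 1,000-point Monte Carlo datasets, and
kinetic fits over a few seconds of simulated fluorescence: each headline
quantity recomputes in seconds on one CPU. `scripts/acceptance.R` re-derives
all of them from scratch against the installed package; all randomness flows
from its `--seed` argument, and the deterministic fits are seed-independent.

# Known limitations

* Channel kinetics are calibrated stand-ins; absolute voltages (threshold
  values, AP peaks) should not be over-interpreted.
* The threshold-adaptation effect has the right sign but is smaller than
  recorded (~1 mV over the accessible rise-time range vs several mV);
  recorded threshold shifts also fold in synaptic conductance effects the
  current-injection model does not represent.
* No stochastic channel gating: the deterministic model shifts its unique
  initiation site, whereas real axons show increased trial-to-trial latency
  variability; that stochastic component lives in the Monte Carlo module
  instead.
* No myelin, no ion-accumulation feedback on reversal potentials, no Ca2+
  buffering/extrusion, single-compartment Na+ kinetics (longitudinal
  diffusion reduced to a first-order escape rate).
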