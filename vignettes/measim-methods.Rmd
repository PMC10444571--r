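---
title: "Modeling hiPSC-derived neuronal networks on multi-electrode arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling hiPSC-derived neuronal networks on multi-electrode arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(measim)
```

measim simulates the spontaneous activity of human iPSC-derived excitatory
neuronal cultures as recorded by multi-electrode arrays (MEAs), and analyzes
the resulting signals with the same chain used for in vitro recordings. This
vignette describes the model, the calibration choices that were genuinely
open, what the synthetic fixtures do and do not emulate, and the package's
known limitations.

## The model

### Single neurons

Each of the `N = 100` neurons is a single-compartment Hodgkin-Huxley model
with voltage-gated sodium, delayed-rectifier potassium and leak currents:

$$C_m \frac{dV_m}{dt} = -\bar g_K n^4 (V_m - E_K) - \bar g_{Na} m^3 h (V_m - E_{Na})
  - \bar g_l (V_m - E_l) + \frac{I + I_{syn} - g_{AHP}(V_m - E_K)}{A} + \eta(t)$$

The gating variables $m, h, n$ follow first-order kinetics with Traub-Miles
rate expressions shifted by a threshold-adjustment potential $V_T$
(`rate_constants()`). The removable singularities of $\alpha_m$, $\beta_m$
and $\alpha_n$ are evaluated by their analytic limits whenever the
denominator argument is within $10^{-9}$ mV of zero; continuity at those
points is pinned by tests.

The constants (capacitance 1 uF cm^-2; conductances 5 / 50 / 0.3 mS cm^-2;
reversal potentials -80 / 70 / -39.2 mV; VT = -30.4 mV) describe a neuron
with a depolarized resting potential near -39 mV and a spike threshold near
-20 mV, characteristic of relatively immature induced neurons.

**Spike-frequency adaptation.** Every registered spike increments a slow
afterhyperpolarization (sAHP) conductance by `alphaCa = 0.0035` nS; the
conductance decays with `tauAHP = 6` s and produces a potassium current
$g_{AHP}(V_m - E_K)$. This lumps slow calcium- and sodium-activated
potassium currents into a single fatigue mechanism and is what paces the
inter-burst rhythm.

**Noise and heterogeneity.** Membrane noise is an additive white-noise term
integrated with the Euler-Maruyama scheme (the Gaussian draw is held
constant over a step and scaled by $\sqrt{dt}$). Its amplitude is chosen as
$\sigma \sqrt{2 (g_l/C_m)\, dt}$ so that on a passive membrane the
stationary standard deviation of $V_m$ equals `sigma = 4.1` mV — i.e.,
`sigma` is defined by the resulting voltage fluctuation, not by the input
amplitude. A property test verifies the stationary standard deviation within
5% across `dt` in {0.05, 0.1, 0.2} ms. Each neuron additionally receives a
constant bias current drawn uniformly from ±9.5 pA, fixed for the whole
simulation; this is the only structural excitability heterogeneity.

### Unit reconciliation: the membrane area

The ionic conductances are area densities while the sAHP increment (nS),
synaptic conductances (nS) and bias currents (pA) are absolute. They meet
through an assumed membrane area `area`, the one genuinely free scale
parameter of the model. We calibrated it to `2.5e-6` cm^2, which sets

* input resistance ≈ 1.3 GOhm and rheobase ≈ 10–15 pA — the current scale
  probed by the experimental step protocols in these neurons,
* unitary AMPA EPSPs of a few mV, and a ±9.5 pA bias spread that makes the
  most depolarized neurons fire spontaneously (the ignition seeds for
  network bursts),

and, with everything else at its table value, makes the default network
self-organize into regular synchronous network bursts at a few per minute.
Larger areas (weaker coupling in voltage terms) leave the same parameter
table in an asynchronous, nearly silent regime. The area is an exposed
configuration field, not a hidden constant.

### Synapses

AMPA and NMDA receptor conductances are driven per presynaptic source
(`gating_step()`): the AMPA open fraction jumps on each delayed spike
arrival and decays with 2 ms (rise time neglected); NMDA uses the standard
saturating two-variable scheme — an auxiliary variable x jumps on arrival
and decays with 2 ms, while the open fraction integrates
$ds/dt = -s/\tau_{decay} + \alpha x (1-s)$ with $\tau_{decay}$ = 100 ms, so
single events already drive s to ~0.6 of saturation. The NMDA current is
scaled by the instantaneous magnesium unblock
$u(V_m) = 1/(1 + e^{-aV_m}[\mathrm{Mg}]/b)$ with a = 0.062 mV^-1,
b = 3.57 mM, [Mg] = 1 mM.

Synaptic weights are drawn per directed edge from a normal distribution
(mean 1, sd 0.7) and clipped to [0, 2]; the clip silences
$\Phi(-1/0.7) \approx 7.7\%$ of draws. All weights are multiplied by a
global scaling factor S (1 in the control model). Short-term depression
follows the Tsodyks-Markram resource picture: the available fraction x
recovers with `tauD = 813` ms and each presynaptic spike consumes `U =
0.015` of it; the transmitted amount uses the resource level just before
its decrement.

### Network, delays and virtual electrodes

Neurons sit on a 10 × 10 grid (100 um pitch) and connect randomly with
probability 0.3 (directed, no autapses). Conduction delays are distance /
velocity, rounded up to whole integration steps with a one-step floor. The
velocity (unquantified experimentally) defaults to 200 um/ms, an
unmyelinated-axon value giving delays of 0.1–7 ms across the grid.

Twelve virtual electrodes in the 4 × 3, 300-um-spaced layout of a 24-well
MEA plate record weighted sums of nearby membrane potentials with weight
$e^{-d/\lambda}$, truncated beyond 300 um. The decay length lambda defaults
to 30 um — of the order of the electrode diameter — so each electrode is
dominated by its one to four nearest neurons while every neuron still
contributes to at least one electrode. Sharper or flatter pickups change
detected spike counts (see Limitations) but not burst timing.

### Integration

Gates use exponential Euler with rates frozen at the step-start voltage
(implemented through voltage-indexed lookup tables on a 0.01 mV grid with
linear interpolation; a test pins the tables to the analytic rates).
Voltage uses forward Euler plus the Euler-Maruyama noise increment; the
nonlinear NMDA open fraction uses forward Euler; all linear decays use
exact exponential factors. The default step is 0.1 ms, recording at 10 kHz,
with the first 50 s of every simulation discarded as settling transient.
Initial conditions are the deterministic resting state (root-found
self-consistently) with gates at steady state and zero sAHP conductance;
the discarded transient absorbs any residual initialization effect. NMDA
gating below 1e-9 (sub-femtoampere currents) is truncated to zero to keep
the sweep over synapses sparse between bursts. A |Vm| > 200 mV guard turns
numerical blow-up into a diagnostic error with the offending step.

## The analysis chain

Simulated electrode signals and in-vitro-style recordings go through one
code path: a fifth-order Butterworth band-pass (100–3500 Hz) applied
causally per channel; spike detection at 4 × the whole-trace RMS of the
filtered signal (absolute value, so the chain is polarity-agnostic; 2 ms
per-electrode dead time; event time = first suprathreshold sample); then
network-burst detection on the pooled spike rate. The population rate uses
10 ms bins smoothed with a 3-bin centered moving average; a burst opens at
the start of a run that stays at or above 1/4 of the recording's maximum
smoothed rate for at least 60 ms and closes at the first bin below 1/100
of the maximum; bursts with more than 80% of spikes from a single
electrode are discarded. Features: NBR (bursts/min), NBD (mean burst
duration; reported as missing — never zero — when there are no bursts, to
avoid silently biasing means), PSIB (% of spikes inside bursts), MFR
(spikes/s per electrode).

Choices that the chain's verbal description leaves open and that we fixed:
whole-trace RMS (no windowing); the 10 ms / 3-bin rate estimate (the 60 ms
sustain criterion needs sub-60-ms resolution); per-recording maximum rate;
burst start = first bin of the sustained run, end = first bin below the
close threshold. All are exposed as arguments.

## Synthetic fixtures

`synth_raster()` generates Poisson background spiking per electrode plus
synchronized high-rate epochs with per-electrode jitter, returning its
ground-truth epochs. It emulates the *statistics* the burst detector keys
on — sustained pooled-rate elevations against sparse background — but not
waveform-level properties (no voltage traces, no amplitude structure, no
refractoriness). Detector tests against it therefore validate the
rate-thresholding logic, not the spike-detection front end; the front end
is tested separately with noise-plus-impulse voltage fixtures. Passing
both says the chain recovers what it is designed to recover, not that it
matches any particular wet-lab recording.

## In-silico experiments

`condition_spec()` implements the pharmacology analogs as parameter
overrides on otherwise identical networks (matched connectivity, weights,
bias and noise seed, so comparisons are paired): halved sAHP increment
(linopirdine), zero sodium conductance (TTX), zero NMDA conductance
(MK-801), zero AMPA conductance (NBQX/NASPM). The Dravet-syndrome (DS)
condition combines a reduced sAHP (×0.4), reduced synaptic scaling
(S ×0.38), reduced short-term depression (U ×0.1) and slowed sodium
activation rates (×0.7). These DS magnitudes are artifact defaults tuned so
that the three phenotype directions — fewer bursts, longer bursts, lower
PSIB — hold robustly across matched networks at the scaled problem size;
they are exposed in the configuration and are not measured values.

`sodium_scan()` runs arbitrary sodium-channel modifications (rate scalings,
activation shifts, conductance scaling) against matched controls and flags
per row whether it reproduces the DS triplet. A direction is called only
beyond a 5% deadband on the normalized feature; a modification that
silences the network entirely counts as "burst rate down" but not as
"burst duration up" (its duration is undefined, not longer).

Problem sizes: the package defaults to the full-scale protocol (650 s, 12
networks per condition); the shipped tests and the acceptance script use a
scaled protocol (120 s with 50 s discarded, 4 matched networks per
condition, 2 per scan row) chosen so the whole suite runs on a laptop-class
single core while leaving the phenotype directions stable across seeds.

## Known limitations

* **AMPA blockade.** In this implementation the NMDA conductance alone can
  regenerate network bursts at the calibrated operating point: with AMPA
  blocked, bursts persist (with unchanged rate and shortened-to-similar
  duration) rather than vanishing. Reproducing burst loss under AMPA
  blockade requires a weaker-coupling operating point (area ≈ 4e-6 cm^2) at
  which, however, NMDA blockade and the DS overrides silence the network
  outright — the saturating NMDA model is strong enough at every operating
  point we explored that the two blockade phenotypes could not be satisfied
  simultaneously. We chose the operating point that preserves the control,
  sAHP, NMDA-block, sodium-block and DS phenotypes and document the AMPA
  discrepancy rather than distorting table parameters.
* **Detected firing rates.** Virtual electrodes register essentially every
  intra-burst action potential of their nearest neurons (and filter lobes
  can double-count), so MFR-scale quantities are substantially higher than
  typical in vitro values, where an electrode resolves few units and misses
  many spikes. Burst-level features (NBR, NBD, PSIB) are robust to this;
  absolute MFRs and MFR differences are not comparable across pickup
  models.
* One compartment, excitatory neurons only, no astrocytes, no synaptic
  rise-time for AMPA, homogeneous channel kinetics across cells; parameter
  degeneracy means the calibrated area/lambda pair is one of several
  combinations with similar burst statistics.
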