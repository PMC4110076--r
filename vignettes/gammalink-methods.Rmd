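---
title: "Delay-coupled gamma populations: model, estimators and design notes"
author: "gammalink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delay-coupled gamma populations: model, estimators and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## What the package models

`gammalink` simulates two reciprocally connected populations of
conductance-based spiking neurons and asks how the conduction delay between
them shapes their collective synchronisation and their capacity to transmit
stimulus information. Each population is a Watts–Strogatz small-world
network of excitatory (80%) and inhibitory (20%) Hodgkin–Huxley neurons
coupled by AMPA- and GABA_A-like synapses and driven by an external
inhomogeneous Poisson bombardment. The recurrent excitatory–inhibitory loop
produces a collective gamma-band rhythm even though individual neurons fire
sparsely and irregularly — the classic sparsely synchronised oscillation.
Long-range projections between the populations are purely excitatory and
carry conduction delays drawn from a gamma distribution whose mean
$\tau$ is the experimental knob.

The analysis side quantifies (i) frequency-resolved phase coherence between
the two populations' local field potentials (LFPs), converted into
inter-population time shifts, and (ii) the mutual information between a set
of stimulus intensities applied to one population (the emitter) and the
single-trial spectral power of the other population's (the receiver's) LFP
or multi-unit activity (MUA).

## Single-neuron model

Each neuron follows a Hodgkin–Huxley membrane equation with sodium,
potassium and leak currents,

$$C_m \dot V = -g_{Na} m_\infty^3(V)\,h\,(V - E_{Na})
  - g_K n^4 (V - E_K) - g_L (V - E_L) + I_{syn} + I_{ext},$$

with the fast sodium activation replaced by its voltage-dependent steady
state $m_\infty(V)$, and first-order kinetics for $n$ and $h$. The default
rate functions are the Wang–Buzsáki family (temperature factor $\phi = 5$
folded into the $n$ and $h$ rates) with $g_{Na} = 35$, $g_K = 9$,
$g_L = 0.1$ mS/cm², $E_{Na} = 55$, $E_K = -90$, $E_L = -65$ mV. Two
considerations fixed this choice. First, this kinetics family is defined
*with* the $m_\infty$ substitution, which is exactly the reduction the
model uses. Second, it remains numerically stable under the explicit Heun
scheme at the default step of 0.05 ms: families with several-fold larger
sodium conductance develop spike upstrokes faster than 0.05 ms can resolve
and need a much smaller step for the same accuracy. Excitatory cells have
$C_m = 1$ µF/cm²; inhibitory cells are fast spiking, implemented as
$C_m = 0.5$ µF/cm².

Synaptic conductances are differences of exponentials,
$g(t) = g_{max}\,c\,(e^{-t/\tau_d} - e^{-t/\tau_r})$, peak-normalised so
that $\max_t g = g_{max}$ ($c$ is the `norm_c` normalisation constant; the
helper `calibrate_norm_c()` instead scales it to a target unitary PSP
amplitude when desired). Defaults: AMPA $\tau_r = 0.5$, $\tau_d = 2$ ms,
$E = 0$ mV; GABA_A $\tau_r = 0.5$, $\tau_d = 4.5$ ms, $E = -80$ mV. The
GABA decay constant is the main pacemaker of the collective rhythm: the
test suite verifies that shortening it raises the LFP spectral peak
frequency. 4.5 ms (together with the conductance scales below) places the
trial-averaged peak in the low-gamma range (roughly 30–48 Hz across
network realisations of the reduced test network), inside the 30–80 Hz
band, with room to move in both directions when the decay constant is
varied.

## Calibration of the conductance scales

The sources that fix every numeric parameter of the original formulation
were not available to this implementation, so the conductance scales were
calibrated once, against the *qualitative* regime the model is known to
operate in, and then frozen as the package defaults:

* inhibition strong enough that excitatory and inhibitory synaptic currents
  balance and the membrane voltage fluctuates below threshold, crossing it
  only occasionally (`g_gaba/g_ampa ≈ 4` per synapse);
* excitatory cells firing sparsely and irregularly (ISI CV above 0.5,
  population means of order 10 spikes/s for excitatory and 50–100 spikes/s
  for fast-spiking inhibitory cells);
* a prominent LFP spectral peak inside the gamma band whose frequency
  tracks the GABA decay constant.

The frozen defaults (per-synapse peak conductances, mS/cm²) are
`g_ampa = 0.0135`, `g_gaba = 0.055` at the reference degree of 100, and an
external-drive synapse `g_ext = 0.006` per event. The external drive is an
Ornstein–Uhlenbeck-modulated Poisson train (mean 1500 events/s, SD 400,
correlation time 16 ms, clipped at zero) shared within a population as a
common rate fluctuation, with independent per-neuron thinning; inhibitory
neurons receive the drive with a gain of 1.2, a standard device for keeping
excitatory firing sparse while the interneuron network paces the rhythm.
Calibration was performed on the reduced 2×400 fixture; none of these
values were revisited afterwards.

## Networks, delays, coupling

Each population is an undirected Watts–Strogatz ring lattice (degree 100 at
the reference size N = 2000, rewiring probability 0.3) duplicated into two
directed edges per pair, because chemical synapses are directed. The
synapse class of an edge follows the presynaptic cell. Intra-population
conduction delays are Gamma(shape 1, scale 1) ms — exponential with unit
mean, so always shorter on average than the inter-areal delays of interest.
Inter-areal delays are Gamma(shape $\tau$, scale 1) ms: mean $\tau$,
variance $\tau$, CV $1/\sqrt\tau$ decreasing with the mean, which is the
anatomically motivated wide-delay-spectrum assumption. A constant-delay
mode (`delay_mode = "constant"`) isolates the effect of delay dispersion
from the delay mean. Long-range projections are excitatory only: 90% of
each population's excitatory cells project, each onto `degree_per_source`
neurons drawn from a quarter of the other population, giving cross-network
connectivity an order of magnitude sparser than the internal one.

Delays are rounded to the nearest integration step (ties up, minimum one
step) and realised with per-edge ring buffers inside the compiled core.
External drive arrives undelayed. Initial voltages are uniform within
±5 mV of rest with gates at steady state; a 200 ms warm-up is discarded
before any analysis. Every trial redraws connectivity, initial conditions
and noise from its seed, and identical (configuration, seed) pairs are
bit-reproducible because all randomness flows through R's RNG — including
inside the C++ core.

## Observables

The LFP proxy is $R_e \langle |I_{exc}| + |I_{inh}| \rangle$ averaged over
the excitatory cells, where $I_{exc}$ includes both the external Poisson
drive and recurrent AMPA currents, and $I_{inh}$ the recurrent GABA
current. $R_e$ (default 1, arbitrary units) only scales the amplitude and
cancels in coherence and information measures. MUA is the total spike
count per unit time over all neurons of a population (1 ms bins by
default). Both are recorded at 1 kHz (the core averages over the 20
integration sub-steps of each sample), which resolves the gamma band with
a wide margin.

## Spectral estimators

Power spectra use Welch's method: Hamming-windowed segments (1 s by
default, 0.5 s for windowed stimulus epochs), 50% overlap, averaged
modified periodograms, one-sided density normalisation. Phase coherence at
frequency $f$ is the resultant length of per-segment *unit-normalised*
cross-spectrum phasors pooled across the segments of all trials of a
condition, and the mean phase is the resultant angle; the phase is
converted to a time shift by dividing by $2\pi f$ (positive = population 1
leads). For $K$ independent segments the chance level is
$\sqrt\pi/(2\sqrt K)$, so significance uses the rule: threshold = 4 × the
mean coherence of an *uncoupled* baseline run analysed with the same K.
The baseline therefore defaults to the same trial count as the coupled
condition — comparing against a baseline with fewer segments would inflate
the threshold mechanically.

Peaks: `f_LFP` is the in-band power maximum; `f_C` collects all
significant local coherence maxima, which is what lets the in-phase and
anti-phase branches coexist in the intermediate-delay regime. A time shift
within one eighth of a period of zero counts as in-phase; within one
eighth of a period of half a period as anti-phase.

## Mutual information

The response variable is the single-trial spectral power at one frequency;
stimuli are uniform over the protocol's rate increments. Power values are
discretised into equipopulated (quantile) bins computed on the responses
pooled across stimuli — a common response alphabet is required for the
marginal $P(r)$ to make sense. The plug-in information is then corrected
in two stages: the first-order analytic bias
$[\sum_s (B_s - 1) - (B - 1)] / (2N\ln 2)$ (occupied-bin counts $B_s$,
$B$; total trials $N$), followed by subtraction of the mean of a
stimulus-shuffled bootstrap null (200 shuffles by default), whose upper
95th percentile also provides the significance level. Six bins are the
default; the scaled-down network experiments use four, matching their
smaller trial counts (the estimator flags undersampling whenever
$N < 4 \cdot n_{bins} \cdot n_{stimuli}$). Corrected values are floored at
zero for reporting, with the unfloored value retained.

## Surrogate generators

Two generators make the estimators testable without the simulator:

* `surrogate_coherent_pair()` builds signal pairs of phase-diffusing
  oscillations (Wiener phase noise mimics the finite self-coherence of
  network gamma) plus white noise, as a trial-level mixture: each trial
  is fully phase-locked at the set lag with probability equal to
  `coherence_level` and fully independent otherwise. The per-segment
  unit phasor is then exactly `exp(i*phase_lag)` or uniform, so the
  expected resultant equals the nominal coherence level for any
  diffusion rate — the nominal statistic is the analytic expectation of
  the estimator, not a label. (An earlier amplitude-mixing construction
  was abandoned: its expected coherence depends on the ratio of the
  phase-diffusion time to the segment length, so no single analytic
  mapping holds across regimes.) The phase lag and hence the time shift
  are set by construction.
* `surrogate_power_channel()` draws log-normal power samples whose
  location shifts linearly with the stimulus index; the exact mutual
  information of the binned construction follows by integrating the known
  normal densities (`surrogate_channel_mi()`), giving a
  numerical-integration oracle for the whole MI stack.

What the surrogates do *not* emulate: spike-level structure, 1/f spectral
backgrounds, cross-frequency coupling, or any dependence between
frequencies. Passing the surrogate tests validates the estimators, not the
biology of the simulator; the network-level claims are tested separately
on simulated fixtures.

## Problem sizes used by the tests

The packaged experiments run at deliberately reduced scale, chosen so the
full suite completes on a desk machine while keeping every qualitative
regime intact: fixture populations of 2×400 neurons (degree 40; per-edge
conductances scaled up by the degree ratio so each neuron's summed
synaptic conductance matches the reference network), 2 s trials (1.5 s for
stimulus epochs), 5–10 trials per condition, and a long-range out-degree
of 6 in the coupled experiments. At this scale the delay sweep reproduces
zero-lag locking at $\tau = 0$, anti-phase locking near half a gamma
period, branch coexistence in between, and the leader–laggard
unidirectional control; trial counts an order of magnitude larger would
mainly narrow the error bars. The `--paper-scale` style full-size runs
(N = 2000, degree 100, 50+ trials) use the same code paths via
`default_profile()`.

## Numerical choices and degenerate inputs

* Heun (trapezoidal predictor–corrector) integration, dt = 0.05 ms;
  empirical order-2 convergence is part of the test suite. Gating
  variables are clamped to [0, 1] after each step; voltages outside
  (−150, 100) mV abort with the neuron index and time.
* Rate functions with removable singularities (`x/(1 − e^{−x})`) are
  evaluated by a series expansion in a narrow band around the singular
  point.
* The compiled core receives the gating rates as a lookup table
  (0.02 mV resolution, linear interpolation) built from the R-level
  `gating_rates()`, so there is a single definition of the kinetics.
* Gamma delays with $\tau = 0$ degenerate; the builder falls back to zero
  delays with a notice. Delay rounding ties go up, and no delivery happens
  earlier than one step after the spike.
* Equipopulated binning under massive ties degrades to the feasible
  number of bins with a warning; an edge at the sample maximum is dropped
  (it would create an empty top bin).
* Zero cross-spectrum phasors (possible on constant segments) are
  excluded from the coherence average and counted.

## Known limitations

* Point neurons only; no NMDA, gap junctions or plasticity, no
  distance-dependent connectivity beyond the small-world clustering, no
  volume-conduction model for the LFP.
* The absolute gamma-peak frequency depends on the calibrated conductance
  scales; only its qualitative dependences (GABA decay, delay structure)
  are claims of this package.
* At the reduced network size, realisation-to-realisation variability of
  firing rates is substantial (finite-size effects); regime assertions in
  the tests are therefore made on trial-averaged quantities with loose
  bounds.
* The two-stage bias correction follows the analytic-plus-bootstrap
  recipe; with very few trials per stimulus the corrected estimate is
  conservative (biased slightly downward), which the constructed-channel
  consistency test quantifies.
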