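---
title: "Learning-rate symmetry and the stability of spiking-network memories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning-rate symmetry and the stability of spiking-network memories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`spikemem` simulates how the *weight dependence* of spike-timing-dependent
plasticity (STDP) determines whether a feedforward spiking network stores
flexible memories — quickly formed, quickly erased — or stable memories that
survive background noise and the arrival of new information.  This vignette
documents the model, its parameters, the experiment protocols, the numerical
choices, and the limits of what the simulations can show.

## The model

### Neurons

Both layers contain leaky integrate-and-fire neurons.  Output neuron $j$
follows

$$C \frac{dV_j}{dt} = g_L (E_L - V_j) + g_j (E_{syn} - V_j) + I_{noise},
\qquad
\frac{dg_j}{dt} = -\frac{g_j}{\tau_{syn}} + c_{syn} \sum_i w_{ij} S_i(t),$$

where $S_i(t)$ is the spike train of input neuron $i$ and $w_{ij} \in [0,1]$
the synaptic weight.  When $V_j$ reaches the threshold it spikes immediately
and resets to $E_L$ within the same step.  $I_{noise}$ is an independent
Gaussian current per neuron per step.  Parameters are dimensionless numbers
in a consistent mV/ms system (`lif_params()`):

| parameter | default | meaning |
|---|---|---|
| `C` | 1 | membrane capacitance; with `g_L` gives $\tau_m = 2.5$ ms |
| `g_L` | 0.4 | leak conductance |
| `E_L` | $-65$ | resting potential (mV) |
| `E_syn` | $-5$ | synaptic reversal potential (mV) |
| `E_threshold` | $-55$ | spike threshold (mV) |
| `tau_syn` | 3 | conductance decay (ms) |
| `c_syn` | 0.12 | conductance increment per unit-weight spike (per ms) |
| `noise_sigma` | 1.2 | membrane noise s.d. |
| `dt` | 1 | Euler step (ms) |

The membrane noise is not a nuisance term: early in training, when all
weights sit mid-range, single-pattern input alone rarely reaches threshold
reliably, and noise-assisted crossings (stochastic resonance) provide the
postsynaptic spikes that let STDP begin to shape the weights.

### Plasticity

A pre/post pair separated by $\Delta t = t_{post} - t_{pre}$ changes the
weight by

$$\Delta w = \begin{cases}
\varepsilon_+(w) \, k_+ \, e^{-\Delta t/\tau_+} & \Delta t > 0 \ (\text{LTP})\\
\varepsilon_-(w) \, k_- \, e^{-|\Delta t|/\tau_-} & \Delta t \le 0 \ (\text{LTD})
\end{cases}$$

with `k_plus` $= 0.06$, `k_minus` $= -0.09$, `tau_plus` $= 3$ ms,
`tau_minus` $= 15$ ms, and the result clipped to $[0,1]$ after every update.
A coincident pair ($\Delta t = 0$) falls in the LTD branch.  The
weight-dependent learning rates come in three profiles (`stdp_config()`):

* **AR** (asymmetric rate, the multiplicative rule):
  $\varepsilon_+ = 1 - w$, $\varepsilon_- = w$.  Weak synapses potentiate
  easily and strong ones depress easily, so the *stable* weight is
  mid-range: memories encoded as saturated weights relax away.
* **SR** (symmetric rate): $\varepsilon_+ = \varepsilon_- =
  2\min(1 - w,\, w)$.  Plasticity vanishes at both bounds, so a weight
  driven to 0 or 1 is locked in: memories persist.
* **HYBRID**: $\alpha\,\varepsilon_{SR} + (1-\alpha)\,\varepsilon_{AR}$.
  $\alpha = 0$ and $\alpha = 1$ reproduce AR and SR bit for bit.

The *synaptic instability* $\varepsilon_+(w)^2 + \varepsilon_-(w)^2$
summarises this: its minima are the rule's stable weights (0.5 for AR; 0 and
1 for SR).  `boltzmann_density()` turns it into a stationary-density
predictor $p(w) \propto e^{-\beta\,[\varepsilon_+^2 + \varepsilon_-^2]}$
with a free inverse temperature `beta` (default 8; only the modal structure
is meaningful, so the default matters little and is exposed).

The Boltzmann predictor treats the weight as a *balanced* random walk: it
keeps only the diffusion term and drops the drift.  With the default kernel
constants the drift is far from zero — the LTD lobe integrates to
$|k_-|\tau_- = 1.35$ against $k_+\tau_+ = 0.18$ for LTP — so under
uncorrelated pre/post firing the expected motion is strongly downward.  The
single-synapse Monte-Carlo (`simulate_single_synapse()`), which implements
the kernel exactly, therefore concentrates AR weights near
$k_+\tau_+/(k_+\tau_+ + |k_-|\tau_-) \approx 0.12$ rather than at the
predictor's mid-range mode, and drains SR mass toward the lower bound.  The
predictor and the Monte-Carlo agree in modality only where the LTP/LTD
balance is approximately symmetric.  We implement both and report the
comparison rather than forcing agreement; the network-level contrasts
between the profiles (below) do not depend on it.

### Pairing scheme

The kernel is applied through exponentially decaying pre- and postsynaptic
traces, which is exactly all-to-all pairing: at each postsynaptic spike the
LTP update uses the presynaptic trace (all earlier pre spikes, weighted
$e^{-\Delta t/\tau_+}$), at each presynaptic spike the LTD update uses the
postsynaptic trace, and same-step pairs are handled once, in the LTD
branch.  The trace form is $O(1)$ per spike; a pair with
$|\Delta t| > 7\max(\tau_+, \tau_-) = 105$ ms contributes less than
$e^{-7}$ of its amplitude, which is what the `pairing_window` field of
`stdp_config()` records for pair-based accounting (the test suite checks
the trace mechanics against a brute-force double loop over spike pairs).

### Network and stimuli

`build_network()` connects 50 input to 50 output neurons, each pair
independently with probability 0.2, initial weights $\mathcal N(0.5,
0.05)$ clipped to $[0,1]$.  A *training pattern* (`make_pattern()`) gives
each input neuron exactly one spike at a uniform-random integer ms within a
100-ms window (10 Hz per neuron when the pattern repeats back to back);
`tile_pattern()` repeats it seamlessly, and `poisson_train()` provides
background activity as per-step Bernoulli spiking on the 1-ms grid.

### Memory index

A memory probe (`test_memory()`) presents a pattern 20 times with frozen
weights and membrane noise on, records per trial which output neurons fired
at least once (`binarize_responses()`), and computes

$$MI = \frac{1}{N_{pair}} \sum_{m<n} \frac{S_m \cdot S_n}{N_{firing}},$$

the average pairwise overlap of the 20 binary response vectors normalised
by the number of neurons that responded at all ($N_{pair} = 190$).  A fully
reproducible response set scores 1; an all-silent one scores 0 by
convention so decay curves stay defined.  Memory retention is quantified by
the maintained ratio $MI_{t=T} / MI_{t=0}$.

## Protocols

All protocols (`decay_experiment()`, `append_experiment()`,
`train_test_experiment()`, `hybrid_sweep()`, `output_pattern_study()`) run
cohorts of independently seeded networks from one master seed, which
spawns per-network streams for construction, pattern draws, training
noise, background noise and probe noise separately.  Three design rules:

* **Probes are read-only.**  Plasticity is off during probes.  Turning it
  on would inject 2 s of extra pattern training per probe and contaminate
  every decay curve with rehearsal.
* **Probes cannot perturb the experiment.**  A decay or appending session
  is one continuous plastic stream (stimulus rasters and membrane noise
  seeded once, membrane/trace state carried across probe boundaries), and
  probe noise comes from a stream indexed by absolute probe time.  Adding
  or removing probes therefore changes nothing else — enforced by test.
* **Sweeps are paired.**  `hybrid_sweep()` reuses identical per-network
  streams across $\alpha$ values, so cohort comparisons across $\alpha$
  are matched-pairs comparisons.

The standard schedules: training presents one pattern 1000 times (100 s);
decay follows with 5-Hz Poisson background on the input layer for up to
1000 s, probing every 100 s, with the maintained ratio read at 800 s;
appending trains further patterns sequentially (a second pattern for
500-1000 s, or six more at 200 s each), probing every trained pattern plus
one held-out untrained pattern at every probe point.  Cohort statistics
use the two-sided Mann-Whitney rank-sum test, unadjusted.

Where the background noise of the decay session enters the network is a
genuine modelling choice.  The default delivers it to the input layer
only, so it must traverse the plastic synapses; this erodes memories
gradually.  The alternative — also forcing Poisson spikes directly onto
the output layer, as in a two-sided single-synapse protocol — is available
via `noise_on_output = TRUE`, but with the depression-dominant default
kernel it collapses all asymmetric-rate weights within roughly a hundred
seconds (the network falls silent and the memory index drops to zero),
which is a qualitatively different, step-like failure mode; we keep the
gradual input-only variant as the default.

## Numerical choices

* **Integration** is coupled forward Euler at `dt` $= 1$ ms: both
  derivatives are evaluated at the step start, so the voltage update sees
  the conductance from the beginning of the step and an input spike first
  influences the voltage one step later.  Spike detection and reset happen
  after the voltage update, within the step.  No refractory period.
* **Thresholds and bounds.**  The threshold sits between $E_L$ and
  $E_{syn}$ by construction (validated in `lif_params()`); weights are
  clipped to $[w_{min}, w_{max}]$ after *every* kernel application, which
  guarantees the bound invariant even for large mid-range updates.
* **Simultaneous spikes.**  Multiple input spikes in one step sum linearly
  into the conductance; a pre and post spike in the same step form one
  $\Delta t = 0$ pair, applied in the LTD branch.
* **Degenerate inputs.**  Zero-rate Poisson trains, zero-duration training
  and silent response sets are all defined (empty raster, unchanged
  network, $MI = 0$); an undefined maintained ratio ($MI_0 = 0$) is an
  error rather than a silent `NaN`.
* **Determinism.**  Every stochastic entry point takes a `seed`; equal
  seeds give bitwise-equal rasters, networks and weights.  The hybrid rule
  at $\alpha \in \{0, 1\}$ is bit-identical to the pure rules because the
  convex combination is evaluated as written.

## Problem sizes

The shipped tests and the acceptance script use the standard 50×50
geometry with cohorts of 20 networks for the decay, training and appending
contrasts, cohorts of 10 for the hybrid sweeps, and 2000 single-synapse
trials; these sizes give comfortable rank-sum resolution for the
qualitative contrasts while keeping a full run in the minutes range on one
core.  Cohorts of 100 (the `run_experiment()` default) sharpen the cohort
means roughly twofold.

## What the generator does and does not emulate

The synthetic inputs capture precise, repeatable spike timing (one spike
per neuron per window), homogeneous Poisson background, and Gaussian
membrane noise.  They do not include inhibition, recurrence, rate coding,
correlated ensembles, oscillations, homeostasis, or biological parameter
heterogeneity.  Passing tests therefore demonstrate properties of this
model family — the link from learning-rate symmetry to memory stability —
not quantitative predictions for any biological circuit.

## Known limitations

* The depression-dominant default kernel (above) makes the Boltzmann
  predictor's mid-range AR mode unreachable by the exact Monte-Carlo, and
  it compresses the dynamic range of the decay protocol: after long
  background noise an asymmetric-rate network settles at mid-range weights
  whose probe responses remain fairly dense and reliable, so the
  maintained ratio floors well above zero.  The qualitative ordering
  (SR retains more than AR, hybrids in between; appending erases AR but
  not SR memories) is robust across seeds.
* In the hybrid decay sweep the maintained ratio rises clearly toward
  $\alpha = 1$ but is flat-to-noisy for $\alpha \lesssim 0.5$ at moderate
  cohorts; strict monotonicity across a five-point sweep is not guaranteed
  at cohort 10.
* Event timing is quantised to the 1-ms integration grid; sub-millisecond
  STDP structure is out of scope.
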