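---
title: "Methods: burst-based spiking vision networks and their digital emulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: burst-based spiking vision networks and their digital emulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(burstnet)
```

# The model stack

`burstnet` simulates a three-layer spiking image-classification network
built from Hindmarsh–Rose (HR) burst neurons, together with the
piecewise-linear substitutions that make the model implementable on a
multiplier-less digital datapath, and a bit-deterministic emulation of that
datapath. This vignette explains the science in the package's own terms:
the model equations and their assumptions, the parameters that matter, the
numerical choices made where the design was genuinely open, and what the
desk-scale experiments do and do not demonstrate.

## The HR neuron and its linear substitution

The HR neuron is the three-variable burster

$$\dot x = y - a x^3 + b x^2 - z + I,\qquad
  \dot y = c - d x^2 - y,\qquad
  \dot z = r\,(s\,(x - q) - z),$$

with `x` the membrane potential, `y` the fast (Na/K) current, `z` the slow
(Ca) current, and constants `a = 1, b = 3, c = 1, d = 5, r = 0.001, s = 4,
q = -1.618` chosen so the cell bursts under constant drive. The package
treats the dimensionless HR time unit as one millisecond so neuron and
synapse time constants share a single clock.

The linear HR (LHR) variant replaces `x^3` and `x^2` by fixed
piecewise-linear segment tables ([cube_table()], [square_table()]; ten and
eight segments). Every multiplication by a segment slope reduces to shifts
and adds in hardware. Two corrections/conventions:

* the printed final condition of the quadratic table (`x > 29.1`) is
  treated as a typo for `x > 1.21`, the value required for contiguity and
  even symmetry;
* segments are half-open `[lo, hi)` — a breakpoint belongs to the higher
  segment — and the outer segments extend to infinity, so evaluation is a
  total function.

Approximation quality is measured by max-normalized errors: `NMAE =
mean(|ref - approx|)/max(ref)` and `NRMSE = rms(ref - approx)/max(ref)`.
The evaluation domain behind the published error figures is not stated;
the package uses a uniform 10,001-point grid on $[-2, 2]$ for the
polynomial tables (spanning all breakpoints with margin) and $[0, 50]$ ms
for the exponential table. On these grids the exponential table reproduces
its published errors exactly (0.0024/0.0029) and the polynomial tables
land within 20% of theirs (0.0111/0.0167 for $x^2$ against published
0.0121/0.0183; 0.0175/0.0379 for $x^3$ against 0.0216/0.0468), consistent
with an unstated, slightly different grid.

[search_best_fit()] implements the seeded best-approximation search: knots
drawn uniformly per half-domain, joined by chords, scored by NMAE, with
the knot count growing from 2 to 11 until the error tolerance is met. The
sampling distribution and the refinement step of the original pseudocode
are under-specified; pure resampling with 60 restarts per knot count is
used, which reaches the published error levels for both polynomials.

## Why the published waveform comparison does not reproduce

Integrating HR and LHR side by side (first-order Euler, `dt = 1/256`, the
step the datapath realizes as an arithmetic right shift) shows a real
reproducibility gap: with the printed tables, LHR at `I = 1.5` fires
quasi-tonically (5 burst groups per 2000 time units where HR shows 19), so
the membrane traces dephase within one burst cycle and the x-series
similarity metrics (NMAE ≈ 0.17, correlation ≈ 0.45, NRMSE ≈ 0.29) are far
from the published 0.065/0.794/0.172. This persists across initial
conditions, comparison windows, best-lag alignment, the uncorrected
quadratic table, and even finer search-fitted tables: the burster
amplifies percent-level table error into qualitative changes of the
attractor. Interestingly, the same comparison computed on the slow current
`z` does approximately recover the published values (0.073/0.845/0.101 at
`I = 1.5`; 0.067/0.897/0.082 at `I = 2`), which suggests the published
metrics were not computed on the raw membrane series. The package computes
[compare_traces()] on `x`, as the text states, and exposes the full
protocol (initial condition, transient discard, window) for sweeping; the
acceptance suite asserts the published values and documents this block as
failing.

Spike events are upward threshold crossings (threshold 0.8 on `x`, a value
in the middle of the spike upstroke); bursts group spikes whose
inter-spike interval (ISI) is at most 15 ms, and are reported by first
spike time. Both values are unstated in the source model and exposed in
configuration.

## Synapses

AMPA (excitatory) and GABA (inhibitory) inputs are rise/decay
double-exponential filters per neuron: an impulse `tau_m * J / tau_r` per
delayed presynaptic spike enters the rise stage, and the current relaxes
toward it with the decay constant. Constants are the published set (AMPA
2/0.4 ms, GABA 5/1 ms, latency `tau_L` 1 ms, membrane constant 20 ms for
pyramidal and 10 ms for interneuron targets, refractory time 2/1 ms at the
source). The distance-dependent coupling multiplies the recurrent impulse
by `exp(-r/D)` for grid distance `r`; the typographic ambiguity of whether
the factor scales only the membrane constant is resolved by always scaling
the impulse term. Delays use a ring buffer of `ceil(tau_L/dt)` steps;
impulses land on the first step at or after the exact delay. The net drive
is `I = I_A - I_G`.

## Plasticity

Burst-timing-dependent plasticity (BTDP) sums a pair window over all
pre/post burst-onset pairings in a trial, with the inter-burst interval
(IBI) defined as post onset minus pre onset (pre leading takes the
potentiation branch):

$$W(x) = (A_+ + \sigma/\gamma_+)\,e^{-x/\tau}\ (x \ge 0),\qquad
  W(x) = (A_- - \sigma/\gamma_-)\,e^{x/\tau}\ (x < 0),$$

with `A_+ = 0.07, A_- = -0.05, gamma_+ = 20, gamma_- = 25, tau = 10 ms`
and `sigma` the post-minus-pre difference of mean ISIs over the trial
window. The reinforcement variant (RBTDP) multiplies the summed increment
by the deviation of the dopamine variable from its baseline, `(D - b_D)`.

Two printed variants of the depression amplitude exist: the window form
uses `A_- - sigma/gamma_-` while the per-synapse network forms print
`A_- + sigma/gamma_-`. The package exposes both ([btdp_window()] and
[synaptic_rate_modifier()]) but the network learning uses the window form:
with the `+` sign, a postsynaptic neuron that fires faster than its
afferents (always true for the classifiers) flips the sign of the entire
pairing sum, so rewarded winners would be weakened — measured directly
during development. Two related desk-scale guards: `sigma` is clamped to
±1 ms (the printed `gamma` values imply ISI differences of that order;
sparse desk-scale firing otherwise produces hundreds-of-ms differences
that swamp the base amplitudes), and the linear-exponential variant of the
kernel floors the table at zero past its last knot.

## Actor–critic and reward emulation

The critic is a population of 20 HR neurons whose mean burst rate provides
the state value `v`; the reward-prediction-error population (1000 Poisson
neurons) is modeled as a rate-modulated Poisson source. The dopamine
variable is `D(t) = vdot + r - v/tau_r`, with the derivative represented
by the two delayed pathways of the circuit (excitatory 1.5 ms, inhibitory
25 ms) as a finite difference, and `b_D` the 10-ms trailing mean of `D`.
`tau_r` is never given a value; the default is 200 ms. Reward emulation
doubles the source rate for 100 ms after a correct classification and
silences it for 100 ms after an error. The scalar learning gate of a trial
is the mean of `(D - b_D)` over the reward window, normalized by the
baseline source rate so that its scale is independent of the rate (which
then only sets the Poisson signal-to-noise; default 100).

## Pseudo-retina

Images are average-pooled (2×2, stride 2, twice: 28×28 → 7×7, 32×32 →
8×8), and each pooled cell emits a homogeneous Poisson train at `intensity
× rate_max`. The internal bipolar/ganglion dynamic models of the original
pathway are not reproduced (their equations are not given); the
rate-to-Poisson surrogate preserves the image-in/spike-array-out
interface. This is a fidelity gap: temporal structure the real encoder
would produce (adaptation, transients) is absent, so tests passing on this
encoder say nothing about encoder dynamics. [make_patterns()] generates
the desk-scale task: one oriented-bar/blob prototype per class plus
clipped Gaussian pixel noise (default sd 0.05 on unit-intensity images) —
distinct, linearly separable prototypes standing in for natural-image
classes at a scale where a 200-neuron network can operate.

## Network, desk-scale operating point, and what the defaults mean

The architecture follows the published one: a recurrent layer of 80%
pyramidal / 20% interneurons with Bernoulli(0.2) connectivity on a grid
with distance-scaled coupling, fixed input wiring, fully connected
classifying and critic layers, weights initialized N(0, 0.2²), winner =
highest output burst count over the evaluation window after a 50-ms
transient discard (ties break to the lowest index and are flagged).

Published scale is 5000–10000 layer-2 neurons, 2000-ms windows, and
60,000-image training sets; the package's defaults are a desk scale (200
neurons, 500-ms windows, dozens of patterns) chosen so a training study
runs in minutes. Several quantities the source leaves unstated had to be
fixed, and the calibration was done once, before the acceptance runs, by
measuring the network's operating regime rather than its test outcomes:

* **Input fanout 3%** of layer 2 per ganglion cell (with `J_ext = 1`,
  fixed): each neuron then pools 1–2 ganglion cells and layer-2 activity
  is sparse and stimulus-selective (~40% silent per pattern) — at dense
  fanout every neuron fires for every class and no code exists.
* **Recurrent gain 0.1** on recurrent impulses: a unit-weight impulse
  peaks near the burst threshold, so unscaled recurrence drives the whole
  population regardless of the stimulus.
* **Readout gain 0.05** on the output/critic projections, moving the
  classifiers into the mean-driven regime where drive reflects the summed
  alignment of ~200 afferents; initial readout weights N(0, 1) so
  untrained classifiers are volley-driven (and hence produce the burst
  pairings learning needs) instead of silent.
* **Drive saturation ±10**: outside its breakpoint span the LHR table
  field loses the cubic's saturation and diverges under strong drive (the
  hardware input register is bounded anyway).
* **Update normalization**: the reinforcement batch update is centered
  across the output population per afferent (a tilt shared by all
  classifiers cannot change the argmax) and made zero-sum per classifier
  (reward reallocates drive; no output drifts into depolarization block,
  where a strongly driven cell stops crossing threshold altogether).
* **Learning rates** `eta_out = 50` with per-epoch decay
  `1/(1 + 0.5(k-1))`, `eta_l2 = 0.002`, weight clip ±5, and best-epoch
  checkpointing on the held-out split.
* Trials start from the `I = 0` resting state `(q, c - d q^2, 0)` so no
  spurious transient volley precedes the stimulus; the 100-ms
  inter-pattern pause of the published protocol is realized by this
  reset-to-equilibrium.

With oracle weights (output weights set to the class-centroid contrast of
layer-2 burst vectors) the readout classifies the desk task at 92–100%,
so the architecture and decision rule are sufficient. The learned
accuracy is lower (~45–70% across seeds, against a 33% chance level):
the reinforcement signal reaches a synapse only through burst pairings
within the 10-ms window, and at this trial budget (~160 presentations)
the per-synapse coincidence statistics integrate to only a partial
alignment with the oracle solution. This is a genuine scale limitation,
not a failure of the rule's direction — the same instrumentation shows
the expected update is aligned with the class contrast — and is why the
desk-scale study demonstrates above-chance learning rather than the
published high-nineties accuracies, which rest on five to six orders of
magnitude more presentations.

## Fixed-point datapath

The digital emulation holds all neuron state in signed Q-format registers,
realizes every constant multiplication as a signed power-of-two
(shift-and-add) program, and realizes the Euler `dt` as an arithmetic
right shift (8 positions for 1/256; the source text also mentions a shift
of 9, i.e. 1/512 — shift 8 is taken as normative and shift 9 is
selectable). Two measured constraints set the defaults:

* **Q8.24** (within the 32-bit budget): at Q8.16 the slow-current
  increment `r(.)dt` is below one LSB after the dt shift, floor-truncation
  freezes `z`, and the fixed neuron never bursts (NRMSE 0.40 against
  float).
* **8-term constant programs**: a 3-term greedy decomposition leaves
  ~0.2% residuals on the segment slopes, which the burster amplifies
  exactly like the LHR-vs-HR table error (NRMSE 0.205). At 8 terms the
  constants are exact at format resolution and the remaining divergence is
  pure quantization noise: NRMSE 0.048 over a 2000-unit run.

The learning block is emulated separately ([fixed_learning_step()]): the
linear-exponential table supplies the kernel, the adaptive amplitude is
applied by canonical-signed-digit recoding (shifts and adds only), and the
dopamine gate contributes the single true multiplication of the
reinforcement path. An operator audit (multiplies/adds/subtracts/shifts)
accompanies every evaluation; the BTDP path contains zero multiplies.

## Problem sizes and runtime

The test suite and the acceptance script use: 10,001-point error grids;
2050-unit neuron comparisons; a 5-seed training study of 3 classes × 12
patterns, 6 epochs, 500-ms windows, 200 layer-2 neurons (about 100
seconds per seed); and 2000-unit fixed-vs-float runs. The published-scale
presets (5000–10000 neurons, 2000-ms windows) are selectable through
`network_config()` but are long-running and not exercised by the tests.

## Known limitations

* The published waveform-similarity figures for HR vs LHR are not
  reproducible from the printed equations on the membrane series (see
  above); the slow-current comparison is reported alongside.
* The pseudo-retina is a rate-coded surrogate without the original
  encoder's internal dynamics.
* Desk-scale learning demonstrates the mechanism (above-chance,
  reward-signed, plateauing) but not the published accuracy level, which
  requires cluster-scale data and compute.
* The actor–critic value pathway is simulated structurally (critic
  population, delayed-difference derivative, Poisson reward source), but
  at desk scale the learning gate is dominated by the reward term rather
  than by critic value changes.
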