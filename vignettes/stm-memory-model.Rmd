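---
title: "A fixed-point spiking memory network: model, training and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A fixed-point spiking memory network: model, training and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the model and its assumptions, the parameters that matter, what the
synthetic-data generator does and does not emulate, the numerical choices,
and the places where the design was genuinely open and a choice had to be
made.

## 1. The memory model

Information is stored by *temporal population coding*: each memory item is a
small assembly of neurons, and the item's content is the precise spike time
of each member within one gamma cycle. Three kinds of memory live in one
network:

* **Hetero-associative** — feedforward weights from the input channels to
  the layer-I assemblies; presenting a pattern makes exactly its assembly
  fire.
* **Auto-associative** — recurrent weights within a layer-I assembly; a
  partial cue recruits the missing members (pattern completion).
* **Episodic** — directed weights between layer-II assemblies; cueing the
  first item of a learned sequence replays the rest in order.

All neurons are leaky integrate-and-fire units evaluated on a 1 ms grid,
once per "evaluating period": synaptic integration over the spikes emitted
in the previous step, a constant leak, then a threshold compare with
fire-and-reset. Every synapse has a uniform one-step delay (hardware
pipeline semantics). The simulator is bit-accurate with respect to the
intended hardware: potentials are signed 14-bit integers with saturating
arithmetic, leaks signed 8-bit, weights signed 11-bit, and thresholds scale
so that the float training threshold 1 becomes 1,000.

## 2. Maintenance: ADP and theta as auxiliary neurons

A recalled item must keep firing for several theta cycles after its
stimulus disappears. Two slow signals produce this: a ramping
after-depolarizing potential (ADP) restarted by each of the neuron's own
spikes, and a global theta oscillation. Neither is representable inside a
plain LIF neuron, so both are *externalized into auxiliary neurons* and
delivered as difference-encoded synaptic input, so that an active membrane
follows

v(t) = v(t−1) + ΔADP(t − t_last_spike) + Δθ(t).

* The **ADP kernel** is linearized to a ramp of `slope = 0.0055` units/ms,
  floored to a 0.01 quantization grid (a staircase on or below the line)
  and capped at `slope × τ_ADP` with `τ_ADP = 12` gamma periods
  (≈ 0.65 at the default gamma of 9.9 ms). Each recall neuron owns one ADP
  neuron: an LIF with `v_reset = v_thr` and zero leak, which therefore
  fires on every step once triggered by its normal neuron — the concrete
  realization of "fires continuously unless inhibited".
* The **theta waveform** is a full sine `A sin(2πt/T)` with `T = 66 ms`,
  `A = 0.6`, quantized to the same 0.01 grid. A full sine is the one
  waveform that reconciles the two published bank sizes: the amplitude bank
  needs `A / w_θ = 60` neurons, and the difference bank needs
  `ceil(max|dθ/dt| · 1 ms / w_θ) = ceil(2πA/T / 0.01) = 6`; a raised-cosine
  would need only 3. The difference bank delivers `Δθ(t)` to every recall
  neuron on every step; the amplitude bank re-injects `θ(t−1)` into a
  neuron on the step after it fired, restoring the theta baseline that the
  reset erased. Signed contributions are carried by the ± quantum weights;
  the engine activates `|n|` bank neurons with the appropriate sign.

**The leak-compensation design.** A collapsed layer-I/recall neuron has to
do two jobs with one leak constant: erase stimulus residue quickly
(selectivity needs a leak of 0.045/ms) and integrate the ADP/theta
increments losslessly (Eq.-style tracking needs zero leak). The package
resolves this by making the ADP neuron's per-step delivery equal to the
target's leak plus the staircase increment. A neuron with an active ADP
chain therefore integrates exactly ΔADP + Δθ per step, while a resting
neuron — which receives no ADP delivery — keeps its full leak and decays to
rest. This preserves the published layer leaks (45 and 28 at scale 1000) on
the neuron table and gives both behaviours. The resting floor at 0 is
engaged only through the leak, so a maintained neuron's potential is
truncated at 0 near the theta valley; the truncation is what lets it
re-cross threshold on the next rising phase (the "pump"), locking refires
to roughly one per theta cycle. A refire may occasionally slip to the next
crossing while the ADP ramp is young; the oscillation tests assert the
cycle-locked cadence with a 1.25-period allowance.

## 3. Architecture and census

The default configuration stores four associative items and one episodic
item (the sequence of the four). Assembly sizes are 10 (input), 8
(layer I), 10 (layer II); consecutive input assemblies share 50% of their
channels (chained overlap). That yields 97 distinct normal neurons in the
logical three-layer network (25 + 32 + 40). On hardware the input layer is
not realized (stimuli are routed directly onto the recall layer) and
layer I is collapsed into the recall layer, so the realized census is
32 recall + 40 layer-II normals + 8 interneurons + 32 ADP + 60 + 6 theta
neurons = 178 LIF neurons. This collapse is the only decomposition
consistent with the three published counts (178 total, 32 ADP, 66 theta);
`build_network(on_hardware = FALSE)` keeps the separate layer-I population
for structural inspection.

Each assembly in the recall and II layers owns one **interneuron**: it is
driven by its own assembly (weight 0.3 per member) with a threshold set so
a strict majority firing within one step triggers it, and it inhibits every
other same-layer assembly (weight −0.2). This separates different
assemblies' volleys into different steps (gamma-subcycle separation) and
suppresses residual cross-talk. Interneuron-to-ADP inhibition — the
synaptic "stop" for a maintenance chain — is wired when
`adp_inhibition_weight` is non-zero but ships disabled: with
difference-encoded ADP delivery, a single inhibitory hit on another
assembly's ADP neuron permanently erases that memory's maintenance, which
contradicts the multi-item maintenance the model is meant to exhibit.
Termination instead happens at the end of the stimulation schedule (the
run simply ends); the enabled path is unit-tested on a two-assembly
micro-network, where the rival interneuron demonstrably kills the chain.

Layer-II neurons use a reset potential of −1 (scale units −1000): a
one-step relative refractory period that absorbs the trailing millisecond
of a spread-out recall volley, so one assembly occupies one gamma subcycle
instead of double-firing into its successor's slot.

The hardware memory cost is pure integer arithmetic: 50 bits per neuron
record (14 + 8 + 14 + 14), 11 bits per synapse, 1 spike bit per neuron,
totalled in exact bits and reported in kilobits (1 kb = 1000 bits). The
published synapse count (8,512) is a configuration constant of the cost
report; the package's own builder instantiates full trainable connectivity
(7,096 synapses by default) and reports, but does not assert, that number.

## 4. Training

Training is offline, floating point, and entirely separate from fixed-point
inference (no online learning in the simulated hardware). Three phases:

1. **Input → layer I (tempotron).** Each recall neuron is a fire/no-fire
   tempotron: on a miss, every presynaptic spike before the time of maximal
   potential is potentiated by `lr · exp(−(t_max − t_j)/τ)`; on a false
   alarm the same magnitude is subtracted; weights are clipped to
   [0, 0.25]. The kernel is a single exponential with τ = one gamma
   period, matching the LIF inference neuron (no second time constant).
   Training simulates the same 1 ms grid as inference *including the
   quantized theta increments after a valley-aligned presentation*, so the
   decision boundary learned is the one the engine will see. Each assembly
   trains with graded firing margins (evenly spaced from 0.25 to 0.85
   above threshold across its 8 members, rejection margin 0.1 below):
   the high-margin members still cross threshold under a degraded cue and
   ignite the rest through the recurrent weights. Margins that the pattern
   geometry cannot support (e.g. at 75% overlap) are annealed down to the
   base margin after half the epoch budget; margins already achieved
   persist, because the tempotron only updates on errors.
2. **Layer I → layer II (tempotron).** Same rule, with the layer-I
   first-crossing volleys as presynaptic teacher trains.
3. **Lateral weights (STDP).** Additive STDP,
   `±A e^{∓Δt/τ}` with A = 0.02 and τ = one gamma period, applied to the
   teacher spike trains produced by the trained feedforward stages and
   clipped to the lateral caps. Isolated single-pattern presentations
   (repeated 20×) potentiate the recurrent connections *within* each
   recall assembly — auto-association. The episodic item is taught by a
   temporally compressed presentation of the sequence (items one gamma
   period apart), and its STDP is restricted to *between-assembly* pairs in
   layer II, potentiating the forward chain (backward pairs are
   depressed). None of these constants is published; all live in
   `learning_config()`.

Two lateral caps are deliberately different. The recall-layer cap (0.08)
keeps the total recurrent drive on a member (7 × 0.08 = 0.56) below what
would let a synchronized volley re-excite itself through its own
recurrence plus the re-injected theta baseline — no runaway echo — while
still bridging the gap for members missing up to ~30% of their input. The
layer-II cap (0.15) makes one full assembly volley (10 × 0.15 = 1.5)
sufficient to ignite the next assembly in the stored sequence through a
single synaptic step, which is what makes the replay cascade tick at
millisecond hops in stored order.

After training, `fixpoint_network()` rounds weights and leaks
half-away-from-zero at scale 1000 into 11-bit/8-bit signed integers
(thresholds 1 → 1000, 14-bit) and warns if anything saturates. On the
default configuration nothing saturates and the trained excitatory weights
stay within 0–300 scale units; the float and fixed-point networks make
identical clean-pattern layer-I decisions.

## 5. The synthetic-pattern generator

`generate_patterns()` *is* the study's data source; there is no external
dataset. Each input channel carries exactly one spike at a time drawn
uniformly on the 1 ms grid of one gamma cycle, and overlapping assemblies
share channels — and therefore share spike times — by construction
(chained overlap between consecutive assemblies, share =
`round(overlap × size)`, half-away-from-zero). Noise enters only through
`apply_noise()`: independent Gaussian jitter of the spike times (sd 1–5 ms,
clipped to the gamma window) or uniform deletion of a fixed number of
spikes with surviving times untouched. The sweep "variance [1, 5] ms" is
interpreted as a standard deviation swept over 1–5 ms — a variance in ms²
would be dimensionally inconsistent with a per-spike time offset.

What this emulates: precisely timed, population-coded stimuli with
controlled feature overlap and two clean, orthogonal noise axes. What it
does not emulate: rate coding, correlated (shared) jitter across channels,
spurious insertions, channel dropout over trials, or any natural-stimulus
statistics. Passing the robustness tests therefore says the *architecture*
degrades gracefully under timing noise and missing features; it says
nothing about performance on naturalistic inputs.

## 6. Scoring and experiment design

Recall fidelity is the cosine of Gaussian-filtered spike trains
(σ_c = 2 ms), evaluated on a 0.1 ms grid; the tests verify it against the
continuous closed form (two single spikes offset by δ score
`exp(−δ²/4σ_c²)`) to 10⁻³. The score of a trial is computed per recall
neuron against that neuron's *clean reference train* — the response the
same trained network gives to the clean cue — and averaged over the cued
assembly; selectivity additionally requires every other assembly to stay
below 0.5 against its own reference (silence scores 0 by the empty-train
convention). A pattern counts as recalled when its score is ≥ 0.9 and the
selectivity condition holds. The reference window is one theta period from
the presentation, which covers the stimulus-driven volley and the first
maintenance refire.

The robustness sweep trains one network per input assembly size
(5, 10, 15, 20; layer I is ¾ of the input size, layer II equal to it) and
perturbs each stored pattern 20 times per noise cell. Twenty repeats keeps
the full sweep around a minute of CPU while the sampling error of a cell
mean stays near 0.05, which is the tolerance the monotonicity checks use on
adjacent noise levels (0.15 for adjacent sizes, whose trainings are
independent). The overlap sweep retrains at each ratio and scores clean
recall; the gamma sweep locks theta:gamma at 20/3 and τ_ADP at 12 γ and
holds the ADP cap constant by scaling the ramp slope inversely with τ_ADP,
reporting associative success, replay order, and whether distinct layer-II
assemblies ever fire in the same millisecond during replay.

## 7. Numerical choices and degenerate inputs

* Grid quantization uses `floor` (the staircase sits on or below the
  continuous curve), with a 10⁻⁹ epsilon guard so exact grid points are not
  pushed down by float representation error. Rounding to integers anywhere
  (fixed-point conversion, overlap share) is half-away-from-zero.
* Saturating, never wrapping, arithmetic at the 14-bit potential
  boundaries; the resting floor engages only through a non-zero leak, so
  zero-leak auxiliary neurons keep exact signed values.
* The fire rule is `≥` threshold; `reset = threshold` is legal and gives
  the continuous-firing ADP contract; `reset < 0` is legal and gives the
  layer-II refractory.
* Empty cases are defined, not errors: an empty spike train scores
  `R_corr = 0`, an empty schedule yields a raster containing only
  theta-bank events, an untrained network recalls nothing.
* Presentations snap to theta valleys (phase 3T/4); with the 66 ms period
  the valleys fall on half-milliseconds and input spike times round to the
  engine's integer grid.
* Engine state (potentials, previous spikes, per-neuron last-fire times) is
  plain data; a run can be serialized mid-way and resumed with an identical
  continuation.

## 8. Known limitations

* The layer-I/recall collapse is a modelling commitment: one neuron per
  assembly slot carries both the selective response and the maintenance
  role. The alternative (a separate 32-neuron relay) is built in
  off-hardware mode but not simulated by default.
* Episodic replay is temporally compressed (millisecond hops between
  assemblies), faster than one assembly per full gamma subcycle; order, not
  spacing, is the tested property.
* Simultaneous maintenance of several items works, but their refire volleys
  can collide in the same millisecond once several ADP ramps saturate at
  the cap; the per-step separation property is therefore stated and tested
  for single-cue runs (stimulation volleys are separated by construction,
  one per theta cycle).
* Training constants (learning rates, margins, caps, epochs, STDP
  amplitudes) are design choices of this package, chosen once for the
  default geometry; they are exposed in `learning_config()` but not
  auto-tuned.
* The gamma-period sweep reports what the fixed mechanism does as the
  oscillation time base shrinks; no attempt is made to re-tune the
  interneuron or margin constants per gamma.
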