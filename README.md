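# stmnet

A bit-accurate software model of a hardware-oriented **spatio-temporal memory
(STM)** spiking neural network. The package is for computational
neuroscientists and neuromorphic-hardware engineers who want to simulate,
train and stress-test an assembly-coded associative/episodic memory built
from fixed-point leaky integrate-and-fire (LIF) neurons, before (or instead
of) committing it to silicon.

## The model

Memory items are stored as **neural assemblies** — small groups of neurons
that code one item by the precise timing of their spikes within a gamma
cycle. The network has four layers: an input layer (spike sources), a
layer I / recall layer holding the hetero- and auto-associative memory, and
a layer II holding episodic (sequence) memory. Every computing element is a
LIF neuron updated once per millisecond:

- integrate: `v_i(t) = v_i(t-1) + Σ_j x_j(t) w_ij` (saturating 14-bit
  arithmetic),
- leak: `v_i(t) = v_i(t) - v_l` (clamped at the resting floor 0),
- fire and reset: if `v_i(t) ≥ v_thr`, emit a spike and set `v_i(t) = v_reset`.

Repetitive firing — the mechanism that holds an item in memory across theta
cycles — comes from two slow processes delivered as *synaptic input from
auxiliary neurons* rather than as intrinsic dynamics:

- a linearized **after-depolarizing potential (ADP)**, a ramp of 0.0055
  potential units/ms quantized to a 0.01 grid and capped at
  `slope × τ_ADP` (τ_ADP = 12 gamma periods), delivered by one dedicated ADP
  neuron per recall neuron (an LIF with `v_reset = v_thr` and zero leak, so
  it fires continuously once triggered);
- a **theta oscillation** `A sin(2πt/T)` (T = 66 ms, A = 0.6) quantized to
  the same grid and delivered by two banks of theta neurons with quantum
  weights ±0.01: 60 amplitude-encoding neurons (re-injecting the theta
  baseline lost when a neuron resets) and 6 difference-encoding neurons
  (delivering the per-millisecond change `Δθ(t)` to everyone). The
  membrane of an active neuron therefore follows
  `v(t) = v(t-1) + ΔADP(t - t_i) + Δθ(t)`.

Training is offline and floating point (all thresholds = 1): inter-layer
weights learn with the **tempotron** rule, intra-layer weights with **STDP**;
the trained weights and leaks are then rounded to signed 11-bit integers
(scale 1000, so threshold 1 → 1,000) for the fixed-point network that the
simulation engine runs. Recall fidelity is scored with the Gaussian-filtered
spike-train correlation

```
R_corr = (s_a · s_d) / (|s_a| |s_d|),   σ_c = 2 ms,
```

the cosine of the filtered actual and desired output trains.

## Worked example

```r
library(stmnet)

map <- build_assemblies()        # 4 patterns, sizes 10/8/10, 50% overlap
map
#> <assembly_map> 4 patterns; sizes input=10 layer1=8 layer2=10; overlap 50% (share 5)
#>   distinct normal neurons (input + layer I + layer II): 97

net <- build_network(map)        # hardware topology with theta/ADP machinery
net
#> <stm_network> 203 neurons (178 LIF), 7096 synapses [scale 1]
#>         adp       input interneuron      normal      theta1      theta2
#>          32          25           8          72          60           6

patterns <- generate_patterns(seed = 1)
net  <- train_network(net, patterns, sequence = 0:3,
                      cfg = learning_config(seed = 1))
qnet <- fixpoint_network(net)    # 11-bit weights, threshold 1 -> 1000

round(recall_scores(qnet, patterns, cue = 0), 3)
#>  0  1  2  3
#>  1  0  0  0

recall_episode(qnet, patterns, cue = 0)
#> [1] 0 1 2 3

memory_cost_report(n_neurons = 178, n_synapses = 8512)
#>          item single_cost_bits count total_kb
#> neuron neuron               50   178    8.900
#> weight weight               11  8512   93.632
#> spike   spike                1   178    0.178
#>         total               NA    NA  102.710
```

The recall scores say that cueing pattern 0 reproduces its stored layer-I
response perfectly (`R_corr = 1`) while the other three assemblies stay
silent; `recall_episode()` shows the stored four-item episode replaying in
order from its first cue alone; the cost table is the on-chip memory budget
in kilobits (1 kb = 1000 bits) for the 178-neuron configuration.

`run_pipeline(stm_config(), "stm_out")` executes
build → train → quantize → simulate → evaluate and writes the network
tables, a hex weight-memory dump, the demonstration spike raster and the
evaluation tables, each stamped with the configuration hash and seed. The
same stages are exposed as a shell tool in `inst/cli/stm`
(`stm pipeline`, `stm cost`, `stm eval-noise`, ...). The robustness sweeps
are `experiment_noise()` (spike-time jitter 1–5 ms, spike deletion
{2,3,5,8}, input assembly sizes 5–20), `experiment_overlap()` (5–75%) and
`experiment_gamma()` (1–25 ms with theta:gamma locked at 20/3 and
τ_ADP = 12 γ).

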