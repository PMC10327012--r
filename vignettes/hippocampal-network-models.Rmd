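---
title: "From parameter tables to spiking hippocampal circuits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From parameter tables to spiking hippocampal circuits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

hippospike turns neuron-type parameter tables -- a census of counts,
single-compartment Izhikevich neuron models, directed connection
probabilities, and Tsodyks-Pawelzik-Markram (TPM) synapse constants -- into
simulatable spiking networks of the rodent hippocampal formation, and
implements the potential-connectivity estimation that produces such
connection probabilities from axonal/dendritic lengths, inter-bouton
distances, and parcel volumes. This vignette explains the models, the
parameters that matter, the numerical choices, and what the synthetic
fixtures do and do not establish about real data.

## The knowledge model

A `knowledge_base` is five cross-indexed tibbles. Neuron types are defined
the way the field's hippocampal classifications define them: by subregion
(DG, CA3, CA2, CA1, Sub, EC), main neurotransmitter (excitatory glutamate
vs. inhibitory GABA), and a laminar code -- one digit per layer of the home
subregion (0 none, 1 axons only, 2 dendrites only, 3 both), with a trailing
`"p"` for types projecting into other subregions. Each type carries an
importance rank from 1 (essential to circuit function) to 5 (dispensable),
so simplified circuits can be cut with `select_types(kb, max_rank = 1)`.

Four invariant families are enforced at load time: range constraints
(probabilities in [0, 1], utilization in (0, 1], `Vr < Vt < Vpeak`),
referential integrity (no connection or census row may name an unknown
type), uniqueness (type names; directed pairs), and single-species censuses
(counts are species-specific, so mixing rat and mouse rows in one build is
an error). Every violation is reported with its table and row.

Where a value is missing the package fills it and says so. Unmeasured
connection probabilities take the class-averaged defaults -- 0.0117 (E to
E), 0.0237 (E to I), 0.00684 (I to E), 0.00423 (I to I) -- and unmeasured
neuron-model and synapse rows take documented package constants
(`default_izhikevich_row()`, `default_tpm_row()`). All filled rows carry
`is_default = TRUE` into the exported CSVs, so provenance survives a round
trip. The fill is idempotent and completes the connection table over the
full Cartesian product of retained types, self-pairs included (recurrent
populations such as CA3 Pyramidal are real). One deliberate wrinkle: the
neuron-type file has no flag column, so a missing rank is filled with the
middle value 3 and reported via a warning rather than a persisted flag --
keeping `read_knowledge_base(write_knowledge_base(kb))` exactly identical
to `kb`, which the package treats as a hard invariant (doubles are written
with 17 significant digits and parsed with base R's correctly rounded
reader for this reason).

## Potential connectivity from axonal-dendritic overlap

The estimator asks: if a presynaptic axon places boutons along its length
inside a parcel (one layer of one subregion, e.g. CA3 stratum lucidum),
what is the chance that any of them lands within reach of one particular
postsynaptic neuron's dendrite? The ingredients per parcel are the axonal
length `La`, the mean inter-bouton distance `ibd` (so the bouton count is
`Nb = La / ibd`), the target's dendritic length `Ld`, the parcel volume
`V`, and an interaction radius `r` (default 1 um, the order of bouton plus
spine reach; configurable). A single bouton hits with probability
`q = min(1, Ld * pi * r^2 / V)` -- the dendrite's interaction cylinder as a
fraction of the parcel. Treating bouton placements as independent,

* expected synapses: `lambda = sum_k Nb_k q_k`,
* connection probability: `p = 1 - prod_k (1 - q_k)^(Nb_k)`,
* contacts per connected pair: `lambda / p` (the conditional expectation
  given at least one contact; undefined at `p = 0`).

Always `p <= lambda`, and contacts is at least 1 whenever `p > 0`. The
closed form keeps fractional bouton counts; the Monte-Carlo reference
(`simulate_connection()`) floors them, so the two routes are compared on
integer counts. The binomial-overlap form is the package's operational
model: published potential-connectivity tables derive from richer
morphology-specific machinery, and reproducing any particular published
probability table is explicitly out of scope (it requires per-parcel
dendritic lengths and hull volumes that are not packaged here). What ships
instead are the printed worked-example inputs: the mossy-fiber scenario
(3,236 um of granule-cell axon, all in stratum lucidum; inter-bouton
distances 162 / 284 / 67.4 um, the last implying 48 contactable
interneurons) with placeholder volumes flagged as synthetic, and the
Schaffer-collateral inputs (axon fractions 27.5% and 64.1% with their
per-layer splits; inter-bouton reports 3.7 / 4.4 / 4.29 um averaging to 4.1
um at display precision). Whether "contacts" should be the conditional
expectation or some other summary of the per-pair count distribution is not
settled usage; the conditional expectation is the choice here because it is
what multiplying a connected pair's conductance should preserve.

## Neuron dynamics

Each type is a nine-parameter single-compartment Izhikevich model:
`C dv/dt = k (v - Vr)(v - Vt) - u + I`, `du/dt = a (b (v - Vr) - u)`, with
reset `v <- Vmin`, `u <- u + d` when `v` reaches `Vpeak`. Units are pF,
nS/mV, mV, 1/ms, nS, pA throughout; this is the dimensional convention
GPU-oriented spiking simulators use, so fitted parameter sets drop in
unchanged. Integration is forward Euler at `dt = 0.1` ms by default
(configurable), with the spike stamped at the step where `v` crosses
`Vpeak` and the recorded sample capped at `Vpeak`. Euler is the deliberate
choice over a higher-order scheme: the hybrid reset makes the trajectory
only piecewise smooth, the field's simulators use the same convention, and
the package's tests pin the behavior that matters -- rest `(Vr, 0)` is an
exact fixed point at `I = 0`, subthreshold error shrinks linearly in `dt`,
and spike times at `dt = 0.1` vs `0.01` ms agree within 1 ms for the
fixture parameter sets over a 1 s near-rheobase protocol. Away from
rheobase the per-interval phase bias accumulates (about 0.1 ms per
interspike interval at 45 Hz), which is why convergence is stated for spike
times, not for phase at arbitrary rates.

Protocols mirror standard cell characterization: a 1 s square pulse with
100 ms padding (`step_protocol()`), F-I curves swept in 10 pA increments
(`f_i_curve()`), rheobase by bisection (`rheobase()`), and a 430 pA / 500
ms demonstration pulse in the tests. Firing-pattern phenotypes
(`classify_firing_pattern()`) use a deliberately simple, total, and
deterministic rule tree over ISI statistics -- silence = no spikes in the
final half of the stimulus; stuttering = ISI CV at least 0.5 with a
largest gap at least 3 times the median ISI (transient if every gap ends in
the first third, else persistent); adapting = last-to-first ISI ratio at
least 1.5. These thresholds are package-defined simplifications of the
field's quantitative phenotype pipeline, adequate for labeling simulated
trains, and are not a reimplementation of any published classifier.

## Synapse dynamics

Synapses follow the TPM short-term plasticity model with five constants per
directed pair: conductance `g`, decay `tau_d`, recovery `tau_r`,
facilitation `tau_f`, and utilization `U`. Between presynaptic spikes the
state relaxes in closed form (`R` toward 1, `u` toward 0, conductance
toward 0); at a spike, facilitation applies before release
(`u+ = u + U(1 - u)`, released `= R u+`), the common convention where the
update order is not otherwise specified. Letting `u` relax to 0 and
re-adding the baseline at spike time (rather than relaxing to `U`) is the
package's documented choice; it only affects facilitating pairs. Synaptic
current is conductance-based, `I = g_t (E_rev - v)`, with reversal
potentials 0 mV (excitatory) and -70 mV (inhibitory) by default. Three
independent anchors check the implementation: a dense-ODE route through
`deSolve::ode()` with spike events (event-driven vs. dense agree to better
than 1e-6 relative release per spike over random trains), the analytic
fixed point of the periodic-train recurrence
(`tpm_periodic_fixed_point()`), and bound preservation under random
decay/spike interleavings.

## Network instantiation and simulation

`build_populations()` sizes each population as
`max(1, round_half_up(scale * count))` -- a retained type never vanishes,
and half counts round up. Wiring is independent Bernoulli per ordered pair
(self-edges excluded within a population), implemented by drawing the edge
count from the exact Binomial(M, p) law and then sampling that many
distinct pairs uniformly; the result is distributionally identical to
per-pair coin flips and passes a chi-square goodness-of-fit against the
binomial across seeds. Every directed pair draws from a substream seeded by
the master seed and the pair's names, so adding a type to a build leaves
every other pair's realization untouched. The expected contacts per
connected pair scale each edge's conductance instead of creating
multi-edges -- identical postsynaptic drive at a fraction of the memory;
conduction delays default to uniform 1-2 ms (no delays are tabulated in
the knowledge model).

The engine advances all populations with the same vectorized Euler update
as the single-neuron path. TPM state lives per (group, presynaptic neuron)
-- exact, because the plasticity state depends only on the presynaptic
spike train -- and is updated event-driven at spikes using the closed-form
relaxation since that neuron's previous spike. Released conductance is
scheduled through a ring buffer and lands on the postsynaptic group
conductance after the edge's delay (rounded to steps, minimum one step, so
causality is strict: nothing arrives earlier than spike + delay).
Per-group conductances decay by the exact factor `exp(-dt / tau_d)` each
step. Background drive is an independent constant-plus-white-noise current
per neuron; the noise is redrawn per step, so its integrated effect is
step-size dependent -- refinement comparisons must use zero noise SD.
Determinism is bit-level for equal (network, duration, dt, seed).

The LFP proxy is the summed absolute synaptic current onto a reference
subset (by default the excitatory populations) -- a standard computable
stand-in, not a biophysical field model. Band analysis uses the canonical
theta (4-12 Hz), gamma (25-100 Hz), and ripple (150-200 Hz) bands with a
zero-phase Butterworth band-pass (2nd order, filtered forward and backward,
hence 4th-order magnitude response) over a reflection-padded signal.

## What the fixtures emulate -- and what they do not

All inputs are generated in code. The toy circuit (2 excitatory + 2
inhibitory types across DG and CA3) and the randomized generator
(`make_random_kb()`) exist to exercise invariants. The CA3-like demo
(`make_ca3_demo()`) has the real circuit's composition -- one excitatory
Pyramidal type plus the Axo-Axonic, Basket, Basket CCK+, Bistratified,
Ivy, MFA ORDEN, and QuadD-LM interneuron types -- with census counts chosen
so `scale = 0.005` instantiates 500 Pyramidal cells and 50 of each
interneuron type (850 neurons), the composition a raster of such a model
would display. Its neuron models (one regular-spiking and seven jittered
fast-spiking parameterizations), connection motif, synapse constants, and
the matching drive (`ca3_demo_drive()`: 150 pA to Pyramidal cells, 70 pA
to interneurons, 30 pA noise SD) are plausible package-defined fixtures
chosen once for balanced activity (Pyramidal near 10 Hz, interneurons
40-80 Hz); none are measured values, and passing the demo shows the
machinery composes and stays stable -- not that real CA3 dynamics are
reproduced. Oscillation structure in the demo's LFP proxy is treated as a
demonstration, not a validated claim.

## Problem sizes and numerical choices, collected

* Default `dt` 0.1 ms; traces downsampled to 1 kHz; LFP proxy downsampled
  to 1 kHz before band filtering (ripple band needs at least 400 Hz).
* Demo runs used by the tests and the acceptance script: 850 neurons for
  1 s (the full demo), 170 neurons for 300 ms (refinement checks), chosen
  as the scales at which the statistical checks are already stable.
* TPM cross-checks: 100 random trains, `deSolve` lsoda at `rtol = 1e-10`;
  Monte-Carlo connectivity: 1e5 replicates compared at 3 standard errors.
* Wiring statistics: 200 seeds of a 100 x 100 block at p = 0.0117,
  chi-square at alpha = 0.01.
* Ties in census rounding go up (`round_half_up`); bouton counts stay
  fractional in the closed form and are floored only in the Monte-Carlo
  route; contacts at `p = 0` are `NA` by contract.

## Known limitations

Single-compartment neurons only; no distance-dependent or topographic
connectivity; no conduction-distance delays; the drive is stationary
(no patterned input); the LFP proxy ignores morphology and electrode
geometry; the firing-pattern rules are simplifications; and published
connectivity tables are not reproduced, only the estimation machinery and
its printed worked examples. The full-scale census (about a million
neurons for a complete circuit) is representable in the tables but not
practical in this pure-R engine; the intended regime is scaled-down
circuits up to a few thousand neurons.
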