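# hippospike

Data-driven spiking neural network models of rodent hippocampal circuits,
built from neuron-type parameter tables.

Quantitative hippocampal knowledge bases tabulate, per neuron type and per
directed pair of types, the four quantities a circuit model needs: (i) a
census of neuron counts, (ii) an input-output response function, (iii) a
connection probability, and (iv) unitary synaptic signals. hippospike is an
R toolkit for scientists who work with such tables: it validates and
subsets them, fills documented defaults where measurements are missing,
instantiates probabilistic connectomes from them, simulates the resulting
conductance-based spiking networks, and implements the potential-
connectivity estimation that produces connection probabilities from
axonal/dendritic overlap in the first place.

## The models at its core

**Neurons** are nine-parameter single-compartment Izhikevich models,

    C dv/dt = k (v − Vr)(v − Vt) − u + I
      du/dt = a (b (v − Vr) − u)
      if v ≥ Vpeak:  v ← Vmin,  u ← u + d

with C in pF, k in nS/mV, potentials in mV, a in 1/ms, b in nS, d in pA.

**Synapses** follow the Tsodyks–Pawelzik–Markram (TPM) short-term
plasticity model with five constants per directed pair (g, τ_d, τ_r, τ_f,
U): resources R recover toward 1 with τ_r, utilization u decays with τ_f
and jumps by U(1 − u) at each presynaptic spike, the released fraction
R·u⁺ is subtracted from R and added (times g) to a conductance decaying
with τ_d; the postsynaptic current is I = g_t (E_rev − v).

**Potential connectivity**: an axon of length La with inter-bouton
distance ibd places Nb = La/ibd boutons in a parcel; each lands within the
interaction cylinder of a target dendrite (length Ld, radius r, parcel
volume V) with probability q = min(1, Ld·πr²/V). Per directed pair,
λ = Σ Nb·q expected synapses, connection probability
p = 1 − Π(1 − q)^Nb, and contacts per connected pair λ/p.

## Worked example

```r
library(hippospike)

# Mossy-fiber worked example: one DG granule cell's 3,236 um of CA3 axon,
# at one en-passant/filopodial bouton per 67.4 um, reaches 48 interneurons
round(bouton_count(3236, 67.4))
#> [1] 48

# Schaffer-collateral inter-bouton distance, averaged across three reports
round(mean_interbouton_distance(c(3.7, 4.4, 4.29)), 1)
#> [1] 4.1

# Unmeasured connection probabilities are filled with flagged
# class-averaged defaults (EE 0.0117, EI 0.0237, IE 0.00684, II 0.00423)
kb <- fill_missing_probabilities(make_incomplete_kb(completeness = 0.5))
dplyr::count(kb$connections, is_default)
#> # A tibble: 2 × 2
#>   is_default     n
#>   <lgl>      <int>
#> 1 FALSE          6
#> 2 TRUE          10

# An eight-type CA3-like circuit: 500 Pyramidal cells plus 50 each of
# seven interneuron types, wired by Bernoulli draws per directed pair
net <- build_network(make_ca3_demo(), scale = 0.005, seed = 1)
glance(net)
#> # A tibble: 1 × 6
#>   n_populations n_neurons n_groups n_edges scale master_seed
#>           <int>     <int>    <int>   <int> <dbl>       <dbl>
#> 1             8       850       20   20353 0.005           1

res <- run_simulation(net, duration_ms = 300, seed = 1,
                      drive = ca3_demo_drive())
population_rates(res)
#> # A tibble: 8 × 4
#>   population       n_neurons n_spikes rate_Hz
#>   <chr>                <int>    <int>   <dbl>
#> 1 CA3 Pyramidal          500     1539    10.3
#> 2 CA3 Axo-Axonic          50     1205    80.3
#> 3 CA3 Basket              50      566    37.7
#> 4 CA3 Basket CCK+         50      941    62.7
#> 5 CA3 Bistratified        50     1120    74.7
#> 6 CA3 Ivy                 50      926    61.7
#> 7 CA3 MFA ORDEN           50     1136    75.7
#> 8 CA3 QuadD-LM            50     1148    76.5
```

The pyramidal population sits near 10 Hz and the fast-spiking interneurons
at 40–80 Hz under the packaged demo drive. `autoplot(res)` draws the spike
raster; `lfp_proxy(res) |> plot_lfp_bands()` shows the summed-|synaptic
current| LFP proxy filtered into the theta (4–12 Hz), gamma (25–100 Hz)
and ripple (150–200 Hz) bands. The demo circuit's parameters are
physiologically plausible package fixtures, not measured values — see the
vignette (`vignettes/hippocampal-network-models.Rmd`) for what they do and
do not establish.

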