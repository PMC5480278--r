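# hubsim

Simulation and analysis of cortical microcircuits that contain **assemblies
of weight-hub neurons** — excitatory cells singled out not by how many
synapses they receive but by how *strong* their summed inward synaptic
weights are, wired together at elevated density. The package is for
computational neuroscientists who want to explore how such non-random
weight structure, embedded in a network whose single-neuron parameters,
pairwise connection probabilities and lognormal weight distribution all
stay at measured cortical values, produces slow up/down-state oscillations
and layer-specific responses to stimulation.

## The model in brief

Neurons are stochastic generalized integrate-and-fire (GIF) units with
spike-triggered adaptation:

- membrane: `C dV/dt = -g_L (V - E_L) - Σ η(t - t̂_j) + I(t)`
- escape-rate spiking: `λ(t) = λ₀ exp((V - V_T)/ΔV)`, with a moving
  threshold `V_T(t) = V_T* + Σ γ(t - t̂_j)`

with exponential kernels η (pA) and γ (mV) accumulating over past spikes.
Synapses deliver exponential current pulses `w e^{-(t-Δ)/τ_syn}` after a
1 ms delay. A layer (454 excitatory + 90 inhibitory neurons for L5A;
1691 + 230 for L2/3) is wired from measured class-wise statistics; the
excitatory weights follow a lognormal whose rows are scaled by per-neuron
inward multipliers (`w_ij = ŵ_ij a_i`), the top 20.9% of neurons by inward
weight sum are labeled weight-hubs, and hub assemblies are rewired to 50%
internal connection probability while conserving the total synapse count.
Analysis tools segment up/down states, compute duration CVs and pairwise
correlations, estimate the neuron's gain function `r = g(⟨I⟩, σ_I)` for
mean-field fixed-point analysis against the network feedback line
`r = ⟨I⟩ / C_fb` with `C_fb = N p q w̄`, and identify hubs from activity
with a from-scratch two-stage K-means.

## Worked example

```r
library(hubsim)

# analytic: split 454 excitatory neurons into 95 weight-hubs and 359
# non-hubs with homogeneous weights, keeping the overall 19% probability
part <- homogeneous_partition(95, 359, p_h = 0.5, p_bar = 0.19)
part
#> homogeneous partition: N_h = 95, N_nh = 359, p_h = 0.5, p_bar = 0.19
#>   p_nh = 0.1758, f_nh = 0.7317, w* = 0.7445 mV
#>   w_nh = 0.3329 mV, w_h = 1.427 mV

psp_to_psc(0.66, 16.3, gif_parameters("exc"))   # mean weight in pA
#> [1] 7.858837

# simulate the reference three-assembly L5 network for 10 s
set.seed(1)
model <- build_network(population_layout("L5"), "heterogeneous")
sim <- run_network(model, duration = 10000, seed = 2)
sim
#> sim_result: 544 neurons, 10 s at dt = 0.1 ms (spontaneous)
#>   27036 spikes (4.97 Hz network mean); V recorded every 1 ms

segs <- segment_result(sim)
nonhub <- setdiff(which(model$classes == "exc"), model$hubs)
mean_duration_cv(segs[nonhub])$mean_cv
#> [1] 0.424688
```

The partition says a homogeneous hub population consistent with the
measured averages needs strong synapses of 1.43 mV (about 17 pA) against
0.33 mV for everyone else, at a non-hub connection probability of 18%. The
simulation produces irregular ~1 Hz up/down oscillations; weight-hubs
occupy the firing-rate tail (8.7 Hz vs. 2.8 Hz for non-hubs in this run)
and the coefficient of variation of non-hub up-state durations comes out
near 0.42 (seed-dependent). `identify_hubs(sim)`, `estimate_gain()` +
`find_fixed_points()`, `optogenetic_protocol()` and
`active_state_protocol()` cover the remaining analyses; the methods
vignette (`vignettes/hubsim-methods.Rmd`) documents the model, the
estimators and the design choices in detail.

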