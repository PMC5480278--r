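---
title: "Weight-hub assemblies in a cortical layer model: methods and design notes"
author: "hubsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weight-hub assemblies in a cortical layer model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hubsim)
```

## The model

`hubsim` simulates a single cortical layer (layer 5A or layer 2/3 of mouse
barrel cortex) as a network of stochastic generalized integrate-and-fire
(GIF) neurons. The subthreshold membrane potential obeys

$$C\frac{dV}{dt} = -g_L\,(V - E_L) \;-\; \sum_{\hat t_j < t}\eta(t-\hat t_j)
\;+\; I(t),$$

where each past spike $\hat t_j$ triggers a stereotyped adaptation current
$\eta(t) = \eta_1(t) + \eta_2(t)$ (exponentials, pA). Spikes are emitted
stochastically with the exponential escape rate

$$\lambda(t) = \lambda_0\,\exp\!\left(\frac{V(t) - V_T(t)}{\Delta V}\right),
\qquad
V_T(t) = V_T^* + \sum_{\hat t_j < t}\gamma(t-\hat t_j),$$

so the firing threshold $V_T$ itself moves after every spike (kernels
$\gamma_1, \gamma_2$, mV). Together $\eta$ and $\gamma$ produce
spike-frequency adaptation on time scales from tens of milliseconds
($\eta_1$, $\gamma_1$) to several hundred milliseconds ($\eta_2$,
$\gamma_2$); the slow threshold kernel $\gamma_2$ (time constant 640 ms for
excitatory cells) is what sets the recovery time between up-states. After a
spike the potential is reset to $V_{\text{reset}}$ and integration restarts
immediately; during the 4 ms absolute refractory period the potential
evolves but spike emission is suppressed. The packaged per-class parameter
files (`inst/extdata/parameters/`) hold the measured excitatory and
inhibitory values; `heterogenize()` applies the standard plus/minus 15
percent uniform cell-to-cell variation to every parameter.

Two conventions for "synaptic weight" coexist in the literature: the peak
post-synaptic potential (PSP, mV) and the amplitude of the exponential
post-synaptic current (PSC, pA), $\alpha(t) = w\,e^{-(t-\Delta)/\tau_{syn}}$
with a global transmission delay $\Delta$ = 1 ms. `psp_to_psc()` converts
between them through the closed-form peak response of the passive membrane;
the conversion reproduces all four measured class-mean pairs (for example
0.66 mV at $\tau_{syn}$ = 16.3 ms on an excitatory receiver is 7.9 pA)
within rounding.

## Network construction

The excitatory weight structure is built in three steps
(`build_network(mode = "heterogeneous")`):

1. **Base matrix.** Erdős–Rényi connectivity at the measured probability
   (19% in L5) with weights drawn from a lognormal
   ($\mu = 0.141$, $\sigma = 0.924$, median 0.372 mV).
2. **Inward correlations.** Every row $i$ (all synapses *received* by
   neuron $i$) is multiplied by a lognormal per-neuron factor $a_i$
   (median 1, $\sigma = 0.15$): $w_{ij} = \hat w_{ij} a_i$. The product is
   again lognormal with $\sigma = \sqrt{0.924^2 + 0.15^2} = 0.936$ and mean
   0.66 mV, matching the measured distribution, but the *sum of inward
   weights* now has a heavy right tail. The top 20.9 percent of neurons by
   inward sum (95 of 454) are labeled **weight-hubs**
   (`label_weight_hubs()`).
3. **Assembly rewiring.** Hubs are split at random into assemblies of 45,
   30 and 20 neurons and `rewire_assemblies()` raises the within-assembly
   connection probability from 19% to $p_h$ = 50% while removing an equal
   number of synapses elsewhere, so the total count and the overall
   probability are conserved exactly. The closed form
   `replaced_fraction()` says this touches
   $f_{hub}^2(p_h/\bar p - 1) = 7.1\%$ of excitatory synapses and nudges
   the mean weight from 0.659 to 0.666 mV.

New within-assembly synapses are drawn from the base lognormal and scaled
by the receiver's $a_i$, so hub inputs remain hub-like after rewiring; this
is a choice the construction leaves open, made so that step 3 does not
dilute the property that step 2 established.

The `homogeneous` mode replaces the lognormal machinery with a two-element
weight distribution derived by `homogeneous_partition()`: the non-hub
probability $p_{nh}$ solves the average-probability constraint (18% for the
reference sizes), the classification boundary $w^*$ splits the lognormal
mass into the weak fraction $f_{nh}$, and $w_{nh}, w_h$ are the conditional
means below and above the boundary (0.34 and 1.42 mV; 4.0 and 16.9 pA).
The conditional means are evaluated on the lognormal truncated at
`w_max = 5` mV, the upper end of experimentally reported EPSP amplitudes:
with an unbounded tail the strong-weight mean comes out 1.52 mV, which
corresponds to synapses outside the measured range; the truncated
evaluation reproduces the printed pair (1.42 mV / 16.9 pA) and leaves
$p_{nh}$, $w^*$ and $w_{nh}$ essentially unchanged. `w_max = Inf` restores
the literal unbounded integral.

Other connection classes (exc→inh, inh→exc, inh→inh) only have measured
means and standard deviations, so their weights are drawn from
moment-matched lognormals in the PSC convention; inhibitory senders act
with negative sign.

The `no_hub` control keeps the base matrix (no inward correlations) and
gives randomly chosen groups dense, internally strengthened connections —
an assembly with strong internal but ordinary inward weights. The
`sparse_hub` control keeps the full hub construction but densifies
assemblies only to 20%.

For layer 2/3 the excitatory probability and mean weight drop to 16.8% and
0.37 mV and, crucially, no assemblies are formed: hubs exist (inward
correlations are applied) but stay at the background density, and no
neuron receives the assembly noise channel.

## Simulation

`run_network()` drives a compiled clock-driven core: forward Euler at
`dt = 0.1` ms, exact exponential updates for kernel states and for one
synaptic-current accumulator per (neuron, $\tau_{syn}$) pair, Bernoulli
spike sampling with hazard $\lambda\,dt$ (evaluated at the start-of-step
potential, capped so the probability saturates at 1), and a ring buffer
implementing the 1 ms delay. All randomness flows through R's RNG, so a
seed makes runs bit-reproducible. Every neuron receives an independent
Poisson noise source (100 Hz; 30 pA onto assembly members, 10 pA onto
other excitatory cells, 80 pA onto inhibitory cells). Protocols:

- `optogenetic_protocol()`: a 100 pA step into a random 15 percent of all
  neurons for 300 ms, with a response summary (depolarization of
  non-stimulated excitatory cells relative to the pre-stimulus baseline,
  spike counts, and a `long_lasting` flag set when the mean depolarization
  exceeds 5 mV — a value chosen to sit between the sub-millivolt responses
  of the sparse configurations and the >10 mV responses of the dense one).
- `active_state_protocol()`: an additional barrage of 70 Poisson sources
  per neuron at 5 Hz (weights +25/+5/−25 pA onto assemblies, non-hubs and
  inhibitory cells) during a window; the barrage *adds* to the standing
  noise, which is the reading we adopt of a protocol description that does
  not state whether the background is replaced.
- `adaptation_sweep()`: re-simulates while varying the slow threshold
  kernel's time constant (`gamma2_tau`) or the fast kernel's amplitude
  (`gamma1_amp`), pooling up- and down-state durations.

Voltages are recorded at 1 ms resolution by default (step resolution via
`record_dt = dt`). Statistics discard the first second as burn-in.

## Up/down-state analysis

`detect_up_states()` smooths the voltage with a Gaussian kernel (the 20 ms
"width" is interpreted as the kernel standard deviation) and marks
contiguous epochs at least 10 mV above the neuron's quiescent potential.
The reference level deserves a note: the nominal rule references the
resting potential $E_L$, but neurons that receive the assembly noise
channel are tonically depolarized by
$0.1\,\text{kHz} \times 30\,\text{pA} \times 16.3\,\text{ms} / 3.7\,\text{nS}
= 13.2$ mV — more than the detection threshold — so a literal $E_L$ + 10 mV
rule would classify them as permanently "up" regardless of their dynamics.
The default baseline (`baseline = "auto"`) therefore estimates the
quiescent potential as the 0.1 quantile of the smoothed trace, floored at
$E_L$; for neurons without tonic drive this reduces to $E_L$ exactly, and
`baseline = "resting"` restores the literal rule. Up-states touching the
window edges are censored and dropped by default.

Downstream statistics: `duration_cv()` (population standard deviation over
mean), `mean_duration_cv()` (per-neuron CVs averaged over a neuron set,
the default estimator for the "non-hub CV" statistic; the pooled variant
is also returned), `transition_correlation()` (Pearson correlation of
binary 20 ms-binned transition indicators), `pairwise_pearson()` (10 ms
binned spike counts, or bin-averaged subthreshold voltage after excising
each spike-to-refractory-end epoch by linear interpolation), and
`rate_distribution()` (skewness plus a Shapiro–Wilk statistic on
log-rates).

## Mean-field analysis

`estimate_gain()` measures the rate-current relation
$r = g(\langle I\rangle, \sigma_I)$ of a fresh (non-adapted) GIF neuron by
direct simulation: the injected current is white noise filtered by the PSC
kernel and scaled so its stationary standard deviation is exactly
$\sigma_I$ (the filtered process is Ornstein–Uhlenbeck with correlation
time $\tau_{syn}$; the normalization uses $q_2^2 = \int\alpha^2 = \tau/2$).
Rates are counted in successive 10 ms windows: the first window is the
non-adapted gain, later windows show the adapted curves lying below it at
high currents. $\sigma_I$ = 20 pA is the package default; it is not a
measured quantity and is exposed as an argument.

`network_feedback()` forms the feedback coefficient
$C_{fb} = N\,p\,q\,\bar w$ (with $q = \int\alpha = \tau_{syn}$ per unit
amplitude) whose inverse is the slope of the self-consistency line
$r = \langle I\rangle / C_{fb}$. `find_fixed_points()` intersects that
line with the gain curve — isotonic regression plus a monotone cubic
interpolant keeps spurious intersections out — and labels one intersection
as the low point or three as low / switch (unstable) / high. Sweeping
$C_{fb}$ (`feedback_sweep()`) crosses a single boundary from the one-point
to the three-point regime, with the high-point rate non-decreasing and the
switch current non-increasing, which is the mean-field account of why
dense, strongly innervated assemblies (large $C_{fb}$) are bistable while
the diffuse non-hub population is not.

## Hub identification from activity

`kmeans_lloyd()` is a from-scratch Lloyd's algorithm: random data points as
initial centers, Euclidean assignment, mean update, convergence when the
assignment stabilizes; an emptied cluster is re-seeded from the farthest
point; 50 restarts by default, best objective kept, and the objective trace
is asserted non-increasing at every iteration. `elbow_method()` warm-starts
each $K$ from the previous best centers (making the error curve
non-increasing by construction) and selects the $K$ with maximal discrete
curvature of the error curve. `stats::kmeans` is used in the test suite as
an independent cross-check of the objective values, never as the
implementation.

`identify_hubs()` applies the two-stage procedure: stage 1 clusters all
analyzable excitatory neurons ($K = 2$) on (firing rate, CV of up-state
durations), z-scored by default because the two features are on different
scales, and names the lower-CV cluster the weight-hubs; stage 2 clusters
the identified hubs ($K = 3$, or the elbow choice) on (mean, CV) of
up-state durations. Accuracies against construction-time labels use exact
permutation matching. Neurons with fewer than two up-states are excluded
and reported.

## Problem sizes and numerical choices

The reference analyses use the full L5 network (454 + 90 neurons) for 10 s
at `dt = 0.1` ms, aggregated over five seeds; weight-matrix statistics use
20 matrix realizations; gain curves use 400-500 neuron-trials per current.
Bundled tests use the same sizes for the reference statistics and smaller
networks (about 150 neurons, a few seconds) for mechanics-level checks.
The hazard is capped at $\lambda\,dt = 10^3$ (probability saturates at 1);
`dt` must not exceed the 1 ms delay so no spike delivery can be skipped;
ties in hub labeling break toward the lowest index; rewiring alternates
additions and removals so the synapse count is conserved at every step.

## What the generator does and does not emulate

The synthetic networks reproduce the measured single-neuron parameters,
class-wise connection statistics, lognormal weight distribution, inward
weight correlations and assembly densification — the ingredients the model
declares. They do not emulate spatial geometry, distance-dependent
connectivity, synaptic short-term plasticity, conductance-based synapses
or inter-layer projections, so passing tests speak to the stated
microcircuit model, not to cortical tissue at large.

Known limitations, measured on this implementation and worth stating
plainly:

- The layer-level dynamics reproduce the qualitative phenomenology
  (irregular ~1 Hz up/down oscillations; hubs in the firing-rate tail;
  non-hub state-indicator correlations ≈ 0.8; the dense/sparse
  stimulation contrast; oscillation collapse at $p_h$ = 20%), and the
  non-hub up-state duration CV comes out at 0.32-0.42 across seed sets
  against the reported 0.42. But our assembly population bursts are
  considerably more irregular
  (duration CV ≈ 0.6) than the very regular assembly oscillations the
  model is reported to produce (CV 0.06–0.16), and detected down-to-up
  transitions are aligned across neurons only to within 50–100 ms, so
  transition-coincidence correlations in 20 ms bins stay near 0.1 rather
  than 0.58.
- Because hub up-states are less regular than non-hub ones here, the
  stage-1 rule "the lower-CV cluster is the hubs" picks the wrong cluster
  even though the two clusters separate almost perfectly; end-to-end
  stage-2 assembly accuracy is reported as measured.
- The layer 2/3 configuration, whose recurrent excitatory feedback is much
  larger than layer 5's (1691 × 0.168 × 16.3 ms × 4.4 pA against
  454 × 0.19 × 16.3 ms × 7.9 pA), shows runaway excursions quenched by
  adaptation rather than a quiescent background; its stimulation response
  still classifies as not long-lasting.
- The active-state class rates come out above the reported values
  (assemblies match within ~20% only under the replace-the-background
  reading of the barrage; the additive default is higher).

These gaps persist after the integration core was verified against exact
single-neuron and single-synapse oracles (passive decay, kernel sums,
hazard calibration, delivery timing and amplitudes to machine precision),
and none of the printed parameters was adjusted to close them; they most
likely trace to simulator details the model description leaves open.
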