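---
title: "Simulating autaptic AEIF networks: model, diagnostics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating autaptic AEIF networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aeifnet)
```

## The model

Each neuron $j = 1,\dots,N$ follows the adaptive exponential
integrate-and-fire (AEIF) equations

$$C_m \frac{dV_j}{dt} = -g_L (V_j - E_L)
  + g_L \Delta_T \, e^{(V_j - V_T)/\Delta_T} - w_j + I + I^{chem}_j(t),$$
$$\tau_w \frac{dw_j}{dt} = a_j (V_j - E_L) - w_j, \qquad
  \tau_s \frac{ds_j}{dt} = -s_j,$$

where $V_j$ is the membrane potential (mV), $w_j$ the adaptation
current (pA) and $s_j$ a dimensionless synaptic trace. When $V_j$
crosses the detection cutoff $V_{thres}$ the neuron spikes and

$$V_j \to V_r, \qquad w_j \to w_j + b_j, \qquad s_j \to s_j + 1.$$

Defaults are the cortical set used throughout: $C_m = 200$ pF,
$g_L = 12$ nS, $E_L = -70$ mV, $\Delta_T = 2$ mV, $V_T = -50$ mV,
$\tau_w = 300$ ms, $\tau_s = 2.728$ ms, $V_r = -58$ mV, $I = 270$ pA.
Excitatory (regular-spiking) neurons draw $a_j$ uniformly from
$[1.9, 2.1]$ nS and use $b_j = 70$ pA; inhibitory (fast-spiking)
neurons have $a_j = b_j = 0$. Because $I$ sits just above the
excitatory rheobase ($\approx 256$ pA at $a = 2$ nS), uncoupled
excitatory cells fire tonically but slowly (about 1.5–2 Hz), while
inhibitory cells, lacking adaptation, fire an order of magnitude
faster — the rate gap the mixed network builds on.

Synaptic coupling is conductance-based and delayed. With binary
adjacency matrices $M^{exc}$, $M^{inh}$ split by presynaptic type,

$$I^{chem}_j = \underbrace{(V^{exc}_{REV} - V_j)
  \sum_k M^{exc}_{jk}\, g_{kj}\, s_k(t - d_{exc})}_{I^{exc}_j}
 + \underbrace{(V^{inh}_{REV} - V_j)
  \sum_k M^{inh}_{jk}\, g_{kj}\, s_k(t - d_{inh})}_{I^{inh}_j},$$

with reversal potentials $0$ and $-80$ mV and presynaptic-type delays
$d_{exc} = 1.5$ ms, $d_{inh} = 0.8$ ms. Autapses are ordinary
self-edges with the same delayed dynamics.

### Trace normalization

The reset rule as usually written increments a single per-neuron
conductance by a class-dependent amount $g_s$, but one shared scalar
cannot encode different increments for a neuron's different outgoing
edge classes (an excitatory neuron may simultaneously project `ee`,
`ei` and autaptic edges with three distinct conductances). We
therefore keep one *normalized* trace $s_j$ per neuron, incremented by
exactly 1 per spike, and multiply by the class conductance $g_{kj}$
per edge inside the current sum. Every class conductance ($g_e$,
$g_{ei}$, $g_i$, $g_{ie}$, $g_e^{aut}$, $g_i^{aut}$) then retains its
independent meaning, and the two formulations coincide whenever a
neuron's outgoing edges share one class.

### The detection cutoff

Only the exponential threshold $V_T = -50$ mV is part of the standard
parameter set; the detection cutoff $V_{thres}$ is a convention. We
default to $V_{thres} = V_T + 5\Delta_T = -40$ mV and expose it as a
config field. Detecting at $V_T$ itself would cut off the exponential
upswing entirely; once the upswing is under way it traverses the last
millivolts in well under a step, so the exact cutoff shifts spike
times by $O(dt)$ only. The exponential argument is capped at $+50$
purely to avoid overflow in the overshoot between crossing and reset;
the cap is unreachable for $V \le V_{thres}$. $\Delta_T \to 0$ (the
hard-threshold limit) is not supported.

## Network construction

The first $\mathrm{round}(P_{exc} N)$ indices are excitatory, the rest
inhibitory ($P_{exc} = 0.8$ by default). The four ordinary classes are
sampled as independent Bernoulli edges over ordered pairs (excluding
self-pairs), with $p_e = 0.05$, $p_i = 0.2$, $p_{ei} = p_{ie} = 0.05$:
the reference definitions are count ratios, and i.i.d. sampling is the
simplest null model matching them in expectation. Autapses are
different: the fraction 0.25 reads as a fixed share of each
population, so exactly $\mathrm{round}(p^{aut} N_{pop})$ neurons are
drawn without replacement and given one self-edge each. Multi-edges
are disallowed. All randomness derives from a master seed through
independent named streams (graph, autapse choice, initial conditions),
so each ingredient can be varied in isolation.

## Integration

The coupled system is integrated with the classical fourth-order
Runge–Kutta scheme at $dt = 0.01$ ms. Delays are integer multiples of
$dt$ (150 and 80 steps at defaults) served from a per-neuron ring
buffer of past traces; history before $t = 0$ is empty. Three
numerical choices deserve note:

* **Delayed values inside RK4 substages.** $s_k(t - d)$ exists only on
  the $dt$ grid, so the per-target delayed sums are frozen at their
  value for the step's start time across all four substages, while
  the driving force $(V_{REV} - V_j)$ does use the substage voltage.
  The freezing error is $O(dt)$ on a quantity that varies on the
  $\tau_s = 2.728$ ms scale — three orders of magnitude slower than
  the step.
* **Spike timing.** Crossings are detected after a full step and the
  spike is stamped at the step-end time, with no within-step
  interpolation; timing error is bounded by $dt$. All neurons are
  then reset simultaneously, and an increment stamped at $t + dt$
  first reaches its targets at $t + dt + d$ — strictly causal.
* **Recording.** The mean network current $I^{chem}(t)$ is sampled
  every 0.1 ms (configurable), 100× coarser than the integration
  grid, which bounds output size without visibly biasing its
  time average.

Initial conditions follow the reference protocol:
$V_j \sim U[-70, -50]$ mV, $w_j \sim U[0, 300]$ pA (excitatory) or
$U[0, 80]$ pA (inhibitory), $s_j = 0$. Non-finite states abort with
the neuron index and time. The compiled integrator is mirrored by a
plain-R step (`aeif_rk4_step`) and the test suite holds the two
together, as well as against a 10×-refined-step trajectory.

## Diagnostics

*Synchronization.* The phase of neuron $j$ grows linearly by $2\pi$
between consecutive spikes,
$\psi_j(t) = 2\pi m + 2\pi (t - t_{j,m}) / (t_{j,m+1} - t_{j,m})$, and
the Kuramoto order parameter is
$R(t) = |N'^{-1} \sum_j e^{i\psi_j(t)}|$. Phases are defined only
between recorded spikes, so $m$ restarts at the first spike inside the
analysis window and neurons whose in-window span does not cover a grid
point are excluded at that point (never extrapolated); $N'$ counts the
included neurons. $R(t)$ is sampled every 1 ms (the sampling density
is a convention; the value is insensitive to it well below the firing
period) and time-averaged with the trapezoidal rule over
$[t_{ini}, t_{fin}]$ to give $\bar R$, with subgroup variants
$\bar R_{aut}$, $\bar R_{non}$ over the autaptic and non-autaptic
neurons.

*Variability.* $CV_j = \sigma_{ISI_j} / \overline{ISI}_j$ per neuron,
averaged into $\bar{CV}$; ensembles with $\bar{CV} \ge 0.5$ are
labelled burst-firing, below spike-firing (boundary inclusive on the
burst side). The standard deviation is the population form (divisor
$n$) by default — determinate for the few ISIs an 8–20 s window
yields at ~2 Hz — with the sample form available as a switch. Neurons
with fewer than two ISIs in the window are excluded and counted.

*Rates and currents.* $\bar F$ (and the autaptic / non-autaptic /
excitatory / inhibitory variants) is the subset spike count divided by
subset size and window length, in Hz. $\bar I_s$ is the trapezoidal
time average of the recorded mean current.

## Synthetic trains

`make_synthetic_trains()` generates the structures the diagnostics are
meant to detect: identical periodic ensembles ($\bar R = 1$,
$\bar{CV} = 0$), anti-phase pairs ($R = 0$ mid-interval), jittered
periodic trains (jitter applied per spike, not cumulatively, so the
underlying phase structure survives — exactly what the order parameter
should report; jitter is truncated at 49% of the period to keep ISIs
positive and is rejected beyond half a period), and homogeneous
Poisson trains ($CV \approx 1$). These fixtures share none of the
simulator's code path, which is what makes them useful as oracles; by
the same token they emulate only the *phase* structure of network
activity, not conductance interactions, delays or adaptation, so
passing diagnostics on fixtures says nothing about simulator
correctness — the integrator has its own oracle tests.

## Experiments at desk scale

The drivers (`sweep_2d`, `line_scan`, `raster_export`, and the
`analysis/` scripts) default to N = 200 neurons, 8 s runs analysed
over [4, 8] s, coarse grids and 3–5 seeds; the reference conditions
(N = 1000, 20 s, [10, 20] s, fine grids) are fully supported by the
same configuration objects. The qualitative structure — the autaptic
synchronization transition at weak excitatory coupling, the
rate-ordering of autaptic vs non-autaptic hosts under excitatory vs
inhibitory self-feedback, the suppression of full synchrony by minimal
cross-population interaction — is reproducible at the reduced scale,
though absolute recurrent drive per neuron is ~5× smaller (in-degree
scales with N at fixed p), so color-map *values* are not comparable
pixel-by-pixel with full-scale runs. Within a sweep, one topology per
seed is reused across grid points with re-mapped edge weights
(switchable), so conductance effects are not confounded with graph
resampling; whether the reference study resampled per point is not
stated, and the switch records our choice. Marked conductance points
from the weak-coupling plane ship as `preset_point()` presets:
circle (0.05, 10), triangle (0.05, 31), square (0.1, 15),
hexagon (0.1, 22) nS.

```{r, eval = FALSE}
base <- config_excitatory_only(g_e = 0.3)
sc <- line_scan(base, axis = list(param = "g_e_aut", values = c(0, 20)),
                metrics = c("F_mean_non", "F_mean_aut", "F_mean"),
                seeds = 1:5)
aggregate(value ~ x + metric, sc, mean)
```

## Known limitations

* Spike times carry an $O(dt)$ quantization; diagnostics that compare
  phases across neurons are insensitive to this at $dt = 0.01$ ms.
* The model is deterministic given the seed; there are no noise
  currents, plasticity, or structured (small-world/scale-free)
  topologies.
* Single-population networks leave the cross-population probabilities
  undefined; configured positive values there are ignored with a
  warning rather than an error.
* Neurons silent over the analysis window are excluded from phase and
  CV statistics (and counted); at extreme inhibitory conductances this
  can shrink the effective ensemble.
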