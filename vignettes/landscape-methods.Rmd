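---
title: "A landscape view of multi-channel neural activity: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A landscape view of multi-channel neural activity: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, algorithms and numerical choices behind
`neurolandscape`. The package treats a multi-channel recording as a cloud of
points in state space — one point per time bin — and extracts the local
maxima of its density ("the landscape"). The centroids of the resulting
clusters then serve three purposes: a compact description of where the
system lives, a parsimonious basis for inverse-Ising coupling inference,
and an alphabet that turns the multidimensional dynamics into a symbolic
sequence amenable to complexity analysis.

## The modified mean-shift on the hypercube

The data are rows $x_1,\dots,x_M \in \{-1,+1\}^N$. One update picks a
random index $i$ and replaces $x_i$ by the flat-kernel neighborhood mean

$$x_i \leftarrow \mathrm{sign}\!\left(\frac{\sum_{j \ne i} x_j\,
  \mathbf{1}[d(x_i, x_j) \le r]}{\sum_{j \ne i} \mathbf{1}[d(x_i, x_j)
  \le r]}\right),$$

with $d$ the Hamming distance and the sign taken per coordinate; a
coordinate whose neighborhood mean is exactly zero keeps its value, and a
point with no neighbors inside the radius does not move. All points are
updated this way in random sequential order (the "blurring" regime: the
density is carried by the moving points themselves), so distances and radii
always refer to the current positions.

The radius is chosen adaptively at every update. For the selected point we
scan the standard deviation $\sigma(n)$ of the distances to its $n$ nearest
neighbors and take $n_{\min} = \mathrm{argmin}_{n \ge n_0}\, \sigma(n)$
(ties resolved to the smallest $n$); the radius is the distance to the
$n_{\min}$-th neighbor. Small $\sigma(n)$ indicates a shell of neighbors at
a coherent scale — a natural neighborhood — while a hard-coded radius would
either fragment noisy data or bridge distinct modes.

Iteration stops when the fraction of position-changing updates among the
last $M$ drops below `convergence_fraction`. Clusters are the groups of
initial points absorbed by the same final point; the group size is the
centroid's *mass*. Two post-passes follow:

* **Refinement.** The centroids are themselves mean-shifted with a fixed
  Hamming radius (2 by default), each centroid weighted by its mass. A
  centroid standing for $m$ samples contributes $m - 1$ to its own
  neighborhood (the moving sample is excluded, its siblings are not), so an
  isolated pair with masses 90 and 10 collapses onto the mass-weighted
  majority vector rather than onto whichever partner was updated first.
* **Mass filtering.** Clusters holding less than `mass_cutoff` (1% by
  default) of the samples are discarded as finite-sample density bumps;
  their samples become unassigned and can later be relabeled by nearest
  centroid.

Defaults: `n0 = 10`, `convergence_fraction = 0.01`, `refine_radius = 2`,
`mass_cutoff = 0.01`, `max_iterations = 200 M`. A continuous-space variant
(`run_meanshift_continuous()`) applies the same scheme with Euclidean
distances, real-valued means and a minimal-displacement threshold
($10^{-6}$ in data units) in the convergence rule.

Mirror clusters $(c, -c)$ are kept distinct by the clustering and merged
only where the analysis requires it (`mirror_dedup()`), since a
Hopfield-like coupling term is blind to the sign of its centroid.

## The Hopfield reference system

The binary reference network stores $P$ random patterns
$\xi^\mu \in \{-1,+1\}^N$ through the Hebbian matrix
$J_{ij} = \sum_\mu \xi_i^\mu \xi_j^\mu$ (zero diagonal) and is sampled from
the Gibbs distribution $p(\sigma) \propto e^{-\beta H[\sigma]}$ of the
pair-sum energy

$$H[\sigma] = -\frac{1}{N} \sum_{i<j} \sigma_i J_{ij} \sigma_j.$$

The pair-sum convention (each pair counted once) is used consistently by
the sampler, the descent and the inference; its virtue is that the weights
$\omega$ recovered by reduced inference from data generated at inverse
temperature $\beta$ come out on the scale of $\beta$ itself, so they read
directly as "how strongly does the data support this centroid's coupling
term". With $N = 50$, $P = 4$ this model is far from its retrieval phase:
at $\beta = 1.3$ the sampled states keep overlaps of magnitude about one
half, at $\beta = 0.83$ the overlap distribution is broad and roughly
centered at zero — a deliberately hard, glassy test bed for clustering.

Sampling is Glauber (heat-bath) single-spin-flip dynamics at uniformly
random sites, one sweep being $N$ attempted flips; one state is recorded
per sweep after a 1000-sweep burn-in (the thermalization length is not
critical at these temperatures; the integrated autocorrelation time of
pattern overlaps at $\beta = 0.83$ is on the order of 15 sweeps).
`zero_temperature_descent()` is the $\beta \to \infty$ limit: spins are
swept in fresh random order and flipped only when the energy strictly
decreases. Zero-energy flips are rejected, which guarantees termination at
a strict local minimum. `basin_check()` uses it to ask whether clusters
behave like attractor basins: a configuration counts as a success when its
descent endpoint overlaps its assigned centroid more than the start did
(ties, including starts already at a minimum, count as failures).

## Coupling inference by Minimum Probability Flow

Given binary data, the inference model is the Ising energy above with
couplings to be estimated — either the full symmetric matrix (upper
triangle as parameters) or the centroid-reduced form

$$J_{ij} = \sum_{\mu=1}^{C} \omega_\mu\, c_i^\mu c_j^\mu,$$

whose parameter count is the number of mirror-merged centroids rather than
$N(N-1)/2$. MPF scores parameters by the initial outflow of probability
from the empirical distribution under single-spin-flip dynamics with rates
$\Gamma_{\alpha\to\beta} = \exp[(H[\alpha]-H[\beta])/2]$ (which satisfy
detailed balance for the Gibbs distribution): the objective is the mean,
over data states, of the summed rates toward all $N$ single-flip
neighbors. By default all flip neighbors are summed; the strict variant
excluding neighbors that are themselves data states is available
(`exclude_data = TRUE`) and makes a negligible difference when the data
occupy a vanishing fraction of the $2^N$ cube. No external-field terms are
used.

Numerics: data states are deduplicated with multiplicity weights (an exact
reformulation that dominates the cost profile), the objective and its
closed-form gradient are evaluated as dense matrix products, and L-BFGS
runs from zero parameters until the projected gradient is below $10^{-6}$
or 500 iterations. Exponents above 700 abort with advice to rescale, since
the objective is unbounded for pathological parameters.

**Weight significance.** The sampling variability of the reduced weights is
estimated by a circular block bootstrap over the time series (default 200
resamples of blocks of 100 bins, each refit warm-started at the point
estimate; the block length is two orders of magnitude above the measured
mixing time of the reference chain). A weight is flagged significant when
$|\omega_\mu|$ exceeds the Bonferroni-corrected normal critical value times
its bootstrap standard error. The family-wise correction matters here: the
$C$ weights are simultaneous hypotheses *and* the centroid basis was
selected from the same data, which biases the small weights a few standard
errors away from zero; the per-weight 95% rule would flag most of them,
while the corrected rule isolates the weights carrying real structure.

## The multi-modular spiking network

Each of `n_modules` modules holds 32 excitatory and 16 inhibitory leaky
integrate-and-fire neurons with spike-frequency adaptation:

$$\dot V_i = -V_i/\tau + \textstyle\sum_j J_{ij} \sum_k
  \delta(t - t_k^j - d_{ij}) - g_{SFA}\, c_i + I_i, \qquad
  \dot c_i = -c_i/\tau_{SFA} + \textstyle\sum_k \delta(t - t_k^i),$$

with threshold 20 mV, reset 15 mV held for the refractory period, membrane
constants 20/10 ms (E/I) and refractory periods 2/1 ms. The calcium-like
variable $c_i$ integrates the neuron's own spikes (unit increment) and
feeds back as self-inhibition; $g_{SFA} = 25/\tau_{SFA}$ keeps the product
$\tau_{SFA}\, g_{SFA}$ — the adaptation strength — constant across
timescale sweeps. External drive is a merged Poisson train per neuron
(aggregate rate `nu_ext`, jumps of 0.320/0.111 mV for E/I); an optional
deterministic current `i_dc` supports closed-form rate checks. Synaptic
weights are Gaussian around their class mean with 25% relative standard
deviation (the multiplier is redrawn until positive, so weights keep the
sign of their mean), and delays are exponential with scale
$d_{\max} - d_{\min}$, shifted by $d_{\min} = 0.1$ ms and truncated at the
class maximum by rejection. Inter-module synapses connect excitatory
neurons across modules with probability 0.5, delays up to 50 ms, and mean
efficacies of either sign.

Integration is clock-driven on a 0.1 ms grid (steps above 0.5 ms are
refused): exponential decay between events, delayed deltas accumulated in
a circular future buffer, delays rounded to the grid. Inputs arriving
during the refractory clamp are discarded. A deterministically driven
neuron reproduces the closed-form rate
$1/\big(t_{ref} + \tau \ln\frac{\mu\tau - H}{\mu\tau - V_{th}}\big)$ to
within 2% at both 0.1 and 0.05 ms steps.

**Working point.** The intra-module operating point was calibrated for this
integrator so that an isolated module is genuinely bistable around the
binarization threshold $\theta_{bin} = 40$ Hz: recurrent excitatory mean
efficacy `j_ee = 2` mV and external rate `nu_ext = 2.5` kHz. The
calibration constraint is easy to state: the Down state can only exist if
the external drive alone leaves an excitatory neuron subthreshold
($\nu J_{ext} \tau < V_{th}$ plus a fluctuation margin), because inhibition
is silent when the module is silent; the Up state then needs recurrent
excitation strong enough to sustain itself against inhibition and
adaptation. At this working point the module-rate histogram is cleanly
bimodal (valley-to-peak ratio near zero at $\theta_{bin}$, Up near 150 Hz,
Down near 0 Hz) and the Up/Down residence times are paced by adaptation,
scaling from about 0.2 s at $\tau_{SFA} = 62.5$ ms to about 7.7 s at 4 s.

Module activity is summarized as the excitatory population rate in a 20 ms
window, sampled every 20 ms (non-overlapping by default), and binarized at
$\theta_{bin}$ into Up/Down words — the binary series that the clustering
and inference machinery consumes.

## Pseudo-Boltzmann learning of inter-module couplings

To give the modular network a prescribed spatial structure, the package
matches its binarized statistics — magnetizations $m_p$ and connected
correlations $c_{pq}$ — to targets (typically measured from a reference
binary network). Lacking an explicit likelihood for the spiking system,
the update uses only the assumed monotone relation between a coupling and
its correlation: each iteration simulates the network, discards the first
$5\tau_{SFA}$, measures, and moves every parameter *against the sign of
its error* with a per-parameter Rprop step:

* same error sign as last iteration: step $\times\ \eta^+ = 1.2$, capped at
  $\Delta_{\max}$ (0.05 mV for couplings, 0.5 kHz for rates);
* opposite sign: step $\times\ \eta^- = 0.5$, floored at $\Delta_{\min}$
  ($10^{-4}$ mV, $10^{-3}$ kHz);
* zero product: step unchanged. Initial steps are 0.01 mV and 0.1 kHz.

Self-couplings are never updated (intra-module synapses are fixed by the
architecture), couplings are not symmetrized, and the quenched Gaussian
multipliers of the inter-module synapses are frozen at network creation so
that learning moves mean efficacies without redrawing the disorder.
Initial inter-module couplings are small Gaussians
($\mathrm{sd} = 10^{-3} j_{ee}$); external rates start at the architecture
default. The per-iteration duration defaults to 100 s of model time; the
package's self-consistency experiment (four modules learning their own
generator's statistics, 40 iterations of 25 s) recovers the target
correlations with $R^2 > 0.99$. A full 64-module run against Hopfield
targets uses exactly the same code path with `n_modules = 64` and is a
multi-hour computation.

## Symbolic dynamics and complexity

`label_series()` replaces each time bin by its centroid index (mass-
filtered samples and new data go to the nearest centroid in Hamming
distance, ties to the larger mass). Runs of identical labels are collapsed
(`remove_self_transitions()`) before any complexity measurement, since
residence runs only add trivial compressibility. From the label sequence
the package estimates the maximum-likelihood transition matrix, generates
memoryless Markov surrogates with the same transition probabilities (first
symbol from the stationary distribution), and computes the Lempel–Ziv 1976
complexity: $S_{LZ}$ is the phrase count of the exhaustive-history parsing
— chosen over compressed bit-length because it is the standard LZ76
measure and makes the normalized

$$C_{LZ} = S_{LZ}\, \frac{\log |S|}{|S| \log |A|}$$

approach 1 for long random sequences. The approach is slow (like
$1/\log|S|$): at $|S| = 10^5$ over a 13-letter alphabet, i.i.d. uniform
sequences score $C_{LZ} \approx 0.94$, and the tests freeze that
oracle-computed value rather than the asymptote. Logarithms are natural
(the ratio makes the base irrelevant). The relative complexity index

$$R = \frac{\bar C_{LZ}^{Markov} - C_{LZ}^{sample}}
           {\bar C_{LZ}^{Markov}}$$

(averaged over 10 surrogates by default) is zero in expectation for a
truly first-order sample and positive when the sequence carries memory the
transition matrix cannot express.

Triplet statistics compare observed overlapping-triplet probabilities with
the first-order prediction $\pi(a) P(a,b) P(b,c)$ ($\pi$ the empirical
unigram distribution) and with a surrogate sequence of the same length;
the Kullback–Leibler distance is taken over the observed support with
add-one smoothing on the surrogate side only. A same-length true-Markov
null chain calibrates the finite-sample spread. Centroid catalogs from
several runs are merged by complete-linkage agglomeration under Hamming
distance (`merge_fuzzy_centroids()`), and reference centroids count as
*recovered* when some run centroid exceeds the 95th percentile of the
run's own inter-centroid overlaps (`centroid_recovery()`).

**Adaptation-timescale sweep.** `tau_sfa_sweep()` packages the experiment
of simulating the same quenched modular network at several $\tau_{SFA}$
(durations growing with $\tau_{SFA}$ so each run collects a comparable
number of transitions), clustering each run and measuring $R$. In the
package's desk-scale configuration (12 modules, 3 stored patterns, planted
inter-module couplings) the centroid alphabet is small (5–8 labels), and
one first-order-adjacent memory effect — adaptation suppresses immediate
returns to the state just left — already makes the sample substantially
more compressible than its surrogates at *every* timescale, saturating
$R$ around 0.3–0.5. The additional, longer-range memory that grows with
$\tau_{SFA}$ is not resolved above that baseline at this network size, so
the monotone increase of $R$ with $\tau_{SFA}$ seen in large (64-module,
per-timescale-learned) systems should not be expected from the scaled-down
experiment; what is robust at desk scale is that the adapting network's
$R$ far exceeds that of a Markovian reference (the Hopfield centroid
sequence).

## Synthetic data generators

The fixture generators are first-class, tested code: planted noisy-pattern
clouds (per-bit flip noise), exact Gibbs samples of enumerable Ising
models ($N \le 16$), first-order Markov label chains, and a second-order
chain whose next symbol depends on the two previous ones with tunable
memory strength (never self-transitioning, so it is comparable to
collapsed label sequences). They emulate the statistical structure the
algorithms target — multimodal state clouds, detailed-balance dynamics,
controlled memory — but none of the non-idealities of real recordings:
non-stationarity, heterogeneous and drifting units, missing channels, or
binarization artifacts from low firing rates. Green tests on these
generators therefore validate the machinery, not the biology.

## Numerical and design notes

* Ties: the zero-mean coordinate rule and the strict-descent tie rejection
  are exact integer comparisons; the adaptive-radius argmin uses a
  $10^{-12}$ tolerance and prefers the smallest $n$.
* Degenerate inputs: empty pattern sets, all-clusters-filtered results,
  reducible transition matrices and dead-end states (restarted from the
  stationary distribution with a warning) are handled explicitly.
* Reproducibility: every stochastic routine takes a seed and is
  deterministic given it; the pipeline writes a provenance JSON per stage.
* Problem sizes in the test suite — 20000-sweep Hopfield runs, a 4-module
  learning loop, a 12-module timescale sweep with durations from 60 s to
  1200 s of model time, $10^5$-symbol complexity checks — were chosen as
  the smallest sizes at which each scientific effect is stably measurable.
* Known limitations: binary mean-shift supports up to 256 channels (bit
  packing); the spiking integrator is clock-driven, so delays are rounded
  to the grid; the full-matrix MPF fit is quadratic in $N$ and intended
  for $N$ up to a few hundred; the Up/Down working point is a property of
  this integrator and must be recalibrated if the single-neuron model
  changes.
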