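---
title: "Simulating population dynamics on structural connectomes with connectosim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating population dynamics on structural connectomes with connectosim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connectosim)
```

## The model

connectosim simulates spontaneous ("resting-state") cortical activity as a
network of neuronal populations coupled through a weighted structural
connectome. Each of the $N$ nodes is a patch of cortex (a region of
interest, ROI) whose state is the average synaptic gating variable
$S_i \in [0, 1]$ — the fraction of open synaptic channels. The dynamics is
the reduced ("dynamical mean-field") limit of a spiking attractor network
of integrate-and-fire neurons:

$$
\frac{dS_i}{dt} = -\frac{S_i}{\tau_S} + (1 - S_i)\,\gamma\,H(x_i)
  + \sigma\,v_i(t),
$$

$$
H(x_i) = \frac{a x_i - b}{1 - \exp(-d\,(a x_i - b))}, \qquad
x_i = w J_N S_i + G J_N \sum_j C_{ij} S_j + I_0 + \mathrm{applied}_i(t),
$$

where $H$ converts the input current $x_i$ (nA) into a population firing
rate (Hz), $C$ is the symmetric matrix of normalized fiber-tract counts,
$v_i$ is uncorrelated Gaussian white noise, and $\mathrm{applied}_i(t)$ is
any injected current (the virtual-stimulation channel). The default
parameters are the standard published values
(`meanfield_params()`): $w = 0.9$, $a = 270$ Hz/nA, $b = 108$ Hz,
$d = 0.154$ s, $\gamma = 0.641$, $\tau_S = 0.1$ s, $J_N = 0.2609$ nA,
$I_0 = 0.3$ nA. Two simpler discrete-time models are also provided — a
rectified linear-threshold map and a leaky logistic ("sigmoid") map — as
fast qualitative alternatives; the mean-field model is the scientifically
interesting one and everything below refers to it.

Two conventions in the printed form of this model family deserve comment,
since we had to decide them:

* **Coupling sign.** One printed variant of the input equation carries a
  minus sign on the network term, which would make all long-range coupling
  inhibitory. We implement the excitatory sign (`+`) as the default: the
  phenomena the model is used for — a high-firing attractor sustained by
  coupling, lesions *reducing* network firing — require net-excitatory
  long-range interactions, consistent with the original reduction where
  long-range projections are glutamatergic. The literal inhibitory reading
  remains available via `coupling_sign = -1` in `simulate_meanfield()` and
  `synaptic_input()`.
* **Units of $\gamma$ and $a$.** Parameter tables in this family list
  $\gamma$ with units of seconds and $a$ as "n/C"; dimensional consistency
  of the gating equation requires $\gamma$ dimensionless when $\tau_S$ is
  in seconds, and $a$ in Hz/nA. We adopt those readings.

## Numerical integration

`simulate_meanfield()` integrates the system with an Euler–Maruyama
scheme in compiled code:

$$
S_i \leftarrow S_i + \Delta t \left[-\frac{S_i}{\tau_S}
  + (1 - S_i)\gamma H(x_i)\right] + \sigma \sqrt{\Delta t}\, z_i,
\quad z_i \sim \mathcal{N}(0, 1).
$$

Defaults follow the protocol the model family uses at this scale:
$\Delta t = 0.1$ ms, 10 s of simulated time, sampling every 1 ms — exactly
10,000 samples per node per run. Design choices:

* **Noise discretization.** The published description says only
  "uncorrelated Gaussian noise"; we use the standard SDE convention
  ($\sqrt{\Delta t}$ scaling) by default and expose plain per-step
  additive noise as `sim_config(noise_scaling = "per_step")`, since the
  original implementation's convention is not recoverable from its
  description.
* **Clamping.** $S$ is a channel-open fraction, so after every step it is
  clamped (not reflected) into $[0, 1]$; with large $\sigma$ the noise
  would otherwise push it out of its physical range.
* **Initial state.** $S_i(0) = 0.001$ everywhere — the near-silent network,
  matching the low-firing starting point of the resting-state protocol.
* **Reported rate.** The "firing rate" time series is $H(x_i(t))$
  evaluated at sample times, the model's population rate (in Hz), with any
  active applied current included in $x_i$.
* **Reproducibility.** Each run draws its noise from a single
  Mersenne-Twister stream seeded from `sim_config(seed = )`, consumed in
  fixed node-major order; the same seed and inputs give bit-identical
  trajectories on a given platform. The transfer function's removable
  singularity at $a x = b$ is evaluated by a series expansion in a
  $|d(ax-b)| < 10^{-8}$ neighbourhood, making $H$ smooth and total.
* **Order check.** With $\sigma = 0$ the scheme is plain Euler; halving
  $\Delta t$ approximately halves the terminal-state error (verified in
  the test suite).

## Calibrating the global coupling

The one free parameter is the global coupling $G$. The operating point of
the resting-state model is the *edge of the bifurcation*: the largest
coupling at which the low-firing state is still (barely) stable. On the
original 998-ROI diffusion-imaging matrix this calibration gives
$G = 2.3$. `calibrate_G()` recovers the edge for any connectome by
bisection on noise-free runs: a probe run (4 s by default) counts as
*destabilized* when its node-mean rate over the final fifth exceeds
`r_low = 20` Hz — a threshold chosen between the low branch (< 10 Hz) and
the high branch (> 150 Hz), since the published description fixes the
operating point but not a numerical criterion. The returned value is the
unstable end of the final bisection bracket (to tolerance `tol`), minus an
optional `margin`.

On the package's default synthetic connectome the edge sits near
$G \approx 0.54$ rather than 2.3. This is expected: the synthetic
generator normalizes weights into $(0, 1]$ with a heavy-tailed
distribution whose row sums are larger than those of the real
fiber-density matrix, and $G$ simply rescales them. All downstream
experiments therefore use the *calibrated* $G$ of whatever connectome they
run on, which is the scientifically meaningful operating point.

## The synthetic connectome

The real 998-ROI connectome (averaged diffusion-spectrum imaging from five
subjects) is distributed by its original authors and is not shipped here.
So that every experiment is runnable and testable, `synthetic_connectome()`
generates networks with the same shape:

* 998 nodes partitioned by the built-in atlas into 33 named regions per
  hemisphere (66 regions; right hemisphere nodes 1–500, left 501–998);
* symmetric, zero-diagonal, non-negative weights, max-normalized into
  $(0, 1]$, drawn log-normally (`meanlog = 0`, `sdlog = 1`) — fiber-count
  distributions are heavy-tailed;
* modular structure through block densities: within-region pair
  probability 0.30, and a between-region probability solved analytically
  (≈ 0.028) so the expected number of unordered connected pairs equals the
  real dataset's ≈ 17,000;
* coordinates clustered around fixed per-region centroids (5 mm jitter),
  hemispheres mirrored in $x$.

What the generator deliberately does **not** reproduce: the real degree
sequence (hub structure), distance-dependent connection probability, and
any spatial embedding statistics. Consequences for what passing tests
show, and the one test that stays red, are discussed below.

## Perturbation protocols

* **Focal lesion** (stroke-like): all nodes of named regions are
  disconnected — rows and columns of the weight matrix zeroed, nodes kept
  in place so indexing is stable. The canonical protocol severs rCUN +
  rLOCC + rPCUN on the right hemisphere, 52 ROIs.
* **Diffuse lesion** (multiple-sclerosis-like): 50 nodes sampled uniformly
  without replacement, seeded for reproducibility. Sampling is not
  stratified by region — the protocol specifies only "randomly scattered".
* **Virtual TMS**: a constant current injected into a node set over a time
  window, entering the input additively. The inhibitory amplitude default
  is −0.1 nA — the original protocol's current is not published, and this
  value produces efferent rate changes of order 10–20 Hz on calibrated
  networks, the magnitude the protocol reports.

Lesioned nodes keep receiving the baseline current $I_0$, so with
$\sigma = 0$ each follows the uncoupled single-node solution exactly (a
test oracle).

## Analyses

`mean_firing()` averages each node's rate over a window — by convention
the final 2 s of a run, where the dynamics has settled into its attractor;
windows are inclusive of both endpoints on the sample grid. The summary's
`total` sums per-node means over non-lesioned nodes. `delta_fr()` forms
per-node differences between conditions (healthy vs lesioned, diffuse vs
focal, post-TMS vs during-TMS). `return_to_baseline()` reports the latency
after a perturbation ends until the node-averaged rate stays within
`k_sd = 2` baseline standard deviations of the baseline mean for
`hold_ms = 20` consecutive milliseconds; baseline statistics come from a
matched unperturbed run with the same seed, which removes the noise-floor
bias from the comparison. The `k_sd`/`hold_ms` rule is this package's
declared convention — the published "returns in about 40 ± 10 ms" does not
state its detection criterion — and the defaults were fixed from the
analytic behaviour of exponential-relaxation test cases, in which the
detected latency matches the closed-form band crossing to within one
sample.

`shortest_path()` traces weighted shortest paths under inverse-weight edge
lengths ($\ell_{ij} = 1/w_{ij}$, the standard convention for fiber-density
matrices; $-\log(w/w_{\max})$ available), with ties broken toward the
lexicographically smallest node sequence so results are reproducible.
Distances come from igraph's Dijkstra; the deterministic reconstruction
and its exhaustive-enumeration test oracle are independent code paths.

## What the full-scale experiments show

The acceptance suite runs the four protocols at study scale (998 nodes,
10 s runs, 5 noise seeds, calibrated $G$). Three headline observations on
the synthetic connectome:

1. **Noise suppresses the attractor.** Total mean firing over the final
   2 s decreases monotonically across $\sigma \in \{0.01, 0.05, 0.07,
   0.1\}$. At the edge of the bifurcation the high-firing attractor's
   drift is concave in $S$ (the $(1-S)\gamma H$ term saturates), so
   symmetric noise lowers the mean — the qualitative effect the model
   family reports, though far milder here than on the real connectome,
   where the high state itself is more fragile.
2. **Lesions reduce firing.** Healthy-minus-focal total firing is positive
   at every noise level: severing the 52-node occipito-parietal set
   removes recurrent excitation and the survivors settle lower.
3. **Clustered vs scattered damage.** On the *real* connectome the
   clustered (focal) lesion is reported to depress activity more than a
   scattered (diffuse) lesion of matched size. On the synthetic connectome
   this comparison comes out the other way, and structurally so: with
   uniform between-region connectivity, a whole-region focal lesion spends
   a sizable share of its edges on pairs *inside* the lesioned set, so 52
   clustered nodes sever fewer survivor-facing connections (≈ 9.4% of pairs)
   than 50 scattered nodes do (≈ 9.6–9.8%, depending on the sampled set), and total firing tracks removed
   coupling almost linearly. The real effect rides on exactly the features
   the generator excludes by design — hub-like focal regions (there, the
   focal lesion removes 6.64% of connections versus the diffuse 4.91%) and
   spatially clustered inter-regional wiring. The corresponding acceptance
   test is kept faithful to the original claim and is expected to fail on
   synthetic data; it documents a real limitation of block-uniform
   surrogates rather than a defect of the dynamics.

The same reasoning delimits all synthetic-data conclusions: passing tests
demonstrate the *mechanics* (integration, calibration, protocols,
analyses) and the coupling-driven phenomenology, not agreement with the
published numbers, which require the original dataset.
`validate_reference_connectome()` runs those numeric comparisons (40 Hz
node mean at $\sigma = 0.07$ with $G = 2.3$; 6.64% focal connection loss;
40 ± 10 ms TMS return) when pointed at the real matrix in GraphML form.

## Problem sizes and degenerate inputs

Unit tests run on small fixtures (single nodes for fixed-point oracles,
8–20-node random networks for graph and I/O properties); the acceptance
suite runs the full 998-node protocols with 5 seeds per condition, and the
calibration probes use 4 s runs sampled at 10 ms. Degenerate inputs are
defined: zero-node connectomes write and read as valid empty GraphML;
empty lesions are identities; empty region lists give empty node sets; a
window outside a series' span, an inverted stimulation window, or a
connectome with no connections raise informative errors; a perturbed run
that never re-enters the baseline band yields an `NA` "not-returned"
sentinel rather than an exception.

## Known limitations

* No haemodynamic (BOLD) forward model, no functional-connectivity
  validation, no spiking implementation, no plasticity.
* Undirected connectomes only — tractography cannot resolve fiber
  direction, and the whole pipeline assumes symmetric coupling.
* Graded (partial) edge lesions and biophysical stimulation field models
  are out of scope; lesions are all-or-none disconnections and TMS is a
  uniform current into a node set.
* The synthetic generator is a shape-level surrogate (see above); results
  that depend on hub structure or spatial wiring statistics do not
  transfer from it to real data.
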