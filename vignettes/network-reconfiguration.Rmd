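---
title: "Dynamic brain-network reconfiguration: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic brain-network reconfiguration: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netreconfig)
```

## The problem

Resting-state EEG networks are not static. Channels (as proxies for
cortical regions) organize into communities of mutually phase-locked
oscillators, and those communities rearrange on the scale of seconds.
`netreconfig` quantifies that rearrangement: how often a channel changes
community, whether it moves together with partners or alone, and how
strongly pairs of channels co-move. These reconfiguration statistics
separate clinical groups in published work and are the package's target
quantities.

The pipeline is: preprocess → band-limit → window → phase-locking
connectivity → multilayer community detection with statistical validation
→ reconfiguration metrics → group statistics and classification.

## Signal model and preprocessing

A recording is a channels × time matrix at sampling rate $f_s$ (500 Hz in
the default geometry, 19 channels in 10–20 order). Preprocessing applies a
second-order IIR notch (default 50 Hz, quality factor 30 — narrow enough
not to distort the gamma band) and a 1 Hz order-4 Butterworth high-pass.
Band decomposition uses order-4 Butterworth band-passes for delta (1–4),
theta (4–8), alpha (8–13), beta (13–30) and gamma (30–45 Hz).

All filters are applied forward–backward (zero phase), which matters
because the downstream statistic is a phase statistic. Because no DSP
package ships with this R stack, the designs are built from first
principles: analog Butterworth prototype poles, pre-warped bilinear
transform, and second-order sections. SOS form is not cosmetic — a single
degree-8 polynomial for the delta band at $f_s = 500$ Hz (normalized
cutoffs 0.004–0.016) is numerically fragile, while biquad cascades are
stable. Start-up transients are suppressed with odd-reflection padding and
steady-state initial conditions per section.

Filtering happens on the full-length signal *before* windowing, so no
window carries filter edge transients. Windows are non-overlapping, 2 s by
default, and a trailing partial window is discarded: 60 s gives exactly
$L = 30$ layers. An optional `edge_trim_s` argument can drop the first and
last moments of the recording (Hilbert-transform edge artifacts) at the
cost of fewer windows; the default is 0 so the layer-count contract stays
exact.

## Connectivity: phase locking value

Within each window, the connectivity between channels $i$ and $j$ is the
phase locking value

$$\mathrm{PLV}_{ij} = \left| \frac{1}{n}\sum_{t=1}^{n}
  e^{\,\mathrm{i}(\phi_i(t) - \phi_j(t))} \right|,$$

with $\phi$ the analytic-signal (Hilbert) phase of the band-limited
channel. The phase is computed once per band on the full-length filtered
signal and then sliced into windows, again to avoid per-segment transform
artifacts. PLV is 1 under perfect locking (including any constant phase
offset), $\approx \sqrt{\pi/4n}$ for independent phases, and exactly 0
when the phase difference completes whole cycles over the window. Layers
stay fully weighted — no thresholding or binarization anywhere.

## Multilayer community detection

Each subject × band yields $L$ symmetric PLV matrices over the same 19
nodes. Communities are found by modularity optimization,

$$Q = \frac{1}{2m}\sum_{ij}\left[W_{ij} - \gamma\frac{k_ik_j}{2m}\right]
  \delta(c_i, c_j),$$

with a seeded Louvain algorithm (local moves with lowest-index
tie-breaking, seed-shuffled sweep order, community aggregation).
Temporal consistency is obtained by maximizing the multilayer quality

$$Q_{ml} = \frac{1}{2\mu}\sum_{ijs}\left[W_{ijs} -
  \gamma\frac{k_{is}k_{js}}{2m_s}\right]\delta(c_{is},c_{js})
  + \frac{1}{2\mu}\sum_{is} 2\omega\,\delta(c_{is},c_{i,s+1}),$$

i.e. Louvain on the supra-modularity matrix with ordinal coupling
$\omega$ between copies of the same node in adjacent layers. The best of
`n_init = 100` seeded runs is returned.

Two implementation details proved load-bearing. First, one run is
warm-started from the independent per-layer partitions (each layer's
communities entering with distinct ids; the aggregation phase merges them
across layers). Second, after each multi-level pass the optimizer restarts
local moves at the node level from the current partition and repeats until
$Q_{ml}$ stops improving. Plain one-shot Louvain reproducibly missed the
global optimum on planted switch instances (e.g. found $Q_{ml} = 0.545$
where the planted truth scores $0.569$); with both refinements the truth
is recovered exactly on the test instances.

**Parameter defaults.** $\gamma = 1$ (dimensionless resolution; the
classical null), $\omega = 1$ (dimensionless coupling; of the same order
as a typical layer's modular gain for 19-node PLV matrices, so layers are
smoothed but a genuine switch still pays for itself), both configurable.

## Statistical validation of layers

Each layer's partition is tested against 100 surrogate networks that
preserve the binary degree sequence (Maslov–Sneppen double edge swaps) and
the exact multiset of edge weights (shuffled over the rewired edge slots).
On complete graphs — which PLV matrices are — rewiring is the identity and
the null reduces to a weight shuffle, as it should. Each surrogate is
itself Louvain-optimized, and the layer is retained when its observed
maximized modularity significantly exceeds the surrogate distribution,
with Bonferroni correction across the $L$ layers of the subject × band.

The p-value estimator deserves a note. The empirical exceedance estimator
$(1 + \#\{Q_{surr} \ge Q_{obs}\})/(n_{surr}+1)$ has a floor of $1/101$ at
100 surrogates and therefore *cannot* reject at the Bonferroni level
$\alpha/L$ once $L > 4$ — at $L = 30$ every layer would always fail. The
default estimator is therefore the upper tail of a Gaussian fitted to the
100 surrogate modularities, which resolves arbitrarily small tails while
agreeing with the empirical estimator in its valid range. The empirical
variant remains available (`method = "empirical"`), and the type-I
calibration of the default is part of the acceptance suite (valid-layer
rate ≤ 0.05 on fully random multilayers; ≥ 0.95 on planted two-community
layers).

Transitions into or out of an invalidated layer are skipped by all
reconfiguration metrics, which renormalize by the number of transitions
actually used.

## Reconfiguration metrics

Let $T$ be the number of usable transitions between consecutive valid
layers, after aligning community labels across layers (greedy maximal
Jaccard matching; unmatched communities get fresh ids — alignment permutes
labels only and never changes which nodes share a community). Node $i$
*moves* at a transition when its label changes; the move is *cohesive*
when at least one other node moves to the same target community at the
same transition, and *disjoint* (solo) otherwise. Every move is exactly
one of the two. Then:

* flexibility $f_i$ = moves / $T$,
* disjointedness $d_i$ = solo moves / $T$,
* cohesive fraction $c_i$ = partnered moves / $T$, so $f_i = c_i + d_i$
  holds *exactly* (it is stored that way, making the identity bitwise),
* cohesion matrix: $\mathrm{counts}_{ij}$ = number of transitions where
  $i$ and $j$ co-move into the same community;
  cohesion strength $s_i = \sum_j \mathrm{counts}_{ij} / T$ (a node
  travelling with $k-1$ constant partners scores $k-1$; strength may
  exceed 1, disjointedness cannot),
* community cohesion = mean over nodes of $s_i$; community disjointedness
  = mean over nodes of $d_i$; community change = their sum (again exact).

"Co-move" requires a shared *target* community, not a shared source; this
is what makes cohesive/disjoint a true dichotomy and the additive
identities exact. Community-level metrics are node-set means, one value
per subject × band, which reproduces the published additive relation
between band-level means (e.g. cohesion 1.96 + disjointedness 0.16 =
change 2.12) and the published magnitudes (strength above 1,
disjointedness well below 1).

## Group analysis

Group differences per metric × band × site use the Kruskal–Wallis omnibus
(tie-corrected, $\chi^2_{k-1}$ reference) followed by Dunn's rank-based
pairwise z tests with Benjamini–Hochberg FDR, the family being all group
pairs and sites within one metric × band (matching per-figure correction).
`significance_matrix()` emits the site × band 0/1 heatmap matrix per group
pair.

The classifier benchmark is one-vs-rest with repeated matched subsampling:
per repetition, 20% of the target group forms the positive test set with
an equal-sized random non-target sample; training uses the remaining
target subjects plus an equal-sized disjoint non-target sample, so chance
is 0.5. Standardization parameters come from the training split only.
Six classifiers run by default — RBF-kernel SVM (least-squares
formulation, since no SVM package is available in this stack), random
forest and binomial gradient boosting on a shared compiled CART learner,
a one-hidden-layer MLP trained by Adam, Gaussian naive Bayes, and KNN
(FNN). Default features: cohesion strength at 19 sites × 5 bands = 95
features. Scores (accuracy, precision, recall, F1) are reported as mean ±
sd over `n_repetitions` (1000 by default; the acceptance run uses 100).

## The synthetic cohort: what it emulates, and what it does not

The generator plants ground truth at two levels.

*Networks:* `generate_planted_multilayer()` draws a stochastic block model
per layer from a community schedule (epochs of constant membership tiling
the layer axis). Edge presence is stochastic (`p_in`, `p_out`); edge
weights are the fixed values `weight_in`/`weight_out`, so the
`p_in = 1, weight_in = 1` limit is exactly a disjoint union of unit
cliques.

*Recordings:* `generate_recording()` gives each community, in each band, a
sinusoidal carrier whose phase performs a slow random walk
(`phase_jitter_sd = 0.05` rad/sample, i.e. a fraction-of-a-Hz linewidth).
Channels sharing a community carry that common oscillation (with
per-channel amplitude jitter), so their noiseless PLV is exactly 1.
Carriers of distinct communities are spread across the band interior
(fractions 0.2–0.8 of the band width over four slots) rather than all
sitting at the band's geometric mean: with a single shared carrier,
between-community PLV driven only by phase diffusion averaged 0.3–0.5 per
2-s window, which is not how distinct neural populations behave and
defeats the required within/between contrast. With spread carriers the
within/between PLV ratio exceeds 3 (typically 5–9). White Gaussian noise
(`noise_sd = 0.5` per unit oscillation amplitude) is added across the
record.

The group deficit is a *coupling multiplier* $c \in (0,1]$: a channel's
band signal is $c \cdot$ (common community oscillation) $+ (1-c) \cdot$
(an independent oscillation with its *own* carrier, drawn uniformly from
the band interior — an uncoupled oscillator has no reason to sit at the
community's frequency, and tying it there would artificially preserve
community structure in low-coupling subjects). Controls have $c = 1$,
patients $c = 0.5$ by default. Lowering $c$ degrades phase locking without
much changing band power, which blurs the detected communities and, at
scheduled switches, breaks up coordinated co-transitions — exactly the
"reduced cohesion strength" phenotype. A `switch_rate` multiplier can
additionally rescale the number of scheduled switches per group.

Epoch boundaries align with window edges, so layer-level ground truth is
unambiguous. Default geometry mirrors the study: 19 channels, 500 Hz,
60 s (duration is a free choice — the study does not state one — 60 s
gives 30 layers, enough transitions for stable rates while keeping the
full-cohort acceptance run around six minutes).

What the generator does **not** emulate: disorder-specific spectral
signatures (1/f background, alpha slowing, asymmetries), volume
conduction, artifacts, or electrode covariance structure. A green
end-to-end test therefore establishes that the pipeline recovers planted
community dynamics and planted group effects from oscillatory signals —
not that it reproduces any clinical result on real EEG.

## Numerical choices and degenerate inputs

* Louvain ties between candidate communities keep the lowest community id;
  sweep order is seed-shuffled; all seeding uses an internal xorshift RNG
  so results are independent of R's global RNG state.
* Modularity includes diagonal null terms, so the one-community partition
  scores exactly 0 at $\gamma = 1$.
* An all-zero channel has undefined phase → error. Zero-total-weight
  layers → error. Fewer than two usable transitions → error (metrics
  undefined rather than silently 0). In the cohort pipeline a band whose
  layers all fail validation yields NA metrics, which the feature matrix
  maps to 0 ("no validated moves observed") — a documented convention,
  not a claim of zero uncertainty.
* Empirical surrogate p-values use the +1 correction; the Gaussian tail
  default exists because Bonferroni at $L > 4$ is unreachable otherwise
  (see above).
* EDF export quantizes to 16 bits over each channel's physical range;
  round-trips are exact to one quantization step.

## Known limitations

* The inter-layer coupling $\omega$ and resolution $\gamma$ are fixed
  defaults, not data-driven; a sensitivity sweep is a one-liner over
  `temporal_consensus()` but no automatic selection is provided.
* Consensus is best-of-`n_init` by $Q_{ml}$, not association-matrix
  clustering; with 100 initializations plus the warm start this found the
  planted optimum in every seeded test, but no global-optimality guarantee
  exists.
* PLV is the only connectivity estimator (by design); it is sensitive to
  volume conduction on real EEG, and no correction is applied.
* The least-squares SVM and compact MLP are faithful to their families but
  not drop-in replacements for libsvm/sklearn hyperparameter behaviour.
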