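---
title: "From transient waveforms to graphs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From transient waveforms to graphs: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ergraph)
```

## The transform

`ergraph` analyzes short transient electrophysiological waveforms — its
motivating signal is the light-adapted flash electroretinogram (ERG), a
200–300 ms retinal response sampled at 2 kHz — by mapping each waveform to
a weighted undirected graph and classifying subjects from the graph's
topology. The construction has three stages:

1. **Normalization.** Each waveform is min–max rescaled to $[0,1]$,
   $x(t) = (\tilde x(t) - \min \tilde x)/(\max \tilde x - \min \tilde x)$.
   Topology then reflects the *shape* of the amplitude trajectory, not
   electrode gain or impedance. Normalization is strictly per waveform.
2. **Quantization.** The normalized signal is snapped to $Q$ evenly spaced
   amplitude levels, $q(t) = \mathrm{round}(x(t)(Q-1))/(Q-1)$. Each visited
   level becomes a graph node, so the graph has at most $Q$ nodes.
3. **Graph construction.** Every consecutive sample pair $(q(t), q(t+1))$
   contributes an edge between its two levels with weight
   $w(v_i, v_j) = 1/(|l_i - l_j| + \varepsilon)$, $\varepsilon = 1/(Q-1)$.
   Nearby-level transitions are strong edges; large jumps are weak
   long-range edges; dwelling produces a self-loop of weight $Q - 1$.
   Revisited transitions increment an integer `count` on the edge.

From each graph nine features are extracted: total load centrality (the
betweenness sum $\sum_v \sum_{s \ne v \ne t} \sigma_{st}(v)/\sigma_{st}$),
total harmonic centrality $\sum_v \sum_{u \ne v} 1/d(v,u)$, the number of
maximal cliques, diameter, radius, average clustering coefficient, average
path length, algebraic connectivity $\lambda_2$ (the Fiedler value of the
weighted combinatorial Laplacian $L = D - A$), and density
$\rho = 2E/(V(V-1))$.

## Numerical and design choices

Several points are deliberately pinned down because the underlying
conventions vary between implementations:

* **Rounding ties.** $x(Q-1)$ exactly halfway between integers rounds
  half-away-from-zero (0.5 → 1). R's `round()` uses banker's rounding,
  which would make outputs representation-dependent; since $x \ge 0$ we use
  `floor(x (Q-1) + 0.5)`.
* **Flat signals.** Min–max normalization is undefined when
  $\max = \min$. Such waveforms become the constant 0.5, are flagged
  `degenerate`, and produce a single-node self-loop graph, keeping batch
  pipelines total.
* **Edge weight versus accumulation.** The weight formula is a function of
  the endpoint levels alone, while repeated transitions intuitively
  "strengthen" an edge. We store both: `weight` (used in $A$ and $L$) and
  `count` (transition multiplicity). `use_count_weight = TRUE` in
  `spectral_summary()`/`as_igraph()` multiplies them for sensitivity
  analysis; the default keeps the level-determined weights.
* **Self-loops** are recorded on the graph (dwelling is informative) but
  excluded from the adjacency matrix, the Laplacian, degrees, density and
  clustering: $L = D - A$ is invariant to self-loops under the standard
  convention and the $V(V-1)$ density denominator presumes a simple graph.
* **Distances.** Path-based features (load centrality, harmonic
  centrality, diameter, radius, average path length) use hop counts on the
  simple graph by default. The weighted graph admits several defensible
  distance conventions; hop counts avoid an arbitrary weight-to-length
  mapping and put diameters of 50-node graphs in the single digits, which
  matches the scale on which these features discriminate. A weighted mode
  (edge length $|l_i - l_j| + \varepsilon$, the inverse weight) is
  available via `weighted_paths = TRUE`.
* **Disconnected graphs.** The quantization graph of a well-behaved
  waveform is connected, but alternative constructions (recurrence and
  $\varepsilon$-ball graphs at small thresholds) can disconnect. The
  default "giant" policy computes diameter, radius, average path length
  and $\lambda_2$ on the largest connected component with a warning;
  `connectivity = "strict"` errors instead. Harmonic centrality needs no
  policy ($1/\infty := 0$), and load centrality, cliques, clustering and
  density are well defined globally.
* **Eigensolver.** Node counts never exceed $Q \approx 50$–100, so the
  Laplacian spectrum comes from a dense symmetric `eigen()` call; no
  iterative-solver tolerances enter the results.
* **Level-count refinement.** The number of distinct quantization levels
  grows with $Q$ as a strong trend but *not* monotonically step by step:
  two values straddling a coarse bin boundary (e.g. 0.4 and 0.6 at
  $Q = 2$) can merge at a finer resolution ($Q = 3$ maps both to 0.5). The
  test suite asserts the true properties: the count is bounded by
  $\min(N, Q)$, correlates strongly with $Q$, and exactly recovers the
  number of distinct signal values once $1/(Q-1)$ falls below the smallest
  gap.

Five comparison constructions are provided with conventional defaults:
natural visibility graph (strict convexity rule), recurrence network
(threshold $\varepsilon_r = 0.1$ on the normalized amplitude, embedding
dimension 1, delay 1 — both exposed), $k$-nearest-neighbour graph in
amplitude space ($k = 3$, distance ties broken by the earlier time index),
$\varepsilon$-ball graph over visited levels (default radius $2/(Q-1)$,
connecting adjacent and next-adjacent levels), and ordinal partition
network (pattern dimension $m = 3$, delay 1, rank ties broken
earlier-index-smaller).

## The synthetic cohort generator

The clinical recordings that motivated this package are not public, so the
generator in `generate_waveform()`/`generate_cohort()` exists to make every
downstream stage testable. It emulates photopic ERG morphology as a sum of
Gaussian bumps plus a windowed sinusoid: an a-wave trough near 15 ms, a
dominant b-wave peak near 32 ms, oscillatory potentials (~120 Hz) on the
b-wave rising limb, a late photopic negative response near 70 ms, and
additive Gaussian noise, at 2 kHz over 250 ms (N = 500). Cohorts mirror a
two-site pediatric study design: groups ASD/ADHD/ASD+ADHD/control with
subject counts 77/43/21/137, one to four recordings per subject, eye and
flash-strength cell, both eyes, and flash strengths 113 and 446 Td.s.
Between-subject variability is log-normal and multiplicative on the
component amplitudes (keeping them positive, SD 0.15 on the log scale);
within-subject repeat variability is smaller (SD 0.05) so that subject-wise
cross-validation leakage is detectable. The 446 Td.s condition scales the
component amplitudes *and* the noise SD by 1.35: we treat residual
variability after sweep averaging as roughly proportional to the response,
which keeps the two flash conditions topologically comparable while the
stronger flash yields larger absolute responses. None of this claims
physiological accuracy; it reproduces the *described* morphology and the
group contrast below.

The group presets encode the clinically reported contrast between a
"compact" and an "expansive" amplitude topology. `COMPACT` (ASD-like) has
small, sharp transients (a-wave 10 µV / 0.9 ms, b-wave 22 µV / 2.2 ms,
oscillatory ripple 2.5 µV, PhNR 1 µV, noise 2.3 µV): after normalization
the noise occupies relatively more of the amplitude range and the fast
sweeps skip levels, so the graphs have fewer nodes that are densely,
redundantly interconnected — smaller diameter and path length, higher
clustering, density and $\lambda_2$. `EXPANSIVE` (ADHD-like) has a large,
broad b-wave (70 µV / 10 ms) with strong oscillatory potentials (12 µV),
so the normalized trajectory sweeps slowly through nearly every level —
chain-like graphs with more nodes, larger diameter, higher load and
harmonic centrality, lower clustering. The preset constants were tuned
once against this directional pattern (all nine feature signs, with large
Cliff's delta for diameter, average path length and clustering) and then
frozen; they are repo constants, not estimates of clinical parameters.

What the generator does *not* emulate: real ERGs have correlated
(band-limited) noise, age and sex effects on morphology, device-specific
preprocessing, and within-protocol latency variation. Passing tests on
synthetic cohorts therefore demonstrate that the pipeline recovers the
structure the generator encodes — not that the same accuracy would be
obtained on clinical data.

## Group statistics

`feature_stats_table()` applies the nonparametric battery appropriate for
these skewed, bounded features: Kruskal–Wallis H (average-rank tie
correction, $\chi^2$ p-values) across groups per feature, Dunn's post hoc
z-tests on pooled ranks with Bonferroni correction, and Cliff's delta
$\delta = (\#\{x_i > y_j\} - \#\{x_i < y_j\})/(n_x n_y)$ per pair. A
Shapiro–Wilk p-value is recorded per feature as metadata (the conventional
justification for going nonparametric). Effect-size labels use
lower-closed/upper-open bins — negligible $[0, 0.15)$, small
$[0.15, 0.28)$, medium $[0.28, 0.43)$, large $[0.43, 1]$ — the bins being
prose conventions whose boundary membership we fixed on the side implied
by "large (≥ 0.43)". The default post hoc alpha 0.017 is $0.05/3$ for
three pairwise comparisons and is a default, not a constant. Recordings
(not subjects) are the default sampling unit; `per_subject_mean = TRUE`
averages repeats per subject first.

## Classification pipeline

`run_nested_cv()` implements three-stage training with subject-wise
validation throughout, because repeated recordings of one subject are far
more similar than recordings of different subjects:

1. **Feature selection** on the outer-training rows: 500-tree random
   forest impurity importance, top-$k$. `top_k = "auto"` picks $k$ over
   the grid $\{3, 5, 7, 9, \text{all}\}$ by inner-CV balanced accuracy;
   the grid bounds reflect that useful models in this domain use a handful
   to a few dozen features.
2. **Model selection** (when more than one candidate classifier is given):
   3-fold subject-wise inner cross-validation. SMOTE oversampling (k = 5
   neighbours, minority classes raised to parity) is fit on the
   inner-training portion only; validation rows are never synthetic and
   never resampled. Ties go to registry order — reproducibility over
   optimism.
3. **Refit and evaluate**: the winner is refit on the SMOTE-balanced outer
   training set and scored on the untouched outer-test fold. Balanced
   accuracy (mean per-class recall) and macro-F1 are reported per fold
   with mean ± SD.

The classifier registry pins seven conventional learners: random forest
(500 trees), AdaBoost (200 depth-1 trees, SAMME — implemented on rpart
stumps), gradient boosting (200 estimators, depth 3, learning rate 0.1,
via xgboost), XGBoost (depth 6), RBF-kernel SVM, 5-nearest-neighbours, and
a multilayer perceptron. The MLP uses `nnet`'s single-hidden-layer
architecture with 128 units and weight decay $10^{-3}$; a second hidden
layer is not available in the standard R stack, and on feature vectors of
this size (9–40 inputs) one layer has ample capacity. All stochastic
stages derive their seeds from the master seed, so a `cv_result` is
byte-reproducible.

Scenario construction follows the diagnostic conventions: the binary
ASD-vs-control scenario pools ASD with the co-occurring ASD+ADHD group
(ADHD-only excluded), the ADHD scenario pools ADHD with ASD+ADHD, the
three-group scenario drops the co-occurring group, and the four-group
scenario keeps all labels. Right+left eye fusion concatenates feature
vectors of same-subject recordings paired by flash and recording index —
the pairing rule is this package's policy (the convention is not
standardized), and unpaired recordings are dropped with a logged count.
Stage-1 selection is refit in every outer fold, again a deliberate
anti-leakage policy.

`q_sweep()` traces balanced accuracy, mean graph density and mean
connected-component count over a grid of $Q$; on synthetic cohorts density
decreases monotonically in $Q$ while graphs stay connected through
$Q \approx 60$, and $Q = 50$ is the package default.
`compare_constructions()` evaluates the six constructions under one fixed
classifier and a single shared fold assignment so the comparison is
controlled.

## Problem sizes in the shipped checks

The test-suite and acceptance-script problem sizes are the package's
reference configurations: 200 random graphs (≤ 12 nodes) against
brute-force oracles at $10^{-9}$ relative tolerance; 1000 random quantized
signals for the construction contracts; 50-waveform mixed cohorts for the
density/connectivity curves over $Q \in \{10, \dots, 80\}$; 60 waveforms
per group at $Q = 50$ for the compact/expansive directionality; and
30-subject two-class cohorts with 10 outer folds for the learning and
permutation-null checks (2000 simulations for the Kruskal–Wallis type-I
rate). These sizes give stable properties while keeping a full run in the
minutes range on one CPU.

## Known limitations

* The generator's noise is white; real band-limited noise (0.1–300 Hz)
  would slightly smooth level transitions.
* Hop-count distances discard the weight structure by default; both
  conventions are implemented but only the default is exercised by the
  shipped acceptance checks.
* The AdaBoost and MLP registry entries are R-stack reconstructions of
  their conventional Python counterparts (SAMME on stumps; one hidden
  layer), with hyperparameters pinned in the registry.
* Four-group scenarios on small synthetic cohorts are limited by the
  co-occurring group's size, exactly as in the clinical setting they
  mirror.
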