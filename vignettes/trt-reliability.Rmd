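---
title: "Test-retest reliability of functional brain-network graph metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Test-retest reliability of functional brain-network graph metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trtnet)
```

## The problem

Graph-theoretical summaries of resting-state functional connectivity —
small-world indices, efficiency, modularity, nodal centralities — are only
useful as biomarkers if they are stable when the same person is scanned
twice. trtnet quantifies that stability: it takes per-subject, per-scan ROI
time series or correlation matrices, builds networks at exact sparsity
levels, computes 12 global and 6 nodal metrics, and expresses test-retest
(TRT) stability as an intraclass correlation coefficient (ICC), summarized
across thresholds by the area under the metric-sparsity curve (AUC). A
companion simulation quantifies how robust each metric is to numerical
noise in the connectivity values themselves.

## The reliability model

For a measure observed on $n$ subjects at $k$ repeated scans, a one-way
ANOVA with random subject effects splits the total sum of squares into a
between-subject part ($MS_b$, on $n-1$ df) and a within-subject residual
($MS_w$, on $n(k-1)$ df). The reliability statistic is the single-score
one-way ICC,

$$\mathrm{ICC} = \frac{MS_b - MS_w}{MS_b + (k-1)\,MS_w},$$

which equals the share of total variance attributable to stable subject
differences. It is linked to the ANOVA $F = MS_b / MS_w$ by
$\mathrm{ICC} = (F-1)/(F+k-1)$; `icc()` and `icc_from_f()` implement both
routes and agree to $10^{-10}$, which the test suite checks on random
tables. Negative estimates are reported as computed — truncation would
bias grade counts — and graded *poor*. The qualitative bands are
lower-inclusive: below 0.25 poor, 0.25–0.4 low, 0.4–0.6 fair, 0.6–0.75
good, 0.75–1.0 excellent. Two-way ICC variants (which separate a fixed
scan effect) are deliberately out of scope: the one-way form treats any
session effect as within-subject noise, which is the conservative choice
for TRT screening.

Two scan pairings are built by `run_study()`: a short-term condition
(scans 2 vs 3, same session) and a long-term condition (scan 1 vs the
average of scans 2 and 3). Averaging is done on the connectivity matrices,
not on derived metrics, and in Fisher-z space: the z-transform
variance-stabilizes correlations, so averaging there is the field norm
(`average_matrices()` exposes an r-space switch for sensitivity checks).

## Network construction

Connectivity is the Pearson correlation of (optionally nuisance-regressed
and 0.01–0.1 Hz band-passed) ROI time series. The band-pass is a
forward–backward 2nd-order Butterworth design, i.e. zero-phase; only the
band is scientifically meaningful, the filter family is a convention.

Thresholding fixes the *sparsity* $S$ — the fraction of the $N(N-1)/2$
possible connections retained — rather than a correlation cutoff, so every
subject and scan contributes a network with exactly
$E = \mathrm{round}(S \cdot N(N-1)/2)$ edges (half-up rounding; the
implied subject-specific cutoff $r_0$ is recorded). Ranking is by
salience: $|r|$ under absolute-value membership, $r$ after zeroing
negatives under positive-only membership. Ties at the cut break by
lexicographic ROI order, which makes edge sets deterministic and nested
across the grid. Under positive-only membership the attainable sparsity is
data-limited; grids are truncated at the minimum attainable value over all
subjects and scans entering a comparison (`truncate_grid()`).

Weighted networks carry the salience as weight; binarized networks carry
0/1. Downstream, weighted path lengths use edge length $1/w$, weighted
clustering is the Onnela geometric-mean triangle intensity with weights
normalized by the network maximum (bounded in $[0,1]$ and invariant to
global weight rescaling), and weighted degree is strength. These weighted
conventions are exactly that — conventions, chosen from the common
toolbox-era definitions — and are pinned by brute-force oracle tests.

## Metrics and their degenerate cases

The 12 global metrics are clustering $C_p$, characteristic path length
$L_p$, their surrogate-normalized ratios $\gamma$, $\lambda$ and
small-worldness $\sigma = \gamma/\lambda$, local and global efficiency,
assortativity, hierarchy, synchronizability, modularity $Q$ and the number
of modules; the 6 nodal metrics are degree, efficiency, betweenness,
clustering, participation and normalized participation.

Numerical choices that matter:

* **Disconnection.** Sparse thresholds produce disconnected graphs.
  $E_{glob}$-type quantities handle this natively (unreachable pairs
  contribute 0); $L_p$ switches to the harmonic-mean form
  $N(N-1)/\sum_{i \ne j} 1/d_{ij}$ so it stays finite.
* **Surrogates.** $\gamma$ and $\lambda$ are normalized against
  degree-preserving double-edge-swap surrogates (default 100 surrogates,
  $10E$ swap attempts; both config-exposed). Weighted surrogates rewire
  the topology and randomly permute the original weight multiset. If the
  ensemble is degenerate (mean surrogate clustering 0, possible at very
  low sparsity), $\gamma/\lambda/\sigma$ are flagged undefined rather than
  aborting.
* **Modularity.** Deterministic greedy Q-maximization (fast-greedy
  agglomeration), so repeated runs of the reliability pipeline cannot
  differ through algorithmic randomness. If the greedy cut returns
  $Q \le 0$ the single-community partition (whose $Q$ is 0 by definition)
  dominates and is returned instead.
* **Normalized participation.** The spread of a node's edges over $M$
  modules maxes out at $1 - 1/M$; `participation_coef()` divides by that
  ceiling so an evenly spread node attains 1 at any $M$. At $M = 1$ the
  quantity is undefined.
* **Flagging.** Assortativity on regular graphs, hierarchy with fewer
  than 3 eligible nodes, and normalized participation at $M=1$ are
  returned as `NA` and excluded pairwise downstream — silent zeros would
  masquerade as (un)reliability.

The AUC over the sparsity grid is a trapezoidal integral; flagged values
are pruned together with their grid points before integrating, so one
degenerate threshold does not discard a subject.

## The synthetic cohort generator

Real TRT cohorts are large downloads; the generator provides cohorts whose
reliability is analytically known, making ICC recovery testable end to
end. Per connection $(i,j)$, subject $s$, scan $t$, in Fisher-z space:

$$z_{ijst} = \mu_{ij} + b_{ijs} + w_{ijst}, \qquad
b \sim N(0, \sigma_b^2), \quad w \sim N(0, \sigma_w^2),$$

with $r = \tanh(z)$. Working in z-space keeps correlations inside
$(-1,1)$ and makes the variance decomposition exact: the true ICC of every
connection is $\sigma_b^2 / (\sigma_b^2 + \sigma_w^2)$. Matrix mode
returns the $\tanh$-mapped matrices directly (downstream stages never
require positive-definiteness). Time-series mode first repairs each scan
matrix to the nearest positive-semidefinite correlation matrix (eigenvalue
clipping at $10^{-8}$ followed by re-normalization to unit diagonal,
iterated), then draws the requested number of multivariate Gaussian
samples; Pearson sampling error then inflates the within-subject variance,
so ICC-recovery assertions are made in matrix mode only.

Defaults are chosen for testability, not biological realism: $\mu = 0.2$
z-units of shared connectivity, $\sigma_b = \sigma_w = 0.3$ (true ICC
0.5, the middle of the grading scale, where recovery errors are most
visible). Real resting-state data differ in ways the generator does not
emulate — spatially structured connectivity, autocorrelated and
physiologically structured noise, motion artifacts, session effects —
so passing recovery tests demonstrates that the *estimator machinery* is
correct, not that any particular empirical reliability value will be
reproduced. Matching `edgewise_reliability()` to the generator, edgewise
ICC is computed on Fisher-z values by default (r-space switchable).

Seeding: each (subject, scan) cell draws from a seed derived
arithmetically from the master seed and its counters, so cohorts are
bit-reproducible independent of generation order.

## The noise experiment

`run_noise_experiment()` mirrors the robustness simulation: reference
metrics are computed from each subject's clean matrix; Gaussian noise with
variance equal to a fraction of that subject's own connectivity variance
(the strict upper triangle's variance — the constant diagonal would
dilute it) is added symmetrically in r-space with clipping to $[-1,1]$;
the full construction-plus-metrics pipeline is re-run; and the ICC between
reference and noisy AUC values across subjects (reference and noisy
playing the role of the $k=2$ scans) is averaged over repetitions. The six
default levels are $i/6 \times 50\%$ for $i = 1..6$, i.e. 8.3% to 50.0%,
with 5 repetitions.

Two deliberate choices: noise is added in r-space (it perturbs
"correlation values", not their z-transforms), and the surrogate-ensemble
seed is a per-subject pipeline constant shared between reference and noisy
runs, so Monte-Carlo noise in $\gamma/\lambda/\sigma$ does not masquerade
as unreliability. The default factor cell is absolute-value membership:
at the 50% level enough connections flip sign that a positive-only grid up
to $S = 0.5$ becomes unattainable for some matrices.

One known discontinuity: metrics that depend on a module partition
(participation) can respond non-smoothly to infinitesimal noise, because
one flipped rank at the sparsity cut can reassign the greedy partition.
At vanishing noise this shows up as isolated node-level ICCs slightly
below 1 while every metric-level mean (nodal metrics averaged across
nodes) stays above 0.99.

## Problem sizes used by the tests and the acceptance script

Simulation sizes are scaled to what the properties need: exhaustive
metric-oracle checks enumerate all labeled connected graphs on up to 5
nodes and sample 6–8-node graphs (metrics are label-invariant, which is
tested separately, so sampling covers the remaining space); ICC recovery
uses 200-subject, 30-ROI matrix-mode cohorts; the variance-ratio sweep
uses 25-subject, 12-ROI cohorts; the noise experiment runs 10 subjects at
10 ROIs with a 0.1–0.5 grid in steps of 0.05 and 5 surrogates per network.
The full-design bookkeeping quantities (90-ROI edgewise tables, the
25-subject noise-count design) are computed at full size, since they are
cheap. Stochastic trend assertions (degradation with noise, nodal-vs-
global robustness) are majority votes over 5 independent seeds.

## Known limitations

* Inputs begin at ROI time series or correlation matrices; image-space
  preprocessing, atlas definition and motion estimation are upstream.
* The weighted-metric formulas are stated conventions; other toolboxes
  make different choices (e.g. Barrat clustering), which would change
  weighted results.
* One-way ICC only; no multiple-testing correction is applied to edgewise
  ICC tables.
* The generator's independence across connections ignores the spatial
  covariance of real connectomes; between-metric comparisons on synthetic
  cohorts should be read as statements about the pipeline, not the brain.
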