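# trtnet

Test–retest (TRT) reliability of graph-theoretical metrics of resting-state
functional brain networks.

Graph summaries of functional connectomes — small-world indices, efficiency,
modularity, nodal centralities — are candidate imaging biomarkers, but a
biomarker is only as good as its stability across repeated scans of the same
person. `trtnet` is an R package plus a set of analysis scripts that
quantify that stability end to end:

1. **Connectivity** — Pearson correlation matrices from ROI time series,
   with nuisance regression, zero-phase 0.01–0.1 Hz band-pass filtering,
   Fisher-z utilities and variance-stabilized scan averaging.
2. **Network construction** — thresholding at exact sparsity levels
   `S = E / (N(N−1)/2)` over a grid, binarized or weighted, with negative
   correlations either zeroed (positive-only) or kept by absolute value.
3. **Graph metrics** — 12 global (clustering C_p, path length L_p,
   γ, λ, small-worldness σ = γ/λ normalized against degree-preserving
   surrogates, local/global efficiency, assortativity, hierarchy,
   synchronizability, modularity Q, number of modules) and 6 nodal metrics
   (degree, efficiency, betweenness, clustering, participation, normalized
   participation).
4. **Reliability** — one-way random-effects intraclass correlation,

       ICC = (MS_b − MS_w) / (MS_b + (k−1)·MS_w),

   per connection and per metric, summarized across thresholds by the area
   under the metric–sparsity curve (AUC), graded poor / low / fair / good /
   excellent, for a short-term (scan 2 vs 3) and a long-term (scan 1 vs
   z-average of scans 2–3) pairing.
5. **Noise robustness** — proportional Gaussian noise injected into the
   connectivity matrices at six graded levels (8.3%–50.0% of each
   subject's connectivity variance), with metric reliability recomputed
   against the noise-free reference.

Because real TRT cohorts are large downloads, the package ships a synthetic
cohort generator with an analytically known reliability: connectivity is
drawn in Fisher-z space as `z = μ + b + w` with subject effect
`b ~ N(0, σ_b²)` and scan effect `w ~ N(0, σ_w²)`, so every connection's
true ICC is `σ_b²/(σ_b²+σ_w²)`. The whole pipeline — including ICC
recovery — is therefore testable without any external data.

## Worked example

```r
library(trtnet)

# cohort with known reliability: true ICC = 0.3²/(0.3²+0.3²) = 0.5
cfg <- cohort_config(n_subjects = 25, n_scans = 3, n_rois = 30,
                     mu = 0.2, sigma_b = 0.3, sigma_w = 0.3, seed = 1)
cohort <- generate_cohort(cfg)

# edgewise reliability, short-term pairing (scan 2 vs scan 3)
ew <- edgewise_reliability(cohort_scans(cohort, 2), cohort_scans(cohort, 3))
ew$mean_icc
#> [1] 0.4845507
ew$grade_counts
#> grades
#>      poor       low      fair      good excellent
#>        35        76       224        89        11
```

The mean edgewise ICC of 0.48 recovers the design value 0.5 up to
estimator noise at n = 25; most connections grade *fair*, as expected when
the truth sits mid-band. The long-term pairing (scan 1 vs the z-average of
scans 2–3) comes out *higher* (0.55 via `analysis/04_reliability.R`):
averaging two scans halves the within-subject variance on one side of the
comparison.

```r
# one network and its global metrics
m <- cohort$matrices[["sub-01"]][["scan-1"]]
net <- threshold_at_sparsity(m, 0.2, "positive_only", "binarized")
net
#> <brain_network> 30 nodes, 87 edges (S = 0.2), binarized/positive_only, r0 = 0.5059
round(global_metrics(net, n_random = 20, seed = 3), 3)[c("Cp", "Lp", "sigma", "modularity_Q")]
#>           Cp           Lp        sigma modularity_Q
#>        0.213        2.071        1.160        0.290
```

The numbered scripts under `analysis/` run the full study on this cohort:
`01_simulate_cohort.R` writes it to `results/cohort/`;
`02_connectivity.R` exercises the time-series branch (within-subject scans
have spatial similarity r ≈ 0.64, unrelated subjects r ≈ −0.06);
`03_networks_metrics.R` writes metric curves over the 2×2
membership-by-type factor grid; `04_reliability.R` produces the edgewise
and per-metric ICC tables (on this cohort — which has no structured
between-subject topology differences — global-metric AUC-ICCs grade
mostly poor, while edgewise ICC tracks its design value);
`05_noise_experiment.R` shows the reliability of nodal metrics degrading
much more slowly with connectivity noise than that of global metrics
(e.g. nodal 0.70 vs global 0.43 mean ICC at the 8.3% level).

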