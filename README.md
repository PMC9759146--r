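# megnet

Band-wise resting-state MEG functional-connectivity networks and weighted
graph-theory metrics, for studies that ask whether a clinical subgroup —
here, children with self-limited epilepsy with centrotemporal spikes
(SeLECTS) and cognitive impairment (full-scale IQ < 80) — shows altered
source-space network organization, and whether network metrics can
discriminate that subgroup.

The package covers the full analysis path from source-level ("virtual
sensor") time series to group statistics:

1. **Preprocessing** — 50 Hz notch, exclusion of >6 pT amplitude
   artifacts, automated spike flagging (robust z in the 1–70 Hz band),
   selection of the earliest spike-free 60 s segment, and decomposition
   into the seven canonical bands: δ (1–4), θ (4–8), α (8–12), β (12–30),
   γ (30–80), ripple (80–250) and fast ripple (250–500 Hz).
2. **Connectivity** — Pearson correlation R of every source pair over the
   segment, thresholded through the t-type statistic

   TP = R·√(K−2) / √(1−R²),

   keeping edges with |TP| above the two-sided Student-t critical value at
   p < .01 (K = samples in the window). Edges keep weight |R| and sign.
3. **Graph metrics** — node-averaged strength S_A, degree D_A,
   characteristic path length L_A (edge length 1/w_ij, unreachable pairs
   counting 0), and the geometric-mean weighted clustering coefficient C_A
   (weights normalized by the network maximum).
4. **Group statistics** — one-way ANOVA per band and parameter across the
   impaired / non-impaired / control groups with Bonferroni correction
   (3 × 7 = 21 tests for connectivity, 3 × 7 × 4 = 84 for graph metrics),
   post-hoc pairwise t-tests, clinical correlations, and binary
   logistic-regression/ROC discrimination (Mann–Whitney AUC, Youden
   operating point).
5. **Synthetic cohorts** — a generator that plants band-wise coupling with
   known expected correlation ρ and group-level coupling reductions, plus
   spike/artifact injection, so every stage is validated against ground
   truth. The 35-subject clinical table of the motivating cohort ships as
   a fixture.

## Worked example

```r
library(megnet)

cohort <- load_cohort()
summarize_cohort(cohort)
#> # A tibble: 9 × 5
#>   group   variable          n  mean    sd
#>   <chr>   <chr>         <int> <dbl> <dbl>
#> 1 FSIQ<80 age              17 6.88  0.993
#> 2 FSIQ<80 course_months    17 2.6   1.14
#> 3 FSIQ<80 n_seizures       17 2.88  0.993
#> 4 FSIQ>80 age              18 8.11  1.84
#> 5 FSIQ>80 course_months    18 0.583 0.311
#> 6 FSIQ>80 n_seizures       18 1.56  0.616
#> 7 all     age              35 7.51  1.60
#> 8 all     course_months    35 1.56  1.31
#> 9 all     n_seizures       35 2.2   1.05
```

The impaired group has a longer disease course (2.60 vs 0.58 months), more
seizures (2.88 vs 1.56) and younger age (6.88 vs 8.11 years); the pooled
t-test for course gives p ≈ 3e-8:

```r
compare_groups_ttest(cohort, "course_months")
#> # A tibble: 1 × 7
#>   variable          t    df            p mean_impaired mean_unimpaired method
#>   <chr>         <dbl> <dbl>        <dbl>         <dbl>           <dbl> <chr>
#> 1 course_months  7.21    33 0.0000000285           2.6           0.583 " Two Sa…
```

A minimal synthetic run — plant ρ = 0.6 on one alpha-band edge, extract the
60 s segment, build and summarize the thresholded alpha network:

```r
cfg <- sim_config(
  n_nodes = 3, fs = 200, duration = 70,
  bands = meg_bands(c("alpha", "beta")),
  planted_edges = tibble::tibble(node_i = 1, node_j = 2, band = "alpha", rho = 0.6),
  rho_jitter_sd = 0
)
rec <- generate_recording(cfg, seed = 5)
seg <- select_clean_segment(rec, flags = NULL, length_s = 60)
net <- threshold_network(pairwise_correlation(segment_bandpass(seg, "alpha")))
net
#> <meg_network> 3 nodes, 2 edges (1+, 1-), band alpha, alpha 0.01, K 12000
graph_metrics(net)
#> # A tibble: 1 × 10
#>   subject_id band  n_nodes k_edges    SA    DA    LA    CA fc_frontal fc_pcc
#>        <int> <chr>   <int>   <int> <dbl> <dbl> <dbl> <dbl>      <dbl>  <dbl>
#> 1         NA alpha       3       2 0.126 0.667 0.588     0          0      0
```

The planted edge is recovered (estimated R ≈ 0.57 against ρ = 0.6 for a
single draw; unbiased in expectation). `autoplot(net)` draws the signed
network, `autoplot(roc_analysis(...))` the ROC curve, and
`plot_band_metrics()` group-by-band boxplots.

The end-to-end pipeline (simulate → preprocess → connect → metrics →
stats) runs from a YAML configuration, in R via `run_all(demo_config())`
or from a shell via the thin CLI:

```sh
Rscript inst/cli/megnet.R all --config inst/extdata/demo_config.yaml --out demo_out
```

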