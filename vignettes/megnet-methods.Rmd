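---
title: "Band-wise MEG correlation networks: models, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Band-wise MEG correlation networks: models, conventions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megnet)
```

## The analysis in one paragraph

megnet implements a resting-state MEG functional-connectivity pipeline for
source-level ("virtual sensor") recordings in a pediatric focal-epilepsy
cohort (SeLECTS, self-limited epilepsy with centrotemporal spikes) split at
full-scale IQ 80 into a cognitively impaired and a non-impaired patient
group, plus healthy controls. Each subject contributes a 60 s spike-free
segment; in each of seven frequency bands (delta 1--4, theta 4--8, alpha
8--12, beta 12--30, gamma 30--80, ripple 80--250, fast ripple 250--500 Hz)
the Pearson correlation $R$ of every source pair is thresholded through its
t-type transform

$$TP = \frac{R\sqrt{K-2}}{\sqrt{1-R^2}},$$

with $K$ the number of samples, keeping edges with $|TP|$ above the
two-sided Student-$t$ critical value at $p < .01$. The retained signed,
weighted graph is summarized by four node-averaged metrics -- strength
$S_A$, degree $D_A$, characteristic path length $L_A$ (edge length
$1/w_{ij}$), clustering coefficient $C_A$ (geometric-mean triangle
intensity) -- which are compared across the three groups band by band with
one-way ANOVA under Bonferroni correction (21 tests for the connectivity
family, 84 for the graph-metric family) and used as predictors in
logistic-regression/ROC discrimination of the impaired group.

Because the underlying patient recordings are available only on request, the
package ships a synthetic generator that emulates the study conditions with
known ground truth, so every downstream stage is testable end to end.

## Connectivity model and thresholding

For sources $a$ and $b$, $R(X_a, X_b) = C(X_a, X_b) / (S_{X_a} S_{X_b})$.
We interpret $C$ as the sample covariance: that is the only reading under
which $R$ is a correlation bounded by 1, consistent with everything
downstream (the source description of the numerator as an "average of the
two signals" does not produce a correlation).

Thresholding is two-sided. Negative connections demonstrably exist in this
kind of data and are retained with their sign; the network stores weight
$|R|$ and the sign separately so that graph metrics can select edge sets
explicitly (see below).

`K` defaults to the raw sample count of the segment (360 000 at 6000 Hz),
matching the published rule. Band-limited signals are serially correlated,
so the raw count overstates the information content: under Bartlett's
approximation the variance of $\hat R$ between two independent filtered
signals is $\tfrac{1}{K}\sum_\tau \rho_a(\tau)\rho_b(\tau)$, which for an
ideal band of width $B$ over $T$ seconds corresponds to roughly $2BT$
effective samples rather than $f_s T$. Consequently the raw-$K$ rule is
anticonservative on null data -- it retains far more than 1% of uncoupled
pairs -- and increasingly so at higher sampling rates. `effective_samples()`
estimates per-pair effective counts from truncated autocorrelation sums
(default truncation 1 s), and `threshold_network(use_effective_k = TRUE)`
applies them. The default remains the raw-$K$ rule for fidelity; the
calibration property (retained-edge density $\approx \alpha$ on uncoupled
data) is verified in the test suite with the correction enabled, and the
raw-rule anticonservatism is asserted alongside as documented behaviour.

## Graph metrics: conventions that matter

* **Strength** (per node) is the sum of incident edge weights divided by
  $N$, following the printed $1/N$ normalization; a `"classic"` unnormalized
  option exists for comparability with other toolboxes. The summation index
  in the printed formula is garbled (it reuses the node index); we sum over
  partners $j$.
* **Path length** uses edge lengths $1/w_{ij}$ and sets $L_{i,j} = 0$ for
  unreachable pairs (and the diagonal), exactly as published. This is
  counterintuitive -- disconnecting a graph *shortens* its average path
  length -- but it is the stated convention and we follow it; comparisons
  between similarly dense networks remain meaningful.
* **Clustering** is the geometric-mean form
  $C_i = \frac{1}{d_i(d_i-1)}\sum_{j,k}(w_{ij} w_{jk} w_{ki})^{1/3}$ with
  weights first divided by the network's maximum weight. The printed formula
  omits the normalization that bounds $C_i$ in $[0,1]$; dividing by the
  maximum weight is the standard convention for this statistic and we
  document it as an interpretation. Nodes of degree < 2 get $C_i = 0$.
* **Edge policy.** The source analysis never states how negative edges enter
  graph metrics; its significant findings concern positive connections. By
  default all metrics are computed on the positive-edge subnetwork
  (`edge_policy = "positive"`); `"absolute"` and `"signed"` are exposed.
* The regional connectivity statistic behind the band-wise FC comparison is
  operationalized as the mean weight of retained positive edges incident to
  a node-role set (`"frontal"`, `"pcc"`), since no regional statistic is
  defined in the source beyond its anatomical label.

Dijkstra shortest paths are delegated to igraph; the test suite checks them
against a hand-written Floyd--Warshall oracle, and the clustering
implementation against a brute-force triple loop, on hundreds of random
graphs to 1e-12.

## Preprocessing chain

1. Amplitude artifacts: any sample exceeding 6 pT (in absolute value, per
   channel, any channel triggering) is flagged, padded by 0.5 s on each side
   (filter-edge contamination), and overlapping flags are merged.
2. Spikes: the published workflow identified epileptiform spikes visually in
   the 1--70 Hz band. The automated surrogate filters to 1--70 Hz and flags
   robust z-scores (median/MAD) above 6, with the same padding/merging.
3. Segment selection: the earliest window of exactly 60 s that overlaps no
   flag (earliest-window tie-break; the published selection rule is
   unstated).
4. Mains interference: a biquad IIR notch at 50 Hz, Q = 30, run forward and
   backward for zero phase.
5. Band decomposition: zero-phase frequency-domain filtering -- the DFT is
   multiplied by a real raised-cosine band gain (transition width the
   smaller of 10% of the bandwidth and half the low edge, at least
   0.05 Hz). We chose spectral filtering over a Butterworth band-pass after
   finding transfer-function IIR designs numerically unstable for narrow
   low bands at high sampling rates (1--4 Hz at 6000 Hz is 4 orders of
   magnitude below Nyquist); the spectral filter is exactly zero-phase,
   stable for every band-rate combination, and makes the generator's
   planted-correlation algebra exact.

## The synthetic generator

`sim_config()` fixes the study conditions: 120 s at 6000 Hz, seven bands,
background SD 0.5 pT (split evenly in power across bands) so the 6 pT rule
is meaningful. Within each band the node signals are jointly Gaussian with
a correlation matrix carrying the planted edges; the common band filter is
linear, so the expected band-filtered Pearson correlation of a planted edge
equals its configured $\rho$ exactly -- making recovery tests analytic. An
unrealizable set of planted correlations (non-positive-definite matrix) is
rejected with an error. Group effects multiply planted $\rho$ on matching
role pairs and bands; the packaged conditions reduce impaired-group coupling
by a factor 0.4 on frontal beta edges and posterior-cingulate ripple and
fast-ripple edges, with planted $\rho = 0.6$ and a truncated-Gaussian
between-subject jitter of SD 0.05 for realistic inter-subject variability.
Spike transients are biphasic (one sine cycle under a Hann window, 60 ms)
at Poisson times; 7 pT events double as artifacts for the 6 pT rule.

The generator deliberately does **not** emulate 1/f spectra, head geometry,
field spread/source leakage, sensor noise covariance, or non-Gaussian
amplitude dynamics. Passing recovery tests therefore demonstrates that the
pipeline's statistics behave correctly under its own assumptions -- not that
the published anatomical findings would replicate on real recordings.

## Statistics layer

Group comparisons use classical one-way ANOVA (with Kolmogorov--Smirnov and
Levene checks available as gates), Bonferroni correction with family sizes
from `correction_count()` (3 groups x 7 bands = 21 for connectivity;
x 4 parameters = 84 for graph metrics), and post-hoc pairwise pooled
t-tests Bonferroni-corrected within each three-comparison family (the
post-hoc method is unstated in the source; pairwise t-tests are the
conservative default). The clinical two-group comparison uses the pooled
Student form by default (Welch available). ROC analysis computes AUC by the
Mann--Whitney pair-counting identity, orients the predictor so AUC >= 0.5,
and reports sensitivity/specificity/accuracy at the Youden-optimal cutoff
(the operating-point rule is likewise unstated in the source). Logistic
fits use ML via `glm`; under complete separation a small ridge penalty
(lambda = 0.01) is applied by IRLS with a warning and the Wald p is
reported as missing.

The "distribution of the main functional connections" contingency analysis
(Fisher/chi-square) is not implemented: the counts entering that table are
not defined precisely enough to reproduce.

## Validation problem sizes

The test suite and the acceptance script run at reduced scale chosen to
keep the full validation under a few minutes while preserving the
statistical structure: threshold calibration uses 30 uncoupled nodes in the
gamma band at 200 Hz (3480 pairs); planted-correlation recovery uses a
single alpha edge at 100 Hz over 50 seeds; and the end-to-end group-effect
study uses a beta-band network of 13 nodes -- an 8-node frontal clique
carrying the 0.4 coupling reduction, a 4-node unaffected anchor clique
(which also pins the clustering max-weight normalization), and one
uncoupled node -- at 1000 Hz so the analysis window holds K = 60 000
samples, with n = 17/18/18 subjects per group as in the clinical cohort.
The frontal-rich design reflects that detection power for the clustering
coefficient scales with the fraction of effect-carrying nodes; the
whole-brain default configuration (`default_sim_config()`) spreads
structure across all seven bands instead.

Known clinical-table notes: every group mean recomputes exactly from the
packaged 35-row table, but the printed dispersion "2.60 ± 0.58" for the
impaired group's disease course does not (the recomputed sample SD is
1.14; 0.58 coincides with the *other* group's mean course). We treat the
table as authoritative and the printed SD as an erratum; only means are
asserted.

## Worked example

```{r example, eval = FALSE}
cohort <- load_cohort()
summarize_cohort(cohort)
compare_groups_ttest(cohort, "course_months")

cfg <- sim_config(
  n_nodes = 3, fs = 200, duration = 70,
  bands = meg_bands(c("alpha", "beta")),
  planted_edges = tibble::tibble(node_i = 1, node_j = 2, band = "alpha", rho = 0.6),
  rho_jitter_sd = 0
)
rec <- generate_recording(cfg, seed = 5)
seg <- select_clean_segment(rec, flags = NULL, length_s = 60)
net <- threshold_network(pairwise_correlation(segment_bandpass(seg, "alpha")))
graph_metrics(net)

# full pipeline on the packaged demo configuration
report <- run_all(demo_config())
```

## Limitations

* The pipeline starts at virtual-sensor waveforms; source localization
  (beamforming), MRI co-registration, and raw CTF parsing are out of scope.
* ECG/EOG projector removal is replaced by the amplitude rule; visual spike
  marking by the robust-z surrogate.
* The $L = 0$ unreachable convention and the raw-$K$ threshold are
  faithful to the published method but statistically awkward; both have
  documented, optional alternatives.
* Synthetic validation bounds what passing tests mean (see above).
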