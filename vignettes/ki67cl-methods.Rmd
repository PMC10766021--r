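---
title: "Methods: spatial Ki67 colocalization scoring and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial Ki67 colocalization scoring and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ki67cl)
```

## The marker

Conventional Ki67 scoring reduces a slide to the fraction of Ki67-positive
tumor cells. The Ki67CL score instead asks *where* the positive cells sit:
are they segregated into proliferative hot spots, or finely intermixed with
non-proliferating tumor cells? The score is built in two stages.

**Spatial clustering.** Tumor cells (classes `TUMOR_POS`, `TUMOR_NEG`;
nontumor cells are discarded first) are grouped by agglomerative clustering
with the Euclidean metric and unweighted average linkage (UPGMA), merging
while the smallest between-cluster average distance is strictly below 300
pixels at ×40. Because average-linkage is quadratic in memory, a uniform
random subsample of at most 10,000 tumor cells is clustered directly and
every remaining cell is attached to the cluster of its nearest clustered
cell (exact ties to the lowest cluster id). The subsample draw is governed
by an explicit seed recorded in the output, so runs are bit-reproducible;
when a slide has at most 10,000 tumor cells the result is seed-independent.

**Colocalization.** Each cluster *i* with Ki67-positive fraction
$p_i^+$ contributes its binary Shannon entropy (in bits),
$H(p_i^+) = -[p_i^+ \log_2 p_i^+ + (1-p_i^+)\log_2(1-p_i^+)]$ with
$0\log_2 0 = 0$, and the slide score is the unweighted mean over the $C$
clusters. Equal weighting — rather than size-weighting — follows the score's
definition as written; a large pure nest and a small pure nest are equally
"uncolocalized". Consequences worth knowing: singleton clusters contribute
entropy 0, and the score is invariant under swapping the two class labels.
The score is exactly 0 when every cluster is single-class and exactly 1 when
every cluster is exactly balanced, independent of cluster sizes.

The **AutoKi67 ratio** is the companion conventional marker: Ki67-positive
tumor cells over all tumor cells. When region annotations are available it
is always computed on the invasive tumor region (tumor polygons minus DCIS),
as conventional scoring prescribes, whatever region setting the Ki67CL score
itself uses.

## Regions and the DCIS settings

Region annotations are GeoJSON polygons labelled `TUMOR`, `DCIS` or
`NORMAL` in the slide's pixel frame. Two scoring settings are first-class:
`WITH_DCIS` (cells inside tumor **or** DCIS polygons — the whole-slide view)
and `WITHOUT_DCIS` (inside tumor, outside every DCIS polygon — the invasive
tumor region). Point-in-polygon membership uses the even-odd fill rule, with
boundary points counted inside; both choices are for determinism across
implementations, and the boundary convention makes filtering monotone (a
cell on a shared edge never silently disappears).

## The survival protocol

Validation of a slide-level marker follows a fixed recipe:

- **Stratification** at a marker cutoff into low/high groups, compared with
  the Kaplan–Meier estimator and the two-group log-rank test
  (`survival::survfit` / `survival::survdiff` behind the package surface).
- **Cutoff selection** by grid search minimizing the log-rank p-value.
  Candidates default to the 10%–90% deciles of the training marker
  distribution, with each group required to hold at least 10% of patients;
  ties go to the smaller cutoff. The grid and constraint are this package's
  explicit choices — published operating points (for example a Ki67CL cutoff
  of 0.375) are protocol *outputs* on a specific cohort, not constants of
  the method, which is why the fixed-cutoff mode accepts any value.
- **Cross-validation** with 3 event-stratified, seeded folds: the cutoff is
  chosen on each training part, the held-out part supplies a log-rank p and
  the Harrell C-index of the continuous marker. Folds are combined as
  combined p = min(1, 2 × median fold p) — a deliberately conservative
  aggregate — and combined C = mean ± SD; the cutoff reported to users is
  the median of the fold cutoffs (the aggregation is unstated in the
  protocol's source, and the median is robust with three folds).
- **Cox regression** (Efron tie handling) for univariate and multivariate
  hazard ratios with Wald 95% CIs. Constant covariates are dropped with
  HR = 1 by convention; separation or non-convergence raises a named error
  rather than returning an unstable fit.
- The C-index is computed on the continuous marker with higher values
  treated as higher risk, since it is meant as a rank correlation between
  score and survival; a binarized-group variant is available by passing the
  group indicator as the marker.

## Detection post-processing

The deterministic halo around a density-map cell detector is included
because the matching rules define how detection quality is measured:

- dot annotations are rasterized by summing a truncated, *peak-normalized*
  Gaussian (max 1, not unit mass) per dot, so the regression target lives on
  the same `[0, 1]` scale as a probability map; the default σ = 3 px is a
  package choice, kept well below half the 15-px merge radius so adjacent
  nuclei stay separable;
- per-channel local maxima are pixels ≥ the probability threshold (default
  0.5) that dominate a Euclidean neighborhood (default radius 15 px);
  plateaus elect the lowest-row, lowest-column pixel;
- across channels, detections strictly closer than 15 px are reduced to the
  highest-probability one ("strictly" is the package's reading of the merge
  rule; ties break by channel order, then coordinates);
- predictions are matched to ground-truth dots one-to-one within 20 px by
  optimal bipartite assignment (maximum pairs, then minimum total distance)
  rather than greedily, making precision/recall/F1 deterministic; kappa and
  accuracy are computed over matched pairs' class labels, and the Spearman
  agreement over per-patch, per-class count vectors — the per-cell versus
  per-patch choice for each metric is documented here rather than claimed to
  match any particular published computation.

## Synthetic data: what it does and does not emulate

`simulate_slide()` scatters tumor cells in Gaussian blobs around jittered
grid centers. The `mixing` parameter interpolates colocalization: each blob
is single-class with probability 1 − mixing (positive with probability
`positivity`), otherwise its cells draw classes independently. This keeps
the expected overall positivity fixed while sweeping the expected Ki67CL
from 0 (segregated) toward the positivity's entropy (well mixed), and it is
monotone by construction — which is exactly what the monotonicity test
checks. Defaults (8 blobs of 60 cells, σ = 40 px, spacing 1500 px) make
blobs compact relative to the 300-px threshold and mutually far beyond it,
so blobs and clusters coincide; cell counts per blob are in the range of a
small tumor nest at ×40. `simulate_cohort()` draws exponential event times
with hazard `baseline × HR^{1(score > threshold)}`, independent exponential
censoring and an administrative cap — a plain proportional-hazards world.

What the generators do *not* emulate: tissue texture, irregular tumor-nest
geometry, spatially varying cell density, classifier noise correlated with
morphology, non-proportional hazards, or informative censoring. Passing
tests therefore demonstrate that the pipeline computes what it claims under
controlled conditions, not that the marker is prognostic on real cohorts —
that question needs real slides and outcomes.

Test and simulation sizes (hundreds of cells per slide, cohorts of 600,
50-seed Monte-Carlo sweeps) were chosen so the entire suite exercises every
claim at desk scale while keeping per-test noise far below the margins being
asserted.

## Numerical and design notes

- Coordinates are 0-based pixels at ×40 throughout; no physical-unit
  conversion is attempted, since every threshold in the protocol is stated
  in pixels.
- The agglomeration threshold is strict (`merge while distance < 300`); the
  boundary case of two points exactly 300 px apart yields two clusters and
  is pinned by a test.
- Cluster ids are reported 1..C (R convention) and are contiguous with no
  empty clusters.
- The log-rank p-value uses the 1-df chi-square upper tail; a pooled sample
  with zero events is defined as statistic 0, p = 1.
- `min(1, 2 × median)` can never fall below the median fold p and never
  exceeds 1; both bounds are property-tested.
- Errors are classed conditions (`ki67cl_error_*`) — unscorable slides,
  unknown labels, unparseable coordinates, infeasible cutoffs and
  event-free folds are all distinguishable programmatically.

## Known limitations

- Average-linkage clustering of the full 10,000-cell subsample builds an
  O(n²) distance matrix (~400 MB at the cap); the cap exists precisely to
  bound this, but very dense slides rely on the nearest-neighbor
  back-assignment being a good proxy for full clustering.
- Only two-class (Ki67±) diversity is implemented; multi-class indices and
  hot-spot detection are out of scope.
- No time-dependent covariates, competing risks, or proportionality
  diagnostics in the Cox layer.
- The detector itself (network, weights, inference) is out of scope: the
  package starts from probability maps or classified centroids.
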