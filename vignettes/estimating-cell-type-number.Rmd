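---
title: "Estimating the number of cell types in scCAS data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the number of cell types in scCAS data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Single-cell chromatin accessibility sequencing (scCAS, most commonly
scATAC-seq) produces a peak-by-cell count matrix $X \in \mathbb{R}^{p
\times n}$ that is extremely sparse (often 1–5% nonzero) and
near-binary. Almost every analysis of such data begins by clustering
cells into putative cell types, yet the clustering tools practitioners
use — K-means, Louvain, Leiden — either require the number of clusters
$k$ or hide it behind a resolution parameter chosen by eye. cask
estimates $k$ itself, by an ensemble of three classical model-selection
criteria evaluated over the standard scCAS embedding workflow.

## The three criteria and the ensemble

All three estimators start from TF-IDF weighting of the counts (cells
play documents, peaks play terms) followed by PCA. Two TF-IDF variants
are used, matching the two weighting styles in widespread scCAS use:

* **V1**: $x_{ij}^{(1)} = \mathrm{tf}_{ij}\,\log(1 + n/\mathrm{df}_i)$,
* **V2**: $x_{ij}^{(2)} = \log\!\big(1 + \mathrm{tf}_{ij}\cdot
  (n/\mathrm{df}_i)\cdot 10^4\big)$,

where $\mathrm{tf}_{ij}$ is the count normalized by the cell's total and
$\mathrm{df}_i$ the number of cells in which peak $i$ is detected. Both
variants preserve the sparsity pattern; both are exposed behind a
variant switch (`tfidf()`) so alternative weightings can be swapped in
without touching the estimators.

**WSS elbow** (on V1). K-means partitions are fitted for every candidate
$k$ and scored by the within-cluster sum-of-squares
$\mathrm{WSS} = \sum_i \min_{\mu_j} \lVert x_i - \mu_j\rVert^2$. WSS
decreases monotonically in $k$, so the estimator takes the knee (maximum
curvature) of the $k$-versus-WSS curve, detected by the normalized
chord-difference construction (Kneedle): rescale both axes to $[0,1]$,
flip the decreasing curve to increasing-concave form, and take the $k$
maximizing the gap between curve and chord. We use no smoothing — the
curves here are short and monotone — and break ties (within $10^{-9}$,
which also absorbs floating-point noise under affine rescaling of the
score axis) toward smaller $k$. An exactly linear curve has no knee; the
estimator then falls back to minimizing $\mathrm{WSS}\cdot k$ and flags
the report.

**Davies–Bouldin minimum** (on V2). The same K-means sweep scored by
$\frac1k\sum_i \max_{j\ne i}(s_i+s_j)/d_{ij}$, with $s_i$ the mean
distance of cluster $i$'s cells to their centroid and $d_{ij}$ the
centroid separation; the minimizing $k$ is taken. Coincident centroids
give that pair an infinite ratio rather than an error, so the argmin
over the remaining candidates still functions.

**Summed Louvain + Leiden silhouette maximum** (on V2). A kNN graph of
cells is built in embedding space; for each candidate $k$, partitions of
size $k$ are sought under both Louvain and Leiden, each partition is
scored by the mean silhouette $\overline{(b-a)/\max(a,b)}$, and the
candidate's score is the sum of the two means (range $[-2, 2]$). The
maximizing $k$ is taken. Silhouette distances are Euclidean in the PCA
embedding — the only metric space in the pipeline, and the space where
$a$ and $b$ are defined for the other criteria too. Cells in singleton
clusters contribute 0, the standard convention.

The reported estimate is the arithmetic mean of the three per-criterion
estimates, rounded to the nearest integer with halves away from zero
(an integer must be reported; the choice of rounding is ours).

## The weighted-bias resolution search

Louvain and Leiden take a resolution $r$, not a cluster count. Plain
practice is to binary-search $r$ until the desired count appears. cask
keeps a bracket $[r_\mathrm{lo}, r_\mathrm{hi}]$ with observed counts
$k_\mathrm{lo} \le k^\ast \le k_\mathrm{hi}$ and proposes

$$r_\mathrm{next} = r_\mathrm{lo} + (r_\mathrm{hi} - r_\mathrm{lo})
\times \frac{k^\ast - k_\mathrm{lo}}{k_\mathrm{hi} - k_\mathrm{lo}},$$

interpolating proportionally to where the target sits between the
observed counts, then shrinks the bracket exactly as binary search
would. We read the update as anchored at the *current* bracket's lower
bound: that is the only reading that both uses the proportional rule and
guarantees termination (an update anchored at the most recent evaluation
point, read literally, could only ever increase $r$).

Two standard safeguards temper the interpolation, which otherwise
inherits the stagnation failure of regula falsi on the plateaus of the
count-versus-resolution response: proposals are kept at least 5% of the
bracket width away from either edge, and an interpolation step that does
not change the observed count at its end of the bracket is followed by a
midpoint step. The default bracket is $[0.1, 3.0]$ with tolerance
$10^{-3}$ and at most 20 proposals — standard Louvain/Leiden resolutions
sit comfortably inside. When a count cannot be achieved exactly (small
graphs quantize coarsely; a graph with $c$ connected components never
yields fewer than $c$ clusters at any resolution), the search returns
the evaluated partition closest in count and flags it.

Within the silhouette estimator the searches for successive candidate
$k$ share an evaluation cache per method, so the bracket endpoints are
clustered once per data set rather than once per candidate; search
semantics are unchanged, since the cache only replaces re-clustering at
an identical resolution with an identical seed. `search_eval_battery()`
benchmarks the search cache-free against plain bisection.

One selection subtlety: when small candidate counts are unachievable,
their stand-in partitions duplicate the smallest achievable one and tie
with it exactly in score. Ties are therefore resolved by preferring
candidates the searches achieved exactly, then smaller $k$ — otherwise
the grid's smallest candidate would always shadow the genuine optimum.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `n_components` | 50 | PCA dimensions (clipped to $\min(p,n)-1$); the EpiScanpy/Scanpy workflow default |
| `n_neighbors` | 15 | kNN graph degree before union symmetrization |
| `binarize` | FALSE | clamp counts to presence/absence before TF-IDF |
| `n_init` | 10 | k-means++ restarts per K-means fit, best by WSS |
| `r_min`, `r_max` | 0.1, 3.0 | resolution bracket |
| `r_tol` | $10^{-3}$ | bracket-width stopping tolerance |
| `k_range` | [2, 30] | candidate grid; 30 exceeds the cell-type counts of typical atlases while keeping desk-scale runtime |

PCA centers per-peak means but does not scale to unit variance (TF-IDF
already equalizes feature scales; scaling would amplify rare-peak
noise). Counts are used as-is by default — binarization is offered but
not imposed, since near-binary data makes the two nearly equivalent and
integer counts let both TF-IDF variants see nontrivial term
frequencies. All randomness — the truncated-SVD initialization, k-means++
sampling, community detection — derives deterministically from one
master seed; per-candidate child seeds make each grid point independent
of evaluation order.

## The synthetic generator

`simulate_sccas()` emulates the cluster structure the estimator targets:
each of `k_true` cell types owns a disjoint block of marker peaks,
accessible with probability `p_signal` (default 0.3) in the type's own
cells, against a background rate `p_background` (default 0.02)
elsewhere; accessible entries carry a count of $1 +
\mathrm{Poisson}(\lambda)$ with $\lambda = 1$ (mean count ≈ 2 at open
sites, matching sparse low-count scCAS); dropout zeroes nonzero entries
independently at a configurable rate. Defaults (5 types, 200 cells/type,
2000 peaks, 100 markers/type) give an overall density of about 3.4%,
within the realistic scATAC range. Unequal `cells_per_type` models
imbalance.

What the generator does **not** emulate: batch effects (the estimator
does not model batch variation — correct batches before estimating),
fragment-length and GC biases, overlapping or hierarchically nested
marker programs, and doublets. Passing recovery tests on this generator
therefore certifies the machinery — embedding, criteria, search,
ensemble — under clean cluster structure, not performance on any real
atlas.

## Numerical choices and degenerate inputs

* All-zero peaks and cells are removed to a fixed point before TF-IDF
  (`filter_degenerate()`); the transform's denominators are otherwise
  undefined.
* Point-to-centroid distances are computed by direct differencing, not
  the inner-product expansion, which loses ~7 digits and would break
  agreement with direct-formula oracles at $10^{-10}$.
* Silhouette with $a=b=0$ (duplicated points) scores 0.
* PCA uses a seeded truncated Lanczos SVD, with a dense SVD fallback
  when the requested rank is close to the matrix dimensions (the
  truncated solver is unreliable there); component signs are fixed so
  the largest-magnitude loading is positive.
* K-means restarts that converge with an empty cluster are discarded;
  if all restarts fail, a standard multi-start Hartigan–Wong fit is
  used.
* Ties everywhere — argmin, argmax, knee, closest-achieved count —
  break toward smaller $k$ (parsimony, and it makes selection
  deterministic).

## Problem sizes

The test suite exercises the full pipeline at the generator defaults
(1000 cells × 2000 peaks; ten generator seeds), a scale chosen so the
whole suite runs in minutes on one core; unit tests use smaller
instances (60–240 cells) whose elbows are naturally noisier, which the
tests acknowledge by allowing ±1 on that criterion. The acceptance
script (`scripts/acceptance.R`) re-runs the default-scale analyses from
scratch.

## Known limitations

* The ensemble inherits each criterion's biases: WSS elbows are
  ill-defined on gradient-structured (trajectory) data; silhouette
  favors well-separated convex clusters. On continua the three
  estimates can disagree widely — the report carries all three curves
  precisely so such disagreement is visible.
* Very high dropout (≳90%) disconnects the kNN graph and fragments
  community detection; estimates degrade (typically upward) though the
  pipeline still runs.
* The candidate grid caps at 30 by default; atlases with more cell
  types need a wider `k_range`, at quadratic-in-$n$ silhouette cost.
* `read_h5ad()` reads the standard dense/CSR/CSC `X` layouts of the
  AnnData container; backed/virtual layouts are out of scope.
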