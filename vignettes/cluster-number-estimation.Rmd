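---
title: "Choosing the number of clusters from a dendrogram"
author: "dendrocut"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Choosing the number of clusters from a dendrogram}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dendrocut)
```

## The problem

Hierarchical clustering is the standard exploratory tool when the number of
clusters in a dataset is unknown — gene-expression sample clustering is the
motivating case for this package. Agglomerative clustering, however, does not
stop: it merges until a single cluster remains, and the analyst is left to cut
the dendrogram by eye. Manual cutting is slow, irreproducible, and two
analysts can defensibly disagree. `dendrocut` automates the cut.

All methods here operate on an **agglomerative average-linkage hierarchy
under Euclidean distance**. For $N$ observations this produces $m = N - 1$
merges with heights $d_1 \le d_2 \le \dots \le d_m$ (average linkage is
monotone, so the sequence is non-decreasing). The package stores this as a
`MergeSequence`; `cutToK()` undoes the last $k - 1$ merges, and
`cutAtHeight(h)` applies exactly the merges with $d_i \le h$.

A useful identity used throughout: just before merge $i$ is applied there are
$m + 2 - i$ clusters. Every height-based rule below selects a merge index
$i^*$ and reports $\hat{k} = m + 2 - i^*$.

## The four cutoff rules

**Elbow (acceleration).** The acceleration of height growth at merge $i$ is
the second difference $a_i = d_i - 2 d_{i-1} + d_{i-2}$, $i \in [3, m]$, and
$i^*$ is its argmax. The intuition is the classic elbow: after the true
structure is exhausted, each further merge has to bridge a much larger
distance, and the sharpest *change of slope* marks the transition. Needs
$m \ge 3$; can never return $\hat{k} = 1$ (or $N$).

**Maximum difference.** The same idea one derivative earlier: $i^*$ is the
argmax of the first difference $d_i - d_{i-1}$, $i \in [2, m]$. Equivalently
the dendrogram is cut inside the widest horizontal gap between consecutive
merge heights — the property the test suite checks against a brute-force
enumeration of all cuts. Needs $m \ge 2$; never returns 1, but copes with
singleton clusters (an outlier joining last produces the widest gap just
before its merge).

**Mode.** The merge heights are treated as an empirical distribution of jump
sizes. The most common jump size $\hat{D}$ reflects within-cluster packing,
so it is a *bad* cutoff; the rule cuts at the higher threshold
$t = \hat{D} + \alpha\,\sigma_D$, where $\sigma_D$ is the sample standard
deviation (denominator $n - 1$) of the heights, and reports the cluster count
of `cutAtHeight(t)`. Because the threshold can exceed $d_m$, this rule *can*
return 1 cluster. The mode of a continuous sample is estimated by a histogram
with $\lceil\sqrt{m}\rceil$ equal-width bins over $[\min d, \max d]$, taking
the midpoint of the fullest bin (ties to the lowest bin); when all heights
are equal, $\hat{D}$ is that height and $\sigma_D = 0$.

The threshold form is dimensionally a *height*, not a count; interpreting it
as a dendrogram cutoff is the design choice made here, on the grounds that
jumps are framed as cutoff candidates and a height threshold is the only
reading that is dimensionally consistent. `alpha` defaults to 3; tuning it
would require labelled training data, which defeats a fully automated cutoff,
so the default is deliberately left untuned.

**Gap statistic.** For each $k \le k_{\max}$, cut the hierarchy to $k$
clusters and compute the size-normalised within-cluster dispersion
$$W_k = \sum_{r=1}^{k} \frac{1}{2 n_r} \sum_{i, i' \in C_r} d_{ii'},$$
with the inner sum over ordered pairs of Euclidean distances. The gap
$\mathrm{Gap}(k) = E^*[\log W_k] - \log W_k$ compares the observed dispersion
with its expectation under a null of no cluster structure: $B$ reference
datasets drawn uniformly over the observed range of each feature, each
clustered by exactly the same average-linkage procedure. With
$s_k = \mathrm{sd}^*(\log W_k)\sqrt{1 + 1/B}$, the estimate is the smallest
$k$ with $\mathrm{Gap}(k) \ge \mathrm{Gap}(k+1) - s_{k+1}$. This is the one
rule that can detect a single cluster, at a computational price: each call
costs $B + 1$ full linkage computations.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 3 | mode-rule threshold multiplier on $\sigma_D$ (unitless) |
| `kMax` | 10 | largest $k$ profiled by the gap statistic |
| `nReference` (`B`) | 50 | reference datasets per gap profile |
| `M` | $\lfloor N/2 \rfloor$ | subsample size for mixing |
| `L` | 100 | number of mixing replicates |

$B = 50$ balances the Monte-Carlo error of $E^*[\log W_k]$ (which enters
$s_k$ as $\sqrt{1 + 1/B}$) against the $B$-fold linkage cost; the gap
reference count is reported in every `GapProfile` so results are
interpretable. `kMax = 10` comfortably covers the simulated scenarios (true
$k \le 4$) and typical expression-sample panels; `gapEstimate()` flags (in
`diagnostics()$noElbow`) the case where the selection rule never fires below
`kMax`, rather than failing, and returns `kMax`.

## Resampling consensus

`mixedEstimate()` draws $L$ subsamples of $M$ rows *without replacement*,
runs the base estimator on each, and reports the **mode** of the $L$
replicate estimates; `loocvEstimate()` is the limiting case in which each
observation is left out once ($L = N$, $M = N - 1$). Subsampling averages
out the influence of individual outlying points on the height sequence.
Replicates on which the base estimator fails (too few merges) are skipped
and counted; more than 50% failures aborts. Ties in the replicate mode break
to the smallest count — the conservative choice — and all base-estimator
parameters are inherited unchanged by every replicate.

## The synthetic-data generator

`generateClusters()` reproduces the benchmark scenario used throughout the
package's evaluation: up to four spherical Gaussian clusters of 100 points
each in 2-D, centred on the corners of a square of side $m = 6$ — i.e.
$(\pm 3, \pm 3)$, taken in the fixed order $(-3,-3)$, $(3,3)$, $(-3,3)$,
$(3,-3)$ — with per-cluster covariance $c_r I_2$ (unit scales by default;
$c = (1, 1, 2, 0.5)$ in the heterogeneous setting). With unit covariance and
$m = 6$, neighbouring clusters are separated by about six within-cluster
standard deviations: visibly distinct, with occasional boundary points.

What this emulates — and what it does not: the generator produces spherical,
equally sized, well-conditioned clusters in two dimensions. Real expression
matrices are high-dimensional, correlated, and heavy-tailed, with cluster
sizes that can be wildly unbalanced. Passing the simulation benchmarks
therefore demonstrates correctness of the machinery and behaviour under the
stated conditions, not performance on arbitrary real data; the 26-sample
expression case study (`expressionSetMatrix()`) is the reality check
included here.

`runExperiment()` repeats generation + estimation `nRuns` times and reports,
per method, the mean estimate, the **success rate** $S_X$ (fraction of runs
with $\hat{k} = k$), and the **error size** $E_X$ — the mean of
$|k - \hat{k}|$ over the *incorrect* runs only, defined as 0 when no run is
wrong so that $S_X = 1 \iff E_X = 0$. Methods are paired: within a run all
methods see the same dataset, and under resampling the height-based methods
share the same subsample draws.

## Numerical and design choices

- **Argmax ties** in the elbow and maximum-difference rules break to the
  smallest merge index (the larger $\hat{k}$); replicate-mode ties break to
  the smallest count. Ties are measure-zero on continuous data, so the rule
  matters only for determinism and degenerate inputs.
- **Second difference sign.** The acceleration is implemented as the
  standard second difference $d_i - 2d_{i-1} + d_{i-2}$ (the form whose
  value is zero on a linear height sequence, as an acceleration must be).
- **Monotonicity.** Merge heights are validated as non-decreasing;
  inversions below $10^{-9}$ (floating-point noise) are clamped, larger ones
  (non-monotone linkages) are an error.
- **Merge ties** inside the linkage computation follow the deterministic
  tie-breaking of the underlying `hclust` implementation; simulated data has
  no ties almost surely.
- **No standardisation** is applied to the input matrix: the estimators are
  deliberately scale-bearing, matching the benchmark protocol, and all
  height-based estimators are exactly invariant to rigid translation.
- **Seeding.** One master seed spawns independent per-run sub-seeds
  (`sample.int` on a locally seeded stream, restored afterwards), so every
  result in the package is bit-reproducible and seeded components never
  perturb the caller's RNG state.
- **Problem sizes.** The reproduction suite runs the benchmark protocol at
  its native size (200 Monte-Carlo runs, 100 points per cluster) for the
  plain and mixing estimators, and at 50 runs for the leave-one-out
  consensus, whose cost per run is $N$ full linkage computations — at 50
  runs the binomial standard error of a success rate near 1 is still below
  0.03.

## Known limitations

- The elbow and maximum-difference rules structurally cannot report a single
  cluster; when $k = 1$ is plausible, consult the gap statistic.
- The mode rule with the default $\alpha = 3$ over-merges aggressively on
  heterogeneous data (its replicate-consensus variant behaves much better);
  treat it as experimental.
- The gap statistic's uniform reference is drawn over the observed
  per-feature ranges; a principal-component-aligned reference box is not
  implemented.
- Half-sample mixing of the gap statistic is supported but costs
  $L \times (B + 1)$ linkage computations per call.
- On very small samples (a few dozen observations) half-sample mixing can
  be unstable — the replicate consensus may flip between adjacent counts;
  the leave-one-out variant is the safer resampling choice there.
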