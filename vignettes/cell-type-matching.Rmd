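---
title: "Graph-based cell type matching with frcellmatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-based cell type matching with frcellmatch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frcellmatch)
```

## The matching problem

Given a query scRNA-seq dataset with cluster labels and a reference atlas
with named cell type clusters, the task is to decide, for every query cell
or cluster, which reference cell type it came from — or that it came from
none of them. `frcellmatch` treats this as a collection of multivariate
two-sample problems: a query group and a reference cluster are "the same
cell type" exactly when their expression distributions in a common
marker-gene space are indistinguishable.

The statistical core is the Friedman–Rafsky (FR) multivariate runs test.
Pool the two samples, build the minimum spanning tree (MST) of their
pairwise distances, and count the runs $R$: the number of maximal
single-sample subtrees, equal to the number of tree edges joining the two
samples plus one. If the samples come from one distribution they
interleave on the tree and $R$ is large; if they are segregated, $R$ is
small. Conditional on the tree, the permutation null has closed-form
moments

$$E[R] = \frac{2mn}{N} + 1,\qquad
\mathrm{Var}[R] = \frac{2mn}{N(N-1)}\left[\frac{2mn-N}{N}
 + \frac{C-N+2}{(N-2)(N-3)}\bigl(N(N-1)-4mn+2\bigr)\right],$$

where $m, n$ are the sample sizes, $N = m+n$, and $C$ is the number of
edge pairs sharing a node. The standardized statistic is
$W = (R - E[R])/\sqrt{\mathrm{Var}[R]}$ and the one-sided p-value is
$\Phi(W)$: only a deficit of runs is evidence against equality. The test
is nonparametric — it assumes only exchangeability under the null — and
needs no estimate of a high-dimensional covariance, which is what makes it
usable on subsamples of 10 cells in a 20–40 dimensional marker space.

## From a two-sample test to cell type matching

`frmatch()` wraps the test in two schemes.

**Cell-to-cluster** (`scheme = "cell2cluster"`): for every pair of a query
cluster $j$ and reference cluster $k$, `subsamp_iter` iterations each draw
`subsamp_size` cells from both sides and run the FR test; every drawn
query cell keeps the *maximum* p-value it has seen against $k$. The output
is a cells × reference-clusters p-value matrix. The max-update rule makes
the scheme robust to heterogeneous query clusters: a cell is credited with
the best-matching subset it was ever drawn with. Cells never drawn against
some reference keep `NA` (distinguished from "always rejected"), with
per-cell draw counts recorded; `auto_iter = TRUE` in `match_params()`
raises the iteration count so every cell is expected to be drawn at least
`target_draws` times when query clusters are large.

**Cluster-to-cluster** (`scheme = "cluster2cluster"`): the pair's p-value
is the *median* over the same kind of iterations — equivalent to giving
all cells of the query cluster the same median p. It treats the query
cluster as a unit and is the conservative choice; `scheme = "two_way"`
additionally requires non-significance in both directions before calling
a pair matched.

Both schemes end the same way: Benjamini–Hochberg correction over the
p-value matrix, then per row the reference cluster with the maximum
adjusted p wins if that maximum reaches `sig_level`; otherwise the row is
`"unassigned"` — the novel-cell-type signal. Note the logic is inverted
relative to ordinary testing: a *large* p-value is a match, and the BH
step (which can only raise p-values) makes unassigned calls harder, not
easier.

The two schemes deliberately measure different functionals — a running
maximum versus a median — so their numeric p-values agree only where both
saturate (clearly wrong pairs, where both sit near 0). Their significance
calls, not their p-values, are what coincide on well-separated data.

### Parameters and defaults

* `subsamp_iter = 2000`, `subsamp_size = 10` — iterations and cells per
  side per iteration. Ten cells per side keeps the test usable for the
  smallest real clusters (around a dozen cells); 2000 iterations gives
  each cell of a 200-cell cluster about 100 draws per reference cluster.
  Clusters smaller than `subsamp_size` shrink the draw to their size (with
  a warning); clusters under 3 cells are skipped.
* `sig_level = 0.1` — the threshold on the maximum adjusted p below which
  a query unit is unassigned.
* `p_adj_method = "BH"`, with `bh_scope = "global"` (jointly over the
  flattened matrix) by default; `"row"` is available, and the choice is
  recorded in the output metadata.
* `metric = "euclidean"` or `"cosine"`. The cosine distance
  $1 - \cos\theta$ is invariant to positive rescaling of any cell, which
  makes it the recommended choice when the two datasets have systematically
  different dynamic ranges (different platforms); see the simulation
  section.
* `seed`, `n_workers` — every (query, reference) cluster pair derives a
  deterministic sub-seed from `seed` and the pair index, so results are
  bit-identical regardless of worker count or scheduling.

## Normalization

Cross-platform matching needs the two datasets on a comparable scale.
Starting from log2(CPM + 1) expression (`cpm_log2()`), normalization has
two stages:

1. **Gene-wise min–max rescaling** (`minmax_rescale()`): each gene row is
   divided by its maximum over all cells, aligning dynamic ranges to
   $[0,1]$. The formula divides by the maximum only — expression is
   non-negative with minimum 0 in practice — and all-zero rows stay zero
   ($0/0$ defined as 0, since dropout-heavy panels contain such rows).
2. **Cluster-summary weighting** (`weight_by_cluster_summary()`): within
   each cluster, every gene row of the rescaled submatrix is multiplied by
   that row's within-cluster mean (or median), and the submatrix is then
   divided by its own maximum so its range tops out at 1 again. Because
   good marker panels are near-binary, the weights are close to 0 or 1:
   the step zeroes out the low-level off-target background expression that
   deep plate-based (SMART-seq-like) profiles show, while leaving true
   signal intact. With `norm_by = "median"` a gene expressed in fewer than
   half of a cluster's cells is set exactly to zero within that cluster.

Weighting is applied only to the side(s) whose platform tag appears in
`norm_config(apply_weighting_to = ...)` — by default SMART-seq-tagged
data, the high-sensitivity platform whose background the step exists to
remove. For same-platform pairs the appropriate configuration is
`norm_by = "none"` (min–max only). A caution that follows from the
formulas: the weights are estimated from the cluster's own cells and enter
multiplicatively (the cluster mean of a weighted row is roughly the square
of the raw mean), so with very small clusters (a few tens of cells) the
finite-sample noise of the weights becomes a real distributional
difference between two otherwise identical datasets, and the FR test is
sensitive enough to see it. Weighting earns its keep on cross-platform
pairs; it should not be switched on casually for tiny same-platform
clusters.

## The synthetic validation suite

The package validates itself on two generators rather than on any
particular public atlas.

**MVN scenarios** (`mvn_scenario()`, `simulate_mvn_two_sample()`): both
samples are $p$-dimensional multivariate normal ($p = 40$ by default, with
equicorrelated covariance, $\rho = 0.2$). Alternatives shift the location
by `delta` per coordinate and/or scale the covariance by `sigma_scale`;
defaults `delta = 1`, `sigma_scale = 1.5` sit in the moderate-power
regime of the location grid $\{0.25, 0.5, 1\}$ and shape grid
$\{1.5, 2\}$ that the study design exposes. A separate knob, `scale_y`,
multiplies the second sample by a positive constant (default 1; the
scale-mismatch studies use 5) — the platform dynamic-range distortion. It
is a nuisance, not a signal, so the generator keeps it orthogonal to the
alternative: the distributional change is applied to the first sample,
the platform factor to the second, and the factor is present under the
null as well. `run_power_study()` builds ROC curves from paired null and
alternative p-value samples and computes the AUC as the Mann–Whitney
rank statistic.

Two behaviours of the euclidean test under pure scale inflation are worth
knowing (both are computed by the calibration/power machinery, not just
asserted): at small samples ($m=n=20$, $p=40$) the one-sided test does
*not* reject a 5× inflated but otherwise identical sample — in high
dimension the compact sample's points are closer to the inflated sample's
points than those are to each other, so the MST interleaves and the runs
count stays near its null mean — while at $m=n=100$ the test's size
inflates badly. The cosine metric is simply unaffected by the factor,
which is the practical argument for `metric = "cosine"` across platforms.

**Synthetic atlases** (`synthetic_atlas()`,
`simulate_cell_atlas_pair()`): a multi-cluster atlas with disjoint blocks
of near-binary markers. Counts are negative-binomial on/off draws
(on-target mean 50, off-target 0.2, dispersion 2 for the plate-like
"bimodal" style; 8 / 0.05 with 50% dropout for the droplet-like
"rightskew" style), plus housekeeping-style noise genes, then converted to
log2(CPM + 1). Defaults are 5 clusters × 200 cells × 4 markers each.
Query and reference are independent draws; modifications delete a query
cluster or merge two query clusters under one label (the
under-partitioning scenario). `loocv_unassigned_eval()` drops each
reference cluster in turn and scores the resulting unassigned calls as a
binary classifier (accuracy and type-I error per left-out cluster).

What the generator does **not** emulate: doublets and ambient RNA,
batch effects within a dataset, continuous differentiation trajectories
(clusters are exchangeable draws, not a manifold), overlapping or nested
marker programs, and realistic library-size variation. Passing the
synthetic suite therefore shows that the machinery is correct and
calibrated under its own assumptions — clean, well-separated,
marker-identifiable types — not that any particular pair of real atlases
will match cleanly. The under-partition scenario also shows genuine
sampling noise: because all cells of a merged cluster share the same
iteration draws, the observed split between the two true types fluctuates
widely around 50:50 from seed to seed.

## Numerical choices

* **Pseudocount.** `cpm_log2()` computes $\log_2(1 + \mathrm{CPM})$ so
  zeros stay at exactly 0 and all values are finite; a bare
  $\log_2(\mathrm{CPM})$ (pseudocount 0, negatives floored at 0) is
  available via the `pseudocount` argument.
* **Normal vs permutation p.** The default p-value is the one-sided
  normal approximation $\Phi(W)$; `permutation_pvalue()` implements the
  estimator $(1 + \#\{R_{perm} \le R_{obs}\})/(1 + n_{perm})$ as the
  exact-null reference. Because $R$ is a lattice statistic, the two differ
  systematically by about half the point mass at the observed value:
  $\Phi(W)$ behaves like a mid-p, the tie-inclusive permutation estimator
  keeps the full tie mass. At pooled size $N = 20$ central point masses
  reach $\approx 0.19$, so mid-range disagreements of $\approx 0.09$ are
  expected and correct; the two converge as $N$ grows. The mid-p
  behaviour is also why the normal approximation is nearly unbiased in
  size at $\alpha = 0.05$ while the discrete permutation test is
  conservative there. For matching, where p-values are compared to a 0.1
  threshold after max/median aggregation, the difference is immaterial.
* **Degenerate trees.** $\mathrm{Var}[R] = 0$ occurs exactly for
  star-shaped trees (e.g. all points identical). Those iterations fall
  back to the permutation p-value automatically.
* **Ties and determinism.** Prim's algorithm on the dense distance matrix
  breaks ties by smallest vertex index (and smallest parent index among
  equal-weight edges), so duplicate points yield a reproducible tree.
  Assignment ties (two references with the same maximum adjusted p) go to
  the first reference in column order and are flagged in the output.
* **Zero vectors under cosine.** A zero vector has no direction; its
  cosine distance to any other point is defined as 1 (neutral) with a
  warning, never NaN.
* **Problem sizes.** The shipped validation runs at desk scale, chosen so
  the whole suite completes in about a minute of compute: calibration at
  2000 null replicates ($m=n=20$) and 1000 replicates ($m=n=100$), power
  and AUC at 500 replicates per scenario, atlas studies at 5 × 200 cells
  with the default 2000 × 10 subsampling, and permutation oracles at
  20000–200000 permutations.

## Limitations

* Matching quality is bounded by the marker panel: markers that do not
  separate two types make them indistinguishable to the test, and the
  package deliberately treats marker selection as an input rather than
  re-implementing it.
* The cell-to-cluster maximum is an extreme-value statistic; its absolute
  magnitude depends on the number of draws a cell receives and should be
  read as a calibrated score only through the significance threshold, not
  as a probability of identity.
* The iterative engine scales with (query clusters) × (reference
  clusters) × `subsamp_iter`; very large atlases are handled by
  parallelism (`n_workers`) rather than by algorithmic shortcuts.
* Distributional equivalence is judged in the normalized marker space;
  systematic distortions that survive normalization (e.g. strongly
  nonlinear platform effects) will register as mismatches.
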