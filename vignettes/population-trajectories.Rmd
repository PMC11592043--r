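---
title: "Population-level trajectory inference: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-level trajectory inference: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poptraj)
```

This vignette is the package's own account of the science it implements:
the statistical model at each stage, the assumptions it rests on, the
parameters that matter and their defaults, what the synthetic-data
generator does and does not emulate, and the design choices made where
the method left genuine freedom.

## The model, stage by stage

### Inputs and preprocessing

The pipeline consumes three aligned cells × genes matrices: spliced
counts, unspliced counts, and RNA velocity. Velocity is strictly an
input: it must be estimated upstream (velocyto- or scVelo-style tools)
and is assumed to be on the working expression scale already. For that
reason `preprocess()` never rescales or log-transforms the velocity
layer; it only subsets genes consistently across all three layers.

Preprocessing follows the usual velocity-workflow protocol: genes with
total spliced signal below `min_counts` (default 20) are dropped, each
cell is library-size normalized to the median total, `log1p` is applied
to the count layers (default on), and optionally only the `n_top_genes`
(default 2000) highest-dispersion genes are kept. Cells are never
reordered or removed, so row indices remain stable through the whole
pipeline. Clustering operates on the resulting expression matrix
directly — not on a PCA embedding — because the mixture model is meant to
describe cell distribution in the original data space. Whether clustering
should instead use neighbour-smoothed moments is left as an explicit
choice: the default is the raw normalized expression, and the flags on
`preprocess()` let a user supply any variant.

### Gaussian mixture clustering

Cells are modelled as draws from $P(x) = \sum_{k=1}^K \omega_k\,
N(x \mid \mu_k, \mathrm{diag}(\sigma^2_k))$. Two covariance structures
are supported, `diagonal` (default) and `spherical`; a full covariance is
singular whenever genes outnumber cells, which is the typical regime, so
it is deliberately not offered. EM alternates a log-space E-step
(responsibilities via log-sum-exp, so no cell can underflow) with an
M-step of responsibility-weighted moments. Numerical guards:

* a variance floor of $10^{-6}$ is added to every variance entry, so
  duplicated cells cannot collapse a component to a point mass;
* a component whose total responsibility falls below $10^{-12}$ is
  re-seeded at the cell worst explained by the current model, keeping K
  fixed;
* convergence is declared when the relative change in total
  log-likelihood drops below `tol` ($10^{-6}$ by default, `max_iter`
  300). The likelihood trace is recorded and is non-decreasing up to
  $10^{-8}$ slack — a property the test suite asserts on seeded fixtures.

Initialization is k-means++ center selection under the caller's seed,
global per-gene variances, uniform weights. K may be fixed (for
instance from known cell-type counts) or chosen by BIC over `K_range`
(default 2–8) with $p = K - 1 + 2Kn$ free parameters. On smooth
trajectory data BIC tends toward the upper end of the range; that is
harmless here because clusters are only an intermediate level — the
working units are the populations refined from them.

### Cell populations

The method's defining move is to work at the level of small sub-clusters
("cell populations", analogous to metacells) so that velocity smoothing
and graph construction see units large enough to average noise but small
enough to retain cell-specific signal. The refinement map from clusters to
populations is genuinely open design space: the only hard requirements
are that populations partition the cells and respect cluster boundaries.
We chose seeded within-cluster k-means with
$s_k = \max(1, \mathrm{round}(|C_k| / \texttt{target\_pop\_size}))$
populations per cluster: it is deterministic given the seed, fast, and
gives direct control over the granularity through one parameter.
`target_pop_size` defaults to 20 cells; population ids are assigned by
parent cluster and then by smallest member index, so runs are exactly
reproducible. Degenerate geometry (fewer distinct points than requested
populations) falls back to balanced index slicing.

### Velocity smoothing by Gaussian-process regression

Cell-level velocities are noisy; populations need a consensus direction.
A GP prior with RBF kernel
$\Sigma(x_i, x_j) = \sigma_{RBF}^2 \exp(-\lVert x_i - x_j \rVert^2 / 2\ell^2)$
is placed on the map from expression to velocity, and the posterior mean
at the population centroid,
$\mu^* = \mu_V + \Sigma_*(\Sigma + \sigma^2 I)^{-1}(V - \mu_V)$,
is the population's velocity. Velocity is an n-dimensional target; the
outputs are treated as independent GPs sharing one kernel and one noise
level, so a single Cholesky factorization serves all genes. Targets are
centered per gene (the prior mean is the per-gene training mean), which
makes far-from-data predictions revert to the mean velocity instead of
zero.

Hyperparameters $\xi = (\sigma, \ell, \sigma_{RBF})$ maximize the summed
log marginal likelihood by L-BFGS-B in log-parameter space with 3
seeded restarts. Bounds are data-scaled: $\ell$ within
$[10^{-2}, 10^3] \times$ the median pairwise training distance, both
scales within $[10^{-4}, 10^3] \times$ the target standard deviation.
Cholesky failures escalate jitter from $10^{-8}$ to $10^{-4}$ before
giving up. By default one GP is fitted per cluster on that cluster's
cells ("per-cluster" mode): this keeps the cost at
$O(\sum_k m_k^3)$ instead of $O(m^3)$ and respects cluster locality. A
"global" mode (one GP on all cells, subsampled to `max_train = 1000`
points) is available for small datasets. Clusters with fewer than two
cells fall back to the mean member velocity.

### The directed population graph

Each population is linked to its `k = 10` nearest populations by centroid
distance. The edge s→q combines two dissimilarities:

* alignment: $l_\alpha = 1 - \cos\alpha$ with
  $\cos\alpha = (X^*_q - X^*_s)^\top v_s / (\lVert X^*_q - X^*_s\rVert\,
  \lVert v_s\rVert)$. The displacement is taken *toward the edge target*:
  an edge pointing exactly where the source's velocity points has
  $l_\alpha = 0$ (best), an edge pointing against it has $l_\alpha = 2$
  (worst). This orientation is the only one under which trajectories
  follow the velocity field, and the graph invariant tests pin it down;
* distance: $l_d = d_{s,q} / d_{\max}$, with $d_{\max}$ the largest
  retained candidate distance over the whole graph (a global
  normalization, so $l_d$ is comparable across nodes).

The weight is the nonlinear combination
$e_{s,q} = \lambda^{\,l_\alpha + \beta l_d} / \lambda$ with defaults
$\lambda = 3$, $\beta = 1$: for $\lambda > 1$ it is strictly increasing
in both terms, equals $1/\lambda$ for a perfect zero-length edge, and
penalizes misalignment exponentially rather than additively — an additive
form would not deserve the name "scaling factor" for $\lambda$. After
weighting, edges at more than 90° to the source velocity
($l_\alpha > 1$) are pruned (`prune_backward = TRUE`), which in practice
gives sources in-degree 0 and sinks out-degree 0.

### Trajectories and pseudotime

Floyd–Warshall computes all-pairs shortest paths in $O(G^3)$ for G
populations — trivial at metacell granularity — and, unlike Dijkstra,
tolerates negative edge weights; a negative *cycle* is reported as an
error. Intermediates are scanned in ascending id with strict-improvement
updates, so tie-breaking is deterministic. Candidate trajectories are the
reconstructed shortest paths from sources (in-degree 0, else minimal
in-degree) to sinks (out-degree 0, else the farthest reachable nodes).
Which of the all-pairs paths constitute "the trajectories" is not
uniquely determined by the shortest-path computation itself; we resolve
it greedily: repeatedly take the path covering the most not-yet-covered
populations (ties to the lower mean edge weight), stopping at
`coverage_target = 0.95` of the reachable populations or `max_paths = 20`.
Each population is attributed to the first path that covers it.

Along a path, populations sit at integer times $t_s = 0, 1, 2, \ldots$
by position — not arc length, because the within-population offsets have
expression/velocity units that are used only ordinally. Each member cell
is projected orthogonally onto the velocity line
$W(t) = X^*_s + v_s(t - t_s)$; its offset
$\delta = (x - X^*_s)\cdot v_s / \lVert v_s \rVert^2$ is rescaled within
the population to $(-0.45, +0.45)$ by dividing by the maximum absolute
offset. The 0.45 bound keeps cells of adjacent populations from
interleaving: population-level ordering stays authoritative, offsets only
order cells within a population. Raw times are then min–max normalized to
[0, 1] per path (a single-population path degenerates to 0 by
convention). Cells in populations on no selected path receive `NA`
pseudotime and are reported as such in the per-cell table.

### Evaluation metrics

Against a known ordering, the package reports the tie-corrected Kendall
coefficient with an absolute-value numerator,
$\tau_b = |C - D| / \sqrt{(C + D + T_1)(C + D + T_2)}$, which maps the
usual $[-1, 1]$ range onto $[0, 1]$ — a path traversed in reverse is
still a perfectly recovered ordering — and the Spearman rank correlation.
With several detected paths, each path is scored on its own cells against
the truth restricted to those cells, and the unweighted mean across paths
is reported; weighting by path size or taking the best path would be
equally defensible, and the per-path table is always returned so any
aggregation can be recomputed.

## The synthetic generator

The generator emulates what a branching-process simulator provides,
at desk scale and with full determinism by seed:

* a topology (linear, bifurcating, trifurcating, or a cycle with four
  branches rooted on it, so every path starts on the cycle);
* per-cell ground-truth time, uniform on [0, 1] along each lineage, and a
  branch label;
* per-gene expression programs that are sums of 2–4 logistic terms with
  random centers, widths and directions, plus branch-specific terms whose
  centers sit at least six widths past the branch point (so programs are
  continuous there to within $e^{-6}$ of the term amplitude). Cycle
  segments use smooth periodic bumps, exactly periodic in the cycle
  phase;
* analytic velocity $v = \partial\mu/\partial t$ — the test suite checks
  it against second-order finite differences of the noise-free expression;
* spliced $s = \mu + \varepsilon$ and velocity $v + \varepsilon'$ with
  independent Gaussian noise scaled to `noise_sd` (default 0.05) times
  each gene's signal standard deviation; unspliced
  $u = (v + \gamma_g s)/\beta_g$ clipped at zero, inverting the
  steady-state kinetic relation $v = \beta u - \gamma s$ with per-gene
  rates $\beta_g \sim U(0.5, 2)$, $\gamma_g \sim U(0.2, 1)$.

Defaults are 500 cells and 50 genes. What it does *not* emulate — and
therefore what passing tests cannot show about real data — includes
count-level sampling noise (negative binomial or otherwise, with its
zero inflation and mean–variance coupling), batch effects, doublets,
velocity estimation error structure (real velocities are themselves
model-based estimates with systematic biases), and regulatory-network
dynamics. Passing at `noise_sd = 0.05` demonstrates that the geometry of
the method is correct and stable under moderate isotropic noise, not that
it is robust to every artefact of real sequencing data.

## Problem sizes and numerical choices

The test suite and the acceptance script run entirely on generated data:
benchmark runs use 500–600 cells × 50 genes (a size at which the full
pipeline completes in a few seconds), property checks use 40–400 cells,
and oracle comparisons (direct-density responsibilities, dense GP
posteriors, Dijkstra, exhaustive path enumeration, brute-force pair
counting) use instances small enough for the naive method to be
unquestionably correct. Tolerances follow the quantity being checked:
$10^{-10}$–$10^{-12}$ for algebraic identities, $10^{-8}$ for quantities
passing through a Cholesky solve, $10^{-6}$ where escalating jitter may
perturb the result, and looser statistical bounds only for genuinely
stochastic properties.

## Known limitations

* The per-cluster GP assumes velocity varies smoothly *within* a cluster;
  a cluster straddling a sharp fate boundary gets a blended velocity.
* Shortest paths under the exponential weight favour long hops when a
  direct edge is cheaper than the sum of local steps, so a detected path
  may skip intermediate populations; those populations keep `NA`
  pseudotime unless another path covers them. The coverage-greedy
  selection bounds, but does not eliminate, this effect.
* Cells are assigned pseudotime through their population only; a cell
  whose expression is far from its population centroid is still ordered
  by the local linear approximation.
* The h5-based single-cell container dialect is not readable in this
  build; datasets arrive via the Matrix Market or delimited dialects.
* The mixture model's diagonal covariance ignores gene–gene correlation
  within clusters; this is a deliberate bias–variance trade-off in the
  genes ≫ cells regime.
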