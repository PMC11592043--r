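# poptraj

Population-level trajectory inference for single-cell RNA-seq data with
RNA velocity.

## The problem

Single-cell RNA sequencing captures a static snapshot of a developing
tissue: thousands of cells, each frozen somewhere along one or more
differentiation paths. Trajectory inference (TI) reconstructs those paths
and assigns each cell a *pseudotime* — a scalar in [0, 1] describing how
far along its path the cell has progressed. Expression similarity alone
cannot orient a path; RNA velocity (the time derivative of spliced mRNA
abundance, estimated upstream from the balance of spliced and unspliced
reads) gives every cell a direction in expression space and resolves the
arrow of time.

`poptraj` is for analysts who already have the three standard matrices —
spliced counts, unspliced counts, and an RNA velocity matrix computed by an
upstream tool — and want directed trajectories and per-cell pseudotime that
are robust to the noise and sparsity of cell-level measurements. The
central idea is to do the geometry at the level of *cell populations*
(small sub-clusters, akin to metacells) rather than individual cells.

## The method

Given expression vectors x_i ∈ R^n for m cells:

1. **Gaussian mixture clustering.** Cells are modelled as draws from
   P(x) = Σ_k ω_k N(x | μ_k, σ²_k) with diagonal covariance, fitted by
   expectation–maximization in the original expression space.
   Responsibilities γ_ir = ω_r N(x_i | μ_r, σ²_r) / Σ_k ω_k N(x_i | μ_k, σ²_k)
   are computed in log space; K can be fixed or selected by BIC.
2. **Cell populations.** Each cluster is refined by k-means into
   populations of roughly `target_pop_size` cells; each population s has a
   centroid X*_s.
3. **Velocity smoothing by GP regression.** A Gaussian process with RBF
   kernel Σ(x_i, x_j) = σ²_RBF exp(−‖x_i − x_j‖² / 2ℓ²) regresses cell
   velocities on cell expression; the posterior mean
   μ* = μ_V + Σ*(Σ + σ²I)⁻¹(V − μ_V) evaluated at the centroids gives each
   population a denoised velocity v_s. Hyperparameters (σ, ℓ, σ_RBF)
   maximize the log marginal likelihood.
4. **Directed KNN graph.** Each population links to its k nearest
   populations. An edge s→q is scored by the velocity-alignment
   dissimilarity l_α = 1 − cos∠(X*_q − X*_s, v_s) ∈ [0, 2] and the
   normalized distance l_d = d_sq / d_max ∈ [0, 1], combined nonlinearly
   into the weight e_sq = λ^(l_α + β·l_d) / λ. Edges pointing against the
   velocity (l_α > 1) are pruned.
5. **Trajectory detection.** Floyd–Warshall all-pairs shortest paths (it
   tolerates negative weights) between source populations (in-degree 0)
   and sinks (out-degree 0); paths are selected greedily by coverage.
6. **Pseudotime.** Along a path, population s sits at integer time t_s.
   Each member cell is projected onto the line W(t) = X*_s + v_s (t − t_s);
   its signed offset δ = (x − X*_s)·v_s / ‖v_s‖² orders cells within the
   population, and path times are min–max normalized to [0, 1].

Agreement with a known ordering is measured by an absolute-numerator
tie-corrected Kendall coefficient, τ_b = |C − D| / √((C+D+T₁)(C+D+T₂)) ∈
[0, 1], and the Spearman rank correlation ρ ∈ [−1, 1], averaged over
detected paths.

A seeded synthetic-data generator produces linear, bifurcating,
trifurcating and cycle-tree topologies with ground-truth time and branch
labels, smooth logistic expression programs, analytic velocities, and
spliced/unspliced layers consistent with the kinetic relation
v = β u − γ s — so the whole pipeline is testable without downloads.

## Worked example

```r
library(poptraj)

ds <- generate_dataset(topology_spec("linear", n_cells = 500, n_genes = 50,
                                     noise_sd = 0.05, seed = 0))
res <- run_pipeline(ds, run_config(seed = 1))
print(res)
#> <poptraj_result> 500 cells, 50 genes after preprocessing
#>   8 clusters -> 24 populations -> 1 trajectories
#>   mean Kendall 0.9743, mean Spearman 0.9985 over 1 path(s)

res$metrics$per_path
#> # A tibble: 1 × 4
#>   path_id n_cells kendall spearman
#>     <int>   <int>   <dbl>    <dbl>
#> 1       1     101   0.974    0.998
```

The mixture model found 8 clusters, refined into 24 populations of ~20
cells; one trajectory was detected (the topology is linear), and the
pseudotime of the cells on it agrees with the generator's hidden
ground-truth time with Kendall 0.974 and Spearman 0.998. `tidy(res)` gives
the per-cell table (`cell_id`, `population_id`, `path_id`, `pseudotime`),
`glance(res)` a one-row run summary, and `autoplot(res, "pseudotime")` /
`autoplot(res, "trajectories")` PCA views of the result. Real data enter
through `load_dataset()` (Matrix Market triplet or delimited dialects,
layers named `spliced`, `unspliced`, `velocity`).

A command-line interface wrapping the same functions ships in
`inst/cli/poptraj.R` with subcommands `simulate`, `run` and `evaluate`.

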