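# cliquecell

Linking cliques of co-expressed genes to cell types in a voxelized
gene-expression atlas.

## The problem

Brain-wide in situ hybridization atlases give, for thousands of genes, a
nonnegative *expression energy* `E(v, g)` in each voxel `v` of a registered
3D grid. Separately, transcriptome profiling gives a panel of cell-type
signatures `C(t, g)`. Sets of genes selected for exceptional spatial
co-expression ("cliques", e.g. groups enriched in autism-susceptibility
genes) are known to highlight specific brain structures — but which *cell
types* do they highlight? `cliquecell` answers that question
quantitatively:

1. **Deconvolution.** Assume the linear mixing model
   `E(v,g) = Σ_t ρ_t(v) C(t,g) + residual`. The spatial density `ρ_t(v)` of
   every cell type is estimated per voxel by nonnegative least squares
   (Lawson–Hanson active set), optionally with an L1 sparsity penalty.
2. **Clique scoring.** A clique's summed expression profile
   `E^C(v) = Σ_{g∈C} E(v,g)` is compared with every density profile using
   cosine similarity `ψ = ⟨E^C, ρ_t⟩ / (‖E^C‖‖ρ_t‖) ∈ [0,1]`.
3. **Monte Carlo significance.** Because ψ is biased by support size, each
   observed ψ is ranked within the empirical distribution of ψ for `R`
   random gene sets of the same size: `P_R` is the fraction of random sets
   scoring strictly lower. `R` is sized by Hoeffding's inequality
   (`2·exp(−2Rτ²) ≤ δ`); `R = 27,000` gives ±0.01 accuracy with 99%
   confidence.
4. **Threshold sweep.** The L2-normalized profile is thresholded at a grid
   of values τ and ψ recomputed, separating cell types highlighted by
   intense expression (similarity rises, peaks, then falls) from those
   riding on diffuse support.
5. **Pair fitting.** The best nonnegative combination
   `α1 ρ_t1 + α2 ρ_t2` of every pair of density profiles is solved in
   closed form; pairs beating every single cell type are reported with
   their own Monte Carlo significance.
6. **Region similarity.** Density profiles are scored against anatomical
   region masks via the unit-norm region indicator `χ_ω`.

Real atlases of this kind are not freely redistributable at voxel level,
so the package ships a synthetic generator — a small 3D grid, cell types
with disjoint marker blocks and box-shaped spatial territories, additive
truncated-Gaussian noise, and cliques planted inside one type's marker
block — giving every stage a testable ground truth.

## Worked example

```r
library(cliquecell)

cfg <- pipeline_config(output_dir = "demo_out", seed = 1)
res <- run_full_pipeline(cfg)
head(res$significance, 4)
```

```
  type_index type_label    psi      P_R rank
1          1     type_1 0.9694 1.00e+00    1
2          5     type_5 0.0895 1.85e-04    2
3          3     type_3 0.1324 1.11e-04    3
4          4     type_4 0.0940 7.41e-05    4
```

The clique planted in `type_1`'s marker block is recovered: its profile has
cosine similarity 0.969 to the fitted density of `type_1`, and all 27,000
random 6-gene sets score lower (`P_R = 1`), while every other type sits at
the bottom of its own null distribution. The threshold sweep peaks at
`τ = 0.0185` with ψ ≈ 1.000 — above the unthresholded 0.969, the signature
of a genuinely highlighted type. Five pairs of types beat the best single
type (best: types 1+6, ψ_pair = 0.979, `P_R = 1`), and `type_1` ranks first
against its own territory mask (φ = 0.958; the runner-up scores 0.001).
All tables are also written as TSVs under `demo_out/`, and a command-line
interface (`run_cli()`, launcher in `inst/scripts/cliquecell`) exposes each
stage as a subcommand (`synth`, `deconvolve`, `cliquescore`,
`significance`, `pairs`, `regionscore`, `run-all`).

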