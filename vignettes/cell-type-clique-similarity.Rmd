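---
title: "Cell-type similarity analysis of gene-expression cliques: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-type similarity analysis of gene-expression cliques: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cliquecell)
```

## The model

The package analyses a voxel-by-gene matrix of expression energies
$E(v,g) \ge 0$ on a regular 3D grid, together with a type-by-gene panel of
cell-type transcriptomes $C(t,g) \ge 0$ whose gene columns are aligned to
the atlas. The mixing model is linear with an additive residual:

$$E(v,g) = \sum_{t=1}^{T} \rho_t(v)\, C(t,g) + \mathrm{Residual}(v,g),$$

where $\rho_t(v) \ge 0$ is the spatial density of cell type $t$. The model
assumes expression energy is linear in mRNA abundance with a
gene-independent coefficient; gene-specific multiplicative noise is *not*
modelled, which is why the clique-profile builder offers a per-gene
L2-normalization flag as a robustness check.

Densities are estimated independently at each voxel:

$$\hat\rho_\cdot(v) = \arg\min_{\nu \in \mathbb{R}^T_{+}}
  \sum_g \Big(E(v,g) - \sum_t \nu(t) C(t,g)\Big)^2
  \;\; [\,+\, \lambda \textstyle\sum_t \nu(t)\,].$$

A clique $\mathcal{C}$ (a set of gene symbols) is represented by its summed
profile $E^{\mathcal{C}}(v) = \sum_{g \in \mathcal{C}} E(v,g)$ and scored
against each density column with the cosine similarity
$\psi(\mathcal{C}, t) \in [0,1]$. Significance is Monte Carlo: with $R$
random gene sets of size $|\mathcal{C}|$ drawn uniformly from the whole
pool, $P_R(\mathcal{C},t)$ is the fraction of random sets whose similarity
falls *strictly below* the observed one. Pair fitting generalizes the
single-type comparison to the best nonnegative combination of two density
profiles, and region scoring compares densities with the unit-norm
indicator $\chi_\omega$ of a voxel set $\omega$.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `l1_penalty` | 0 | sparsity penalty on the voxel fit; 0 reproduces the plain constrained least-squares used for the headline analysis. Useful only when the type panel grows far beyond a few dozen entries. |
| `n_draws` (R) | 27,000 | Monte Carlo draws; by Hoeffding's bound, $R=26{,}500$ already pins $P_R$ to ±0.01 with 99% confidence, and 27,000 is the value used for the reference tables. |
| `sweep_steps` | 101 | threshold-grid resolution on $[0, \max]$ of the L2-normalized profile. |
| `report_threshold` | 0.99 | pairs with $P_R$ at or above this enter the significant-pair report. |
| `per_gene_normalize` | off | normalize each gene column before summing; the main pipeline sums raw energies. |

## The synthetic world

The generator emulates the statistical structure the analysis assumes, at
desk scale. Defaults: an $8\times8\times8$ grid (512 voxels), $T = 6$ cell
types, 300 genes, 20 markers per type at 10-fold over a baseline of 1,
territory magnitudes uniform on $[0.5, 1.5]$, additive Gaussian noise with
$\sigma = 0.1$ truncated at zero, and planted cliques of 6 genes (the size
of the smaller of the two reference cliques; the pipeline exposes it).

Choices a user should understand:

* **Noise model.** The mixing model only states that noise is additive;
  we take i.i.d. Gaussian — the simplest distribution honoring that
  statement — truncated at zero so the atlas stays nonnegative. The
  truncation slightly biases low-signal voxels upward; at the default
  $\sigma$ this is negligible against a baseline of 1.
* **Disjoint marker blocks and slab territories.** Each type's markers are
  disjoint and its territory is a contiguous slab along the longest grid
  axis, so the panel has full row rank and the noise-free composition is
  exactly identifiable: the NNLS recovery test then has a right answer to
  1e-6, and the first two territories (the toy "cerebellum" and "cortex")
  are disjoint by construction.
* **What a green test does not establish.** The synthetic world has no
  registration error, no multiplicative (gene-specific) noise, no
  overlapping cell populations within a voxel, and territories far more
  clear-cut than real neuroanatomy. Green tests establish correctness of
  the computations, not that the model assumptions hold for any particular
  real atlas.

## Numerical choices

* **NNLS solver.** Lawson–Hanson active set posed on the normal equations;
  the $T \times T$ Gram matrix is computed once per field fit. The
  entering variable is the largest gradient component with smallest-index
  tie-break, making degenerate (duplicate-row) panels deterministic
  without any seed. Optimality is tested against random candidate vectors
  and an exact lattice-search oracle.
* **Pair fit.** The two-variable problem is solved in closed form:
  the two boundary problems $\alpha_i = 0$ are always evaluated, plus the
  unconstrained $2\times2$ solution when the determinant exceeds
  $10^{-12}\,a_{11}a_{22}$ and lands in the nonnegative quadrant; the
  lowest objective wins. Evaluating boundaries unconditionally makes
  near-collinear profile pairs numerically safe (the ill-conditioned
  unconstrained solution can never win when a boundary point is better).
* **Threshold semantics.** `threshold_profile()` zeroes entries
  $\le \tau$. At $\tau = 0$ only entries already equal to zero are zeroed,
  so the profile is preserved exactly; at $\tau = \max$ (the top of the
  sweep grid) everything is zeroed and the zero-norm cosine convention
  gives similarity 0, matching the large-threshold limit. A strict
  $< \tau$ rule would leave the argmax entries alive at the top of the
  grid and the curve would not close at zero.
* **Zero-norm cosine = 0.** Needed at the top of the sweep and for
  all-zero densities; it keeps every similarity matrix entry in $[0,1]$.
* **Strict inequality in $P_R$.** Ties count as not-lower. With continuous
  expression values ties have measure zero; in degenerate fixtures (a
  one-gene pool) the convention makes $P_R = 0$, which the tests pin down.
* **Shared draw sequence.** One sequence of $R$ random sets is scored
  against every type, making per-type $P_R$ values positively coupled but
  each marginally correct; the suite verifies agreement with independent
  per-type draws on an exhaustively enumerable toy pool. Draws are not
  deduplicated.
* **Seed discipline.** Every stochastic function takes an explicit seed
  and restores the caller's RNG state. The pipeline's top-level seed fans
  out to stages by fixed offsets (+1 field, +2 noise, +3 clique, +10
  Monte Carlo), so identical configs give byte-identical outputs while
  stages remain individually re-runnable.
* **Monte Carlo shortcut.** Similarities of a summed $k$-gene profile are
  computed from the precomputed gene-by-type cross-product and
  gene-by-gene Gram matrix ($O(k^2 + kT)$ per draw) rather than from the
  voxel vector; identity with the direct computation is unit-tested.

## Degenerate inputs

All-zero atlas rows fit to zero densities; an all-zero panel is an error;
a `marker_strength` of 1 (indistinguishable types) generates with a
warning; collinear density pairs are fitted via boundary enumeration;
an empty better-pair set produces empty but schema-complete reports.

## Known limitations

The deconvolution trusts the panel: cell types missing from it are
absorbed into the available profiles, and closely related transcriptomes
compete for the same voxels, so per-type densities are identifiable only
up to panel quality. The voxel solver is exact but dense — for atlases
with $10^5$ voxels and hundreds of types a compiled or batched solver
would be the next step. Region masks are flat index sets; no anatomical
ontology or hierarchy is modelled. The file formats are plain TSV chosen
for inspectability, not throughput.
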