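# Fixtures and independent oracles shared across the suite. Oracles here
# deliberately avoid the package's computational shortcuts: similarities
# are recomputed from raw voxel vectors, lattice searches enumerate the
# stated grid, and null CDFs come from full enumeration.

# Atlas on a trivial V x 1 x 1 grid from a plain matrix.
toy_atlas <- function(values, gene_ids = sprintf("g%d", seq_len(ncol(values)))) {
  values <- as.matrix(values)
  coords <- cbind(seq_len(nrow(values)) - 1L, 0L, 0L)
  expression_atlas(values, gene_ids, coords, c(nrow(values), 1L, 1L))
}

toy_panel <- function(values, type_labels = sprintf("t%d", seq_len(nrow(values))),
                      gene_ids = sprintf("g%d", seq_len(ncol(values)))) {
  cell_type_panel(as.matrix(values), type_labels, gene_ids)
}

random_atlas <- function(n_voxels, n_genes, seed) {
  set.seed(seed)
  toy_atlas(matrix(runif(n_voxels * n_genes), n_voxels, n_genes))
}

# Plain-vector cosine, no conventions, for strictly positive-norm inputs.
naive_cosine <- function(x, y) sum(x * y) / sqrt(sum(x^2) * sum(y^2))

# Straightforward per-draw null simulation: materializes each summed
# profile in voxel space (no Gram shortcut).
direct_null_samples <- function(atlas, field, draws) {
  R <- nrow(draws)
  out <- matrix(0, R, ncol(field$values))
  for (i in seq_len(R)) {
    prof <- rowSums(atlas$values[, draws[i, ], drop = FALSE])
    for (t in seq_len(ncol(field$values))) {
      out[i, t] <- cosine_similarity(prof, field$values[, t])
    }
  }
  out
}

# Exact null by full enumeration of all choose(n, k) gene sets: returns
# the similarity of every set to every density column.
enumerate_null <- function(atlas, field, k) {
  sets <- utils::combn(ncol(atlas$values), k)
  out <- matrix(0, ncol(sets), ncol(field$values))
  for (i in seq_len(ncol(sets))) {
    prof <- rowSums(atlas$values[, sets[, i], drop = FALSE])
    for (t in seq_len(ncol(field$values))) {
      out[i, t] <- cosine_similarity(prof, field$values[, t])
    }
  }
  out
}

# Exact minimum of the quadratic q(a1, a2) = e2 - 2 a1 b1 - 2 a2 b2 +
# a1^2 a11 + a2^2 a22 + 2 a1 a2 a12 over the lattice
# {0, step, ..., upper}^2. Exploits convexity in a2 for fixed a1: the
# lattice minimum over a2 sits at the lattice points bracketing the 1-D
# vertex, so the full-lattice minimum is recovered exactly without
# enumerating upper/step + 1 squared points.
grid_min_quad2 <- function(b1, b2, a11, a22, a12, e2, upper = 3, step = 1e-3) {
  grid1 <- seq(0, upper, by = step)
  eval_q <- function(a1, a2) {
    e2 - 2 * a1 * b1 - 2 * a2 * b2 + a1^2 * a11 + a2^2 * a22 +
      2 * a1 * a2 * a12
  }
  if (a22 <= 0) {
    return(min(eval_q(grid1, 0)))
  }
  vertex2 <- (b2 - grid1 * a12) / a22             # argmin over a2 given a1
  lo <- pmin(pmax(floor(vertex2 / step), 0), upper / step)
  cand <- cbind(lo, pmin(lo + 1, upper / step)) * step
  best <- pmin(eval_q(grid1, cand[, 1]), eval_q(grid1, cand[, 2]))
  min(best)
}

# Same lattice search posed for the 2-type NNLS voxel problem
# min ||e - nu1 c1 - nu2 c2||^2 over the lattice.
grid_min_nnls2 <- function(c1, c2, e, upper = 3, step = 1e-3) {
  grid_min_quad2(sum(e * c1), sum(e * c2), sum(c1^2), sum(c2^2),
                 sum(c1 * c2), sum(e^2), upper, step)
}
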