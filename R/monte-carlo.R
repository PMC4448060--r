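# Monte Carlo null for clique-to-type similarity: draw R random gene sets
# of the observed clique's size, score each against every density column,
# and read significance off the empirical distribution. R is sized from
# Hoeffding's concentration bound 2*exp(-2*R*tau^2) on an empirical
# proportion. Similarities are computed algebraically from the gene-level
# cross-products (see simulate_null), so a draw costs O(k^2 + k*T) instead
# of O(V*k).

#' Hoeffding bound and sample size for the Monte Carlo null
#'
#' `hoeffding_bound()` evaluates the two-sided Hoeffding bound
#' \eqn{2 e^{-2 R \tau^2}} on the probability that an empirical proportion
#' from `R` draws misses the truth by more than `tau`.
#' `hoeffding_sample_size()` inverts it: the smallest integer `R` with
#' bound `<= delta`, i.e. `ceiling(log(2/delta) / (2 tau^2))`.
#'
#' @param n_draws Number of Monte Carlo draws `R`.
#' @param tolerance Allowed deviation `tau`, in `(0, 1)`.
#' @param delta Allowed failure probability, in `(0, 1)`.
#' @return `hoeffding_bound()`: the bound value; `hoeffding_sample_size()`:
#'   an integer `R`.
#' @export
hoeffding_bound <- function(n_draws, tolerance) {
  if (n_draws < 1) stop("n_draws must be >= 1", call. = FALSE)
  if (tolerance <= 0 || tolerance >= 1) {
    stop("tolerance must be in (0, 1)", call. = FALSE)
  }
  2 * exp(-2 * n_draws * tolerance^2)
}

#' @rdname hoeffding_bound
#' @export
hoeffding_sample_size <- function(tolerance, delta) {
  if (tolerance <= 0 || tolerance >= 1 || delta <= 0 || delta >= 1) {
    stop("tolerance and delta must be in (0, 1)", call. = FALSE)
  }
  as.integer(ceiling(log(2 / delta) / (2 * tolerance^2)))
}

#' Monte Carlo configuration
#'
#' @param n_draws Number of random gene sets `R`; the default 27,000 is the
#'   value used for the reference analysis.
#' @param seed Integer seed for the draws.
#' @param tolerance,delta Passed to [hoeffding_sample_size()] when sizing a
#'   simulation; not used by the simulation itself.
#' @return A `monte_carlo_config` list.
#' @export
monte_carlo_config <- function(n_draws = 27000L, seed = 1L,
                               tolerance = 0.01, delta = 0.01) {
  if (n_draws < 1L) stop("n_draws must be >= 1", call. = FALSE)
  structure(list(n_draws = as.integer(n_draws), seed = as.integer(seed),
                 tolerance = tolerance, delta = delta),
            class = "monte_carlo_config")
}

#' Draw random same-size gene sets
#'
#' Draws `R` sets of `k` genes, each sampled uniformly without replacement
#' from the full pool (the observed clique's genes are not excluded), sets
#' independent across draws. Returned as an `R x k` integer index matrix of
#' class `clique_draws` carrying the pool, which is what the simulation
#' consumes; [draw_clique()] materializes one draw as a [gene_clique()].
#'
#' @param gene_pool Character vector of gene ids to draw from.
#' @param k Genes per set.
#' @param n_draws Number of sets `R`.
#' @param seed Integer seed; the same seed reproduces the same sequence.
#' @return A `clique_draws` object.
#' @export
draw_random_cliques <- function(gene_pool, k, n_draws, seed = 1L) {
  gene_pool <- as.character(gene_pool)
  n <- length(gene_pool)
  if (k > n) stop("k exceeds the gene pool size", call. = FALSE)
  if (k < 1L || n_draws < 1L) stop("k and n_draws must be >= 1", call. = FALSE)
  idx <- with_seed(seed, {
    matrix(vapply(seq_len(n_draws), function(i) sample.int(n, k),
                  integer(k)),
           nrow = n_draws, byrow = TRUE)
  })
  structure(idx, gene_pool = gene_pool, seed = as.integer(seed),
            class = c("clique_draws", "matrix"))
}

#' @rdname draw_random_cliques
#' @param draws A `clique_draws` object.
#' @param i Draw number in `1..R`.
#' @export
draw_clique <- function(draws, i) {
  stopifnot(inherits(draws, "clique_draws"))
  gene_clique(sprintf("random_%d", i),
              attr(draws, "gene_pool")[draws[i, , drop = TRUE]])
}

# Shared algebraic machinery: for a draw with gene indices `idx`,
#   <P, rho_t> = sum of cross[idx, t]   with cross = t(E) %*% field
#   ||P||^2    = sum of gram[idx, idx]  with gram  = t(E) %*% E
# by bilinearity of the inner product (P is the sum of the gene columns).
null_precompute <- function(atlas_values, field_values) {
  list(cross = crossprod(atlas_values, field_values),
       gram = crossprod(atlas_values),
       rho_norms = sqrt(colSums(field_values^2)))
}

draw_similarities <- function(pre, idx) {
  # cosine of the summed profile of `idx` to every density column
  p2 <- sum(pre$gram[idx, idx])
  if (p2 <= 0) return(numeric(ncol(pre$cross)))
  numer <- colSums(pre$cross[idx, , drop = FALSE])
  psi <- numer / (sqrt(p2) * pre$rho_norms)
  psi[pre$rho_norms == 0] <- 0
  pmin(psi, 1)
}

#' Simulate the null distribution of clique-to-type similarity
#'
#' For each of `R` random `k`-gene sets, computes the cosine similarity of
#' the set's summed expression profile to every density column. One shared
#' draw sequence is reused across all types (each type's marginal
#' distribution is unaffected; values are positively coupled across types).
#'
#' @param atlas An [expression_atlas()] providing the gene pool and
#'   expression columns.
#' @param field A [density_field()].
#' @param k Clique size whose null is simulated.
#' @param config A [monte_carlo_config()].
#' @param draws Optional precomputed [draw_random_cliques()] result
#'   (overrides `k`/`config` draw settings).
#' @return A `null_distribution`: `samples` (`R x n_types`, each column
#'   sorted ascending), `clique_size`, `seed`, `type_labels`.
#' @export
simulate_null <- function(atlas, field, k, config = monte_carlo_config(),
                          draws = NULL) {
  stopifnot(inherits(atlas, "expression_atlas"),
            inherits(field, "density_field"))
  if (nrow(atlas$values) != nrow(field$values)) {
    stop("atlas and field voxel counts differ", call. = FALSE)
  }
  if (is.null(draws)) {
    draws <- draw_random_cliques(atlas$gene_ids, k, config$n_draws,
                                 config$seed)
  }
  pre <- null_precompute(atlas$values, field$values)
  R <- nrow(draws)
  samples <- matrix(0, nrow = R, ncol = ncol(field$values),
                    dimnames = list(NULL, field$type_labels))
  for (i in seq_len(R)) {
    samples[i, ] <- draw_similarities(pre, draws[i, ])
  }
  samples <- apply(samples, 2L, sort)
  structure(list(samples = samples, clique_size = as.integer(k),
                 seed = attr(draws, "seed"),
                 type_labels = field$type_labels),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution> |C| = %d, R = %d draws, %d types\n",
              x$clique_size, nrow(x$samples), ncol(x$samples)))
  invisible(x)
}

#' Monte Carlo significance of observed similarities
#'
#' For each type, `P_R` is the fraction of null samples strictly below the
#' observed similarity (ties count as not-lower). Types are ranked by
#' descending `P_R`; ties broken by descending observed similarity, then
#' ascending type index.
#'
#' @param observed Numeric vector of observed similarities, one per type,
#'   in the field's type order (e.g. `psi` from [rank_by_similarity()]
#'   reordered, or computed directly).
#' @param null A `null_distribution` over the same types.
#' @return A `significance_table` data.frame: `type_index`, `type_label`,
#'   `psi`, `P_R`, `rank`, ordered by rank.
#' @export
significance <- function(observed, null) {
  stopifnot(inherits(null, "null_distribution"))
  n_types <- ncol(null$samples)
  if (length(observed) != n_types) {
    stop("observed similarities do not match the null's types",
         call. = FALSE)
  }
  R <- nrow(null$samples)
  p_r <- vapply(seq_len(n_types), function(t) {
    # columns are sorted: count of samples strictly below the observation
    findInterval(observed[t], null$samples[, t], left.open = TRUE) / R
  }, numeric(1))
  ord <- order(-p_r, -observed, seq_len(n_types))
  out <- data.frame(type_index = ord,
                    type_label = null$type_labels[ord],
                    psi = observed[ord], P_R = p_r[ord],
                    rank = seq_len(n_types), stringsAsFactors = FALSE)
  class(out) <- c("significance_table", "data.frame")
  out
}
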