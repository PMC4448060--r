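# Best nonnegative combination of two density profiles for a clique
# profile. The 2-variable quadratic program is solved in closed form:
# unconstrained 2x2 normal equations, and when a coefficient goes negative
# (or the profiles are collinear) the two boundary problems alpha_i = 0 are
# enumerated and the lower objective kept. Exact and branch-complete, which
# is why no generic NNLS call is used here.

solve_pair_qp <- function(b1, b2, a11, a22, a12, e2) {
  # min ||E - a1 r1 - a2 r2||^2 over a >= 0, expressed through the scalars
  # b_i = <E, r_i>, a_ij = <r_i, r_j>, e2 = ||E||^2.
  objective <- function(a1, a2) {
    e2 - 2 * a1 * b1 - 2 * a2 * b2 +
      a1^2 * a11 + a2^2 * a22 + 2 * a1 * a2 * a12
  }
  # boundary problems are always candidates: they are the answer when the
  # unconstrained optimum leaves the cone or the profiles are (near-)
  # collinear, and harmless otherwise
  c1 <- if (a11 > 0) max(0, b1 / a11) else 0
  c2 <- if (a22 > 0) max(0, b2 / a22) else 0
  cand <- list(c(c1, 0), c(0, c2))
  det <- a11 * a22 - a12^2
  if (det > 1e-12 * max(a11 * a22, .Machine$double.xmin)) {
    a1 <- (b1 * a22 - b2 * a12) / det
    a2 <- (b2 * a11 - b1 * a12) / det
    if (a1 >= 0 && a2 >= 0) cand[[length(cand) + 1L]] <- c(a1, a2)
  }
  objs <- vapply(cand, function(a) objective(a[1], a[2]), numeric(1))
  best <- cand[[which.min(objs)]]
  list(alpha = best, objective = min(objs))
}

#' Optimal nonnegative pair fit of a clique profile
#'
#' Finds \eqn{\alpha^* \ge 0} minimizing
#' \eqn{\|E - \alpha_1 \rho_1 - \alpha_2 \rho_2\|_2^2} and returns the
#' cosine similarity between the fitted vector and the profile. The fit can
#' never be worse than the better single profile (either single solution is
#' feasible), so `psi_pair >= max(single psi) - 1e-9` always holds.
#'
#' @param profile A `clique_profile` (non-zero).
#' @param rho1,rho2 Nonnegative density vectors (not both zero).
#' @return A `pair_fit` list: `alpha` (length 2, `>= 0`), `fitted`
#'   (combined voxel vector), `psi_pair`, `objective`.
#' @export
fit_pair <- function(profile, rho1, rho2) {
  stopifnot(inherits(profile, "clique_profile"))
  e <- profile$values
  if (all(e == 0)) stop("zero clique profile", call. = FALSE)
  if (any(rho1 < 0) || any(rho2 < 0)) {
    stop("density vectors must be nonnegative", call. = FALSE)
  }
  if (length(rho1) != length(e) || length(rho2) != length(e)) {
    stop("length mismatch", call. = FALSE)
  }
  sol <- solve_pair_qp(sum(e * rho1), sum(e * rho2),
                       sum(rho1^2), sum(rho2^2), sum(rho1 * rho2),
                       sum(e^2))
  fitted <- sol$alpha[1] * rho1 + sol$alpha[2] * rho2
  structure(list(alpha = sol$alpha, fitted = fitted,
                 psi_pair = cosine_similarity(fitted, e),
                 objective = sol$objective),
            class = "pair_fit")
}

#' Pairwise optimal-similarity matrix
#'
#' Symmetric `n_types x n_types` matrix whose entry `(t1, t2)` is the
#' optimal pair similarity of [fit_pair()]; the diagonal holds the
#' single-type similarities.
#'
#' @param profile A `clique_profile`.
#' @param field A [density_field()] with at least two types.
#' @return A numeric matrix with type labels as dimnames.
#' @export
pair_similarity_matrix <- function(profile, field) {
  stopifnot(inherits(profile, "clique_profile"),
            inherits(field, "density_field"))
  n_types <- ncol(field$values)
  if (n_types < 2L) stop("need at least two types", call. = FALSE)
  e <- profile$values
  if (all(e == 0)) stop("zero clique profile", call. = FALSE)
  # all the needed inner products at once
  b <- drop(crossprod(field$values, e))
  A <- crossprod(field$values)
  e2 <- sum(e^2)
  en <- sqrt(e2)
  out <- matrix(0, n_types, n_types,
                dimnames = list(field$type_labels, field$type_labels))
  pair_cos <- function(alpha, t1, t2) {
    f_dot_e <- alpha[1] * b[t1] + alpha[2] * b[t2]
    f2 <- alpha[1]^2 * A[t1, t1] + alpha[2]^2 * A[t2, t2] +
      2 * alpha[1] * alpha[2] * A[t1, t2]
    if (f2 <= 0) return(0)
    min(max(f_dot_e, 0) / (sqrt(f2) * en), 1)
  }
  for (t1 in seq_len(n_types)) {
    out[t1, t1] <- pair_cos(c(1, 0), t1, t1)
    for (t2 in seq_len(n_types)[-seq_len(t1)]) {
      sol <- solve_pair_qp(b[t1], b[t2], A[t1, t1], A[t2, t2], A[t1, t2], e2)
      out[t1, t2] <- out[t2, t1] <- pair_cos(sol$alpha, t1, t2)
    }
  }
  out
}

#' Pairs beating every single cell type
#'
#' Unordered pairs whose optimal combined similarity strictly exceeds the
#' maximum single-type similarity.
#'
#' @param pair_matrix Matrix from [pair_similarity_matrix()].
#' @param single_psi Numeric vector of single-type similarities (defaults
#'   to the matrix diagonal).
#' @return A data.frame `t1`, `t2` (1-based, `t1 < t2`), `psi_pair`,
#'   ordered by decreasing `psi_pair`.
#' @export
better_pairs <- function(pair_matrix, single_psi = diag(pair_matrix)) {
  n <- nrow(pair_matrix)
  best_single <- max(single_psi)
  t1 <- t2 <- integer(0)
  psi <- numeric(0)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      if (pair_matrix[i, j] > best_single) {
        t1 <- c(t1, i); t2 <- c(t2, j); psi <- c(psi, pair_matrix[i, j])
      }
    }
  }
  out <- data.frame(t1 = t1, t2 = t2, psi_pair = psi)
  out[order(-out$psi_pair, out$t1, out$t2), , drop = FALSE]
}

#' Monte Carlo significance of pair fits
#'
#' For each random `k`-gene set, re-solves the pair fit of that draw's
#' summed profile against the same two density columns and records its
#' optimal similarity; `P_R` is the fraction of draws strictly below the
#' observed pair similarity.
#'
#' @param atlas An [expression_atlas()] (gene pool and columns).
#' @param field A [density_field()].
#' @param pairs data.frame with columns `t1`, `t2` (1-based type indices),
#'   e.g. from [better_pairs()].
#' @param k Clique size.
#' @param config A [monte_carlo_config()].
#' @param observed Numeric vector of observed pair similarities, one per
#'   row of `pairs` (defaults to re-computing from `profile`).
#' @param profile The observed `clique_profile` (needed when `observed` is
#'   not given).
#' @return `pairs` with columns `psi_pair` and `P_R` added.
#' @export
pair_significance <- function(atlas, field, pairs, k,
                              config = monte_carlo_config(),
                              profile = NULL, observed = NULL) {
  stopifnot(inherits(atlas, "expression_atlas"),
            inherits(field, "density_field"))
  if (nrow(pairs) == 0L) {
    pairs$psi_pair <- numeric(0)
    pairs$P_R <- numeric(0)
    return(pairs)
  }
  A <- crossprod(field$values)
  if (is.null(observed)) {
    if (is.null(profile)) {
      stop("either `observed` or `profile` must be supplied", call. = FALSE)
    }
    observed <- vapply(seq_len(nrow(pairs)), function(r) {
      fit_pair(profile, field$values[, pairs$t1[r]],
               field$values[, pairs$t2[r]])$psi_pair
    }, numeric(1))
  }
  draws <- draw_random_cliques(atlas$gene_ids, k, config$n_draws,
                               config$seed)
  cross <- crossprod(atlas$values, field$values)   # genes x types
  gram <- crossprod(atlas$values)
  R <- nrow(draws)
  below <- integer(nrow(pairs))
  for (i in seq_len(R)) {
    idx <- draws[i, ]
    e2 <- sum(gram[idx, idx])
    if (e2 <= 0) {
      # zero random profile scores 0 against everything
      below <- below + as.integer(observed > 0)
      next
    }
    bvec <- colSums(cross[idx, , drop = FALSE])
    for (r in seq_len(nrow(pairs))) {
      t1 <- pairs$t1[r]; t2 <- pairs$t2[r]
      sol <- solve_pair_qp(bvec[t1], bvec[t2], A[t1, t1], A[t2, t2],
                           A[t1, t2], e2)
      f_dot_e <- sol$alpha[1] * bvec[t1] + sol$alpha[2] * bvec[t2]
      f2 <- sol$alpha[1]^2 * A[t1, t1] + sol$alpha[2]^2 * A[t2, t2] +
        2 * sol$alpha[1] * sol$alpha[2] * A[t1, t2]
      psi <- if (f2 <= 0) 0 else min(max(f_dot_e, 0) / sqrt(f2 * e2), 1)
      if (psi < observed[r]) below[r] <- below[r] + 1L
    }
  }
  pairs$psi_pair <- observed
  pairs$P_R <- below / R
  pairs
}

#' Occurrence histogram of types in qualifying pairs
#'
#' Each pair contributes one count to both member types, so the total mass
#' is twice the number of pairs.
#'
#' @param pairs data.frame with columns `t1`, `t2` (1-based type indices).
#' @param n_types Total number of types.
#' @return Integer vector of length `n_types`.
#' @export
pair_occurrence_histogram <- function(pairs, n_types) {
  counts <- integer(n_types)
  if (nrow(pairs)) {
    tab <- table(factor(c(pairs$t1, pairs$t2), levels = seq_len(n_types)))
    counts <- as.integer(tab)
  }
  names(counts) <- as.character(seq_len(n_types))
  counts
}
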