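# Clique expression profiles and their cosine similarity to density
# profiles. Cosine of two nonnegative voxel vectors lies in [0,1]; the
# zero-norm case is defined as 0, which is what makes the top of the
# threshold sweep (everything thresholded away) well defined.

#' Summed expression profile of a gene clique
#'
#' Elementwise sum of the clique's gene columns of the atlas. With
#' `per_gene_normalize = TRUE` each column is first divided by its L2 norm
#' (a guard against gene-specific multiplicative noise); all-zero columns
#' are skipped with a warning.
#'
#' @param atlas An [expression_atlas()].
#' @param clique A [gene_clique()]; every gene must be present in the atlas.
#' @param per_gene_normalize Normalize each gene column before summing.
#' @return A `clique_profile` object: `values` (voxel vector),
#'   `clique_name`, `n_genes`.
#' @export
sum_expression <- function(atlas, clique, per_gene_normalize = FALSE) {
  stopifnot(inherits(atlas, "expression_atlas"),
            inherits(clique, "gene_clique"))
  missing <- setdiff(clique$gene_ids, atlas$gene_ids)
  if (length(missing)) {
    stop("clique gene(s) not in atlas: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  cols <- atlas$values[, clique$gene_ids, drop = FALSE]
  if (per_gene_normalize) {
    norms <- sqrt(colSums(cols^2))
    zero <- norms == 0
    if (any(zero)) {
      warning(sum(zero), " all-zero gene column(s) skipped in normalization",
              call. = FALSE)
      norms[zero] <- 1
    }
    cols <- sweep(cols, 2L, norms, "/")
  }
  clique_profile(rowSums(cols), clique$name, length(clique$gene_ids))
}

#' @rdname sum_expression
#' @param values Nonnegative voxel vector.
#' @param clique_name Name carried along into reports.
#' @param n_genes Number of genes summed into the profile.
#' @export
clique_profile <- function(values, clique_name, n_genes) {
  values <- as.numeric(values)
  check_nonneg_finite(values, "clique profile")
  structure(list(values = values, clique_name = as.character(clique_name),
                 n_genes = as.integer(n_genes)),
            class = "clique_profile")
}

#' @export
print.clique_profile <- function(x, ...) {
  cat(sprintf("<clique_profile> '%s', %d genes, %d voxels\n",
              x$clique_name, x$n_genes, length(x$values)))
  invisible(x)
}

#' Cosine similarity of two nonnegative voxel vectors
#'
#' \eqn{\psi(x, y) = \langle x, y\rangle / (\|x\|_2 \|y\|_2)}, a number in
#' `[0, 1]` because both vectors are nonnegative; 0 by convention when
#' either norm is zero.
#'
#' @param x,y Nonnegative numeric vectors of equal length.
#' @return Scalar in `[0, 1]`.
#' @export
cosine_similarity <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (any(x < 0) || any(y < 0)) {
    stop("cosine_similarity requires nonnegative vectors", call. = FALSE)
  }
  nx <- sqrt(sum(x^2))
  ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) return(0)
  min(sum(x * y) / (nx * ny), 1)
}

#' Threshold a clique profile
#'
#' Sets entries `<= tau` to zero and keeps the rest unchanged. At `tau = 0`
#' the profile is preserved exactly (only zero entries are zeroed); above
#' the maximum entry the result is all-zero.
#'
#' @param profile A `clique_profile`.
#' @param tau Nonnegative threshold.
#' @return A thresholded `clique_profile`.
#' @export
threshold_profile <- function(profile, tau) {
  stopifnot(inherits(profile, "clique_profile"))
  if (tau < 0) stop("tau must be >= 0", call. = FALSE)
  out <- profile
  out$values <- ifelse(profile$values <= tau, 0, profile$values)
  out
}

#' Threshold sweep of clique-to-type similarities
#'
#' L2-normalizes the profile, then for each threshold on a uniform grid
#' from 0 to the maximum normalized entry (inclusive) computes the cosine
#' similarity of the thresholded profile to every density column. The
#' similarity curve of a highlighted type typically rises as low-expression
#' voxels are zeroed, peaks, and falls to 0 at the top of the grid.
#'
#' @param profile A `clique_profile` (non-zero).
#' @param field A [density_field()].
#' @param n_steps Number of grid points, `>= 2` (default 101).
#' @return A `threshold_sweep` object: `thresholds`, `similarities`
#'   (`n_steps x n_types`, entries in `[0,1]`), `peak_threshold` and
#'   `peak_value` per type (ties resolved to the smallest threshold).
#' @export
threshold_sweep <- function(profile, field, n_steps = 101L) {
  stopifnot(inherits(profile, "clique_profile"),
            inherits(field, "density_field"))
  if (n_steps < 2L) stop("n_steps must be >= 2", call. = FALSE)
  norm <- sqrt(sum(profile$values^2))
  if (norm == 0) stop("zero clique profile", call. = FALSE)
  normalized <- clique_profile(profile$values / norm, profile$clique_name,
                               profile$n_genes)
  thresholds <- seq(0, max(normalized$values), length.out = n_steps)
  n_types <- ncol(field$values)
  sims <- matrix(0, nrow = n_steps, ncol = n_types,
                 dimnames = list(NULL, field$type_labels))
  for (i in seq_len(n_steps)) {
    thr <- threshold_profile(normalized, thresholds[i])
    for (t in seq_len(n_types)) {
      sims[i, t] <- cosine_similarity(thr$values, field$values[, t])
    }
  }
  peak_idx <- apply(sims, 2L, which.max)   # first max = smallest tau
  structure(list(thresholds = thresholds, similarities = sims,
                 peak_threshold = thresholds[peak_idx],
                 peak_value = sims[cbind(peak_idx, seq_len(n_types))],
                 clique_name = profile$clique_name),
            class = "threshold_sweep")
}

#' @export
print.threshold_sweep <- function(x, ...) {
  cat(sprintf("<threshold_sweep> '%s': %d thresholds x %d types\n",
              x$clique_name, length(x$thresholds), ncol(x$similarities)))
  invisible(x)
}

#' Rank cell types by cosine similarity to a clique profile
#'
#' @param profile A `clique_profile`.
#' @param field A [density_field()].
#' @return A data.frame with columns `type_index` (1-based), `type_label`,
#'   `psi`, sorted by decreasing `psi`; ties broken by ascending type
#'   index.
#' @export
rank_by_similarity <- function(profile, field) {
  stopifnot(inherits(profile, "clique_profile"),
            inherits(field, "density_field"))
  psi <- vapply(seq_len(ncol(field$values)), function(t) {
    cosine_similarity(profile$values, field$values[, t])
  }, numeric(1))
  ord <- order(-psi, seq_along(psi))
  data.frame(type_index = ord, type_label = field$type_labels[ord],
             psi = psi[ord], stringsAsFactors = FALSE)
}
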