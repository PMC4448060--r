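# Region scoring: each region mask defines a unit-norm indicator vector
# (uniform on its voxels), and a density profile's similarity to the
# region is its cosine to that indicator.

#' Unit-norm indicator vector of a region
#'
#' Value \eqn{1/\sqrt{|\omega|}} on the mask's voxels and 0 elsewhere, so
#' the vector has unit L2 norm and uniform support on the region.
#'
#' @param mask A [region_mask()].
#' @param n_voxels Atlas voxel count.
#' @return A `region_indicator`: `values` (voxel vector), `mask_name`.
#' @export
region_indicator <- function(mask, n_voxels) {
  stopifnot(inherits(mask, "region_mask"))
  if (any(mask$voxel_indices >= n_voxels)) {
    stop("mask voxel index out of range", call. = FALSE)
  }
  values <- numeric(n_voxels)
  values[mask$voxel_indices + 1L] <- 1 / sqrt(length(mask$voxel_indices))
  structure(list(values = values, mask_name = mask$name),
            class = "region_indicator")
}

#' Cosine similarity of a density profile to a region
#'
#' \eqn{\phi_\omega(\rho) = \sum_v \rho(v)\chi_\omega(v) / \|\rho\|_2}
#' (the indicator is already unit norm); 0 by convention for a zero
#' density. Equals 1 exactly when the density is a positive multiple of
#' the uniform indicator on the region.
#'
#' @param density Nonnegative voxel vector.
#' @param indicator A [region_indicator()].
#' @return Scalar in `[0, 1]`.
#' @export
region_cosine <- function(density, indicator) {
  stopifnot(inherits(indicator, "region_indicator"))
  if (any(density < 0)) stop("density must be nonnegative", call. = FALSE)
  if (length(density) != length(indicator$values)) {
    stop("length mismatch", call. = FALSE)
  }
  norm <- sqrt(sum(density^2))
  if (norm == 0) return(0)
  min(sum(density * indicator$values) / norm, 1)
}

#' Rank cell types by similarity to a region
#'
#' @param field A [density_field()].
#' @param mask A [region_mask()].
#' @return A data.frame `type_index` (1-based), `type_label`, `phi`,
#'   sorted by decreasing `phi`; ties by ascending type index.
#' @export
rank_types_by_region <- function(field, mask) {
  stopifnot(inherits(field, "density_field"))
  chi <- region_indicator(mask, nrow(field$values))
  phi <- vapply(seq_len(ncol(field$values)), function(t) {
    region_cosine(field$values[, t], chi)
  }, numeric(1))
  ord <- order(-phi, seq_along(phi))
  data.frame(type_index = ord, type_label = field$type_labels[ord],
             phi = phi[ord], stringsAsFactors = FALSE)
}
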