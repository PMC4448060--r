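# Internal: evaluate an expression with a temporary RNG seed, restoring the
# caller's .Random.seed afterwards so package functions never perturb the
# user's random stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

check_nonneg_finite <- function(values, what) {
  if (!all(is.finite(values))) {
    stop(sprintf("%s contains non-finite values", what), call. = FALSE)
  }
  if (any(values < 0)) {
    stop(sprintf("%s contains negative values", what), call. = FALSE)
  }
  invisible(TRUE)
}

#' Voxel-by-gene expression atlas
#'
#' Container for a dense nonnegative matrix of expression energies
#' \eqn{E(v,g)} over a regular 3D voxel grid, one row per voxel and one
#' column per gene.
#'
#' @param values Numeric matrix, `n_voxels x n_genes`, all entries finite
#'   and `>= 0`.
#' @param gene_ids Character vector of unique gene identifiers, one per
#'   column. Matching elsewhere in the package is exact and case-sensitive.
#' @param voxel_coords Integer matrix `n_voxels x 3` of 0-based `(x, y, z)`
#'   grid coordinates, one row per voxel.
#' @param grid_dims Integer vector `(nx, ny, nz)`.
#'
#' @return An object of class `expression_atlas` with fields `values`,
#'   `gene_ids`, `voxel_coords`, `grid_dims`.
#' @export
expression_atlas <- function(values, gene_ids, voxel_coords, grid_dims) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  check_nonneg_finite(values, "atlas values")
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene identifiers: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (length(gene_ids) != ncol(values)) {
    stop("length(gene_ids) must equal ncol(values)", call. = FALSE)
  }
  voxel_coords <- as.matrix(voxel_coords)
  storage.mode(voxel_coords) <- "integer"
  if (nrow(voxel_coords) != nrow(values) || ncol(voxel_coords) != 3L) {
    stop("voxel_coords must be an n_voxels x 3 integer matrix", call. = FALSE)
  }
  grid_dims <- as.integer(grid_dims)
  if (length(grid_dims) != 3L || any(grid_dims < 1L)) {
    stop("grid_dims must be three positive integers", call. = FALSE)
  }
  for (ax in 1:3) {
    if (any(voxel_coords[, ax] < 0L | voxel_coords[, ax] >= grid_dims[ax])) {
      stop("voxel coordinates outside grid_dims on axis ", ax, call. = FALSE)
    }
  }
  colnames(values) <- gene_ids
  structure(
    list(values = values, gene_ids = gene_ids,
         voxel_coords = voxel_coords, grid_dims = grid_dims),
    class = "expression_atlas"
  )
}

#' Type-by-gene cell-type transcriptome panel
#'
#' Nonnegative matrix \eqn{C(t,g)} of transcriptome profiles, one row per
#' cell-type sample. Gene columns must be aligned (same content and order)
#' with the paired [expression_atlas()] before fitting; see [align_genes()].
#'
#' @param values Numeric matrix, `n_types x n_genes`, nonnegative and finite.
#' @param type_labels Character vector of unique type labels.
#' @param gene_ids Character vector of gene identifiers, one per column.
#' @param type_indices Optional integer identifiers for the types (defaults
#'   to `1:n_types`); report tables print these 1-based indices.
#'
#' @return An object of class `cell_type_panel`.
#' @export
cell_type_panel <- function(values, type_labels, gene_ids,
                            type_indices = seq_along(type_labels)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  check_nonneg_finite(values, "panel values")
  type_labels <- as.character(type_labels)
  if (anyDuplicated(type_labels)) {
    stop("duplicate type labels", call. = FALSE)
  }
  if (length(type_labels) != nrow(values)) {
    stop("length(type_labels) must equal nrow(values)", call. = FALSE)
  }
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene identifiers in panel", call. = FALSE)
  }
  if (length(gene_ids) != ncol(values)) {
    stop("length(gene_ids) must equal ncol(values)", call. = FALSE)
  }
  type_indices <- as.integer(type_indices)
  if (length(type_indices) != length(type_labels)) {
    stop("type_indices length mismatch", call. = FALSE)
  }
  rownames(values) <- type_labels
  colnames(values) <- gene_ids
  structure(
    list(values = values, type_labels = type_labels,
         type_indices = type_indices, gene_ids = gene_ids),
    class = "cell_type_panel"
  )
}

#' Voxel-by-type density field
#'
#' Estimated nonnegative spatial densities \eqn{\rho_t(v)}, one column per
#' cell type, typically produced by [fit_density_field()] or by the
#' synthetic generator.
#'
#' @param values Numeric matrix `n_voxels x n_types`, nonnegative.
#' @param type_labels Character vector of type labels, as in the panel.
#'
#' @return An object of class `density_field`.
#' @export
density_field <- function(values, type_labels) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  check_nonneg_finite(values, "density values")
  type_labels <- as.character(type_labels)
  if (length(type_labels) != ncol(values)) {
    stop("one type label per density column required", call. = FALSE)
  }
  colnames(values) <- type_labels
  structure(list(values = values, type_labels = type_labels),
            class = "density_field")
}

#' Gene clique
#'
#' An ordered set of gene symbols treated as a unit: its summed expression
#' profile is the object scored against cell-type densities.
#'
#' @param name Clique name.
#' @param gene_ids Character vector of distinct gene symbols, non-empty.
#'
#' @return An object of class `gene_clique`.
#' @export
gene_clique <- function(name, gene_ids) {
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) == 0L) stop("clique is empty", call. = FALSE)
  if (anyDuplicated(gene_ids)) {
    stop("duplicate genes in clique: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
         call. = FALSE)
  }
  structure(list(name = as.character(name)[1L], gene_ids = gene_ids),
            class = "gene_clique")
}

#' Anatomical region mask
#'
#' A named set of voxel row indices (0-based, as everywhere in the package)
#' into an atlas.
#'
#' @param name Region name.
#' @param voxel_indices Integer vector of distinct 0-based voxel indices.
#' @param n_voxels Optional atlas size for range validation.
#'
#' @return An object of class `region_mask`.
#' @export
region_mask <- function(name, voxel_indices, n_voxels = NULL) {
  voxel_indices <- as.integer(voxel_indices)
  if (length(voxel_indices) == 0L) stop("mask is empty", call. = FALSE)
  if (anyDuplicated(voxel_indices)) stop("duplicate voxel indices", call. = FALSE)
  if (any(voxel_indices < 0L)) stop("negative voxel index", call. = FALSE)
  if (!is.null(n_voxels) && any(voxel_indices >= n_voxels)) {
    stop("voxel index out of range [0, n_voxels)", call. = FALSE)
  }
  structure(list(name = as.character(name)[1L],
                 voxel_indices = sort(voxel_indices)),
            class = "region_mask")
}

#' @export
print.expression_atlas <- function(x, ...) {
  cat(sprintf("<expression_atlas> %d voxels x %d genes, grid %s\n",
              nrow(x$values), ncol(x$values),
              paste(x$grid_dims, collapse = "x")))
  invisible(x)
}

#' @export
print.cell_type_panel <- function(x, ...) {
  cat(sprintf("<cell_type_panel> %d types x %d genes\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
print.density_field <- function(x, ...) {
  cat(sprintf("<density_field> %d voxels x %d types\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
print.gene_clique <- function(x, ...) {
  cat(sprintf("<gene_clique> '%s', %d genes\n", x$name, length(x$gene_ids)))
  invisible(x)
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("<region_mask> '%s', %d voxels\n", x$name,
              length(x$voxel_indices)))
  invisible(x)
}

#' Align atlas and panel gene columns
#'
#' Restricts both objects to the intersection of their gene sets, with
#' columns in identical order (atlas order of the shared genes). Genes
#' dropped on either side are reported via `message()`.
#'
#' @param atlas An [expression_atlas()].
#' @param panel A [cell_type_panel()].
#'
#' @return A list with elements `atlas` and `panel`, gene columns aligned.
#'   Errors if the gene sets are disjoint.
#' @export
align_genes <- function(atlas, panel) {
  stopifnot(inherits(atlas, "expression_atlas"),
            inherits(panel, "cell_type_panel"))
  shared <- atlas$gene_ids[atlas$gene_ids %in% panel$gene_ids]
  if (length(shared) == 0L) {
    stop("atlas and panel share no genes; cannot align", call. = FALSE)
  }
  dropped_atlas <- setdiff(atlas$gene_ids, shared)
  dropped_panel <- setdiff(panel$gene_ids, shared)
  if (length(dropped_atlas)) {
    message(length(dropped_atlas), " atlas gene(s) absent from panel, dropped")
  }
  if (length(dropped_panel)) {
    message(length(dropped_panel), " panel gene(s) absent from atlas, dropped")
  }
  new_atlas <- atlas
  new_atlas$values <- atlas$values[, shared, drop = FALSE]
  new_atlas$gene_ids <- shared
  new_panel <- panel
  new_panel$values <- panel$values[, shared, drop = FALSE]
  new_panel$gene_ids <- shared
  list(atlas = new_atlas, panel = new_panel)
}
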