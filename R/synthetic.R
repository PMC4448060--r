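# Synthetic world: a small 3D grid, a panel of cell types with disjoint
# marker blocks, sparse box-shaped spatial territories, and a linear
# composition with additive truncated-Gaussian noise. Planted cliques are
# subsets of one type's marker block, so downstream ranking has a known
# right answer.

#' Configuration of the synthetic atlas generator
#'
#' Defaults describe the stated testing world: an 8x8x8 grid, 6 cell types
#' with 20 disjoint marker genes each (10-fold over a baseline of 1),
#' a 300-gene panel, and additive Gaussian noise with sd 0.1 truncated at 0.
#'
#' @param grid_dims Grid dimensions `(nx, ny, nz)`.
#' @param n_types Number of cell types.
#' @param n_genes Number of genes.
#' @param markers_per_type Marker-block size per type; blocks are disjoint,
#'   so `markers_per_type * n_types <= n_genes`.
#' @param marker_strength Fold-increase of a marker gene in its own type
#'   relative to `baseline_expression`.
#' @param baseline_expression Expression of every non-marker entry.
#' @param noise_sd Standard deviation of the additive Gaussian residual on
#'   the composed atlas, truncated at 0.
#' @param seed Integer seed; all generator randomness flows from it.
#'
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(grid_dims = c(8L, 8L, 8L), n_types = 6L,
                             n_genes = 300L, markers_per_type = 20L,
                             marker_strength = 10, baseline_expression = 1,
                             noise_sd = 0.1, seed = 1L) {
  cfg <- list(grid_dims = as.integer(grid_dims), n_types = as.integer(n_types),
              n_genes = as.integer(n_genes),
              markers_per_type = as.integer(markers_per_type),
              marker_strength = as.numeric(marker_strength),
              baseline_expression = as.numeric(baseline_expression),
              noise_sd = as.numeric(noise_sd), seed = as.integer(seed))
  if (length(cfg$grid_dims) != 3L || any(cfg$grid_dims < 1L)) {
    stop("grid_dims must be three positive integers", call. = FALSE)
  }
  if (cfg$n_types < 1L || cfg$n_genes < 1L || cfg$markers_per_type < 1L) {
    stop("counts must be positive", call. = FALSE)
  }
  if (cfg$markers_per_type * cfg$n_types > cfg$n_genes) {
    stop("markers_per_type * n_types exceeds n_genes", call. = FALSE)
  }
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (cfg$baseline_expression <= 0 || cfg$marker_strength <= 0) {
    stop("baseline_expression and marker_strength must be > 0", call. = FALSE)
  }
  structure(cfg, class = "synthetic_config")
}

marker_block <- function(config, type) {
  # 1-based column indices of the disjoint marker block of `type` (1-based)
  start <- (type - 1L) * config$markers_per_type + 1L
  seq.int(start, start + config$markers_per_type - 1L)
}

#' Generate the synthetic cell-type panel
#'
#' Each type carries a disjoint block of `markers_per_type` marker genes at
#' `baseline_expression * marker_strength`; all other entries equal the
#' baseline. Deterministic given the config.
#'
#' @param config A [synthetic_config()].
#' @return A [cell_type_panel()] with labels `type_1 ... type_n`.
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$marker_strength == 1) {
    warning("marker_strength = 1 gives identical panel rows (degenerate panel)",
            call. = FALSE)
  }
  values <- matrix(config$baseline_expression,
                   nrow = config$n_types, ncol = config$n_genes)
  for (t in seq_len(config$n_types)) {
    values[t, marker_block(config, t)] <-
      config$baseline_expression * config$marker_strength
  }
  gene_ids <- sprintf("gene_%03d", seq_len(config$n_genes))
  cell_type_panel(values, sprintf("type_%d", seq_len(config$n_types)),
                  gene_ids)
}

voxel_grid_coords <- function(grid_dims) {
  # x varies fastest; coordinates are 0-based
  as.matrix(expand.grid(x = 0:(grid_dims[1] - 1L),
                        y = 0:(grid_dims[2] - 1L),
                        z = 0:(grid_dims[3] - 1L),
                        KEEP.OUT.ATTRS = FALSE))
}

#' Generate the synthetic density field and territory masks
#'
#' Every type's density is positive inside one contiguous axis-aligned
#' sub-box of the grid (its "territory") and exactly zero outside.
#' Territories are slabs along the longest grid axis, one per type, so all
#' of them — in particular the first two, the toy "cerebellum" and
#' "cortex" — are pairwise disjoint and the composed atlas is identifiable.
#' Magnitudes inside a territory are drawn uniform on `[0.5, 1.5]`.
#'
#' @param config A [synthetic_config()]. Randomness uses `config$seed + 1`.
#' @return A list with a [density_field()] (`field`) and a list of
#'   [region_mask()] territories (`masks`), one per type.
#' @export
generate_density_field <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  dims <- config$grid_dims
  axis <- which.max(dims)
  if (dims[axis] < config$n_types) {
    stop("grid too small: longest axis must hold one slab per type",
         call. = FALSE)
  }
  coords <- voxel_grid_coords(dims)
  n_voxels <- nrow(coords)
  # slab boundaries along the chosen axis, as equal as integer division allows
  cuts <- floor(seq(0, dims[axis], length.out = config$n_types + 1L))
  values <- matrix(0, nrow = n_voxels, ncol = config$n_types)
  masks <- vector("list", config$n_types)
  pos <- coords[, axis]
  with_seed(config$seed + 1L, {
    for (t in seq_len(config$n_types)) {
      inside <- which(pos >= cuts[t] & pos < cuts[t + 1L])
      values[inside, t] <- stats::runif(length(inside), 0.5, 1.5)
      masks[[t]] <- region_mask(sprintf("territory_type_%d", t),
                                inside - 1L, n_voxels)
    }
  })
  list(field = density_field(values, sprintf("type_%d",
                                             seq_len(config$n_types))),
       masks = masks)
}

#' Compose a synthetic expression atlas
#'
#' Linear composition `E = rho %*% C` plus i.i.d. Gaussian noise with sd
#' `config$noise_sd`, truncated at zero so atlas invariants hold;
#' `noise_sd = 0` gives the exact matrix product.
#'
#' @param field A [density_field()].
#' @param panel A [cell_type_panel()] with the same type dimension.
#' @param config A [synthetic_config()]. Noise uses `config$seed + 2`.
#' @return An [expression_atlas()].
#' @export
compose_atlas <- function(field, panel, config) {
  stopifnot(inherits(field, "density_field"),
            inherits(panel, "cell_type_panel"),
            inherits(config, "synthetic_config"))
  if (ncol(field$values) != nrow(panel$values)) {
    stop("field and panel disagree on the number of types", call. = FALSE)
  }
  values <- field$values %*% panel$values
  if (config$noise_sd > 0) {
    noise <- with_seed(config$seed + 2L,
                       matrix(stats::rnorm(length(values), 0, config$noise_sd),
                              nrow = nrow(values)))
    values <- pmax(values + noise, 0)
  }
  coords <- voxel_grid_coords(config$grid_dims)
  if (nrow(coords) != nrow(values)) {
    stop("field voxel count does not match config grid", call. = FALSE)
  }
  expression_atlas(values, panel$gene_ids, coords, config$grid_dims)
}

#' Plant a clique inside one type's marker block
#'
#' Samples `k` genes without replacement from the marker block of
#' `target_type`, producing a clique whose summed expression profile should
#' rank that type first.
#'
#' @param panel The synthetic [cell_type_panel()] (for gene ids).
#' @param config The [synthetic_config()] that built the panel.
#' @param target_type 1-based type index.
#' @param k Clique size, at most `markers_per_type`.
#' @param seed Seed for the draw.
#' @return A [gene_clique()] named after the target type.
#' @export
plant_clique <- function(panel, config, target_type, k, seed = config$seed + 3L) {
  stopifnot(inherits(panel, "cell_type_panel"),
            inherits(config, "synthetic_config"))
  if (target_type < 1L || target_type > config$n_types) {
    stop("target_type out of range", call. = FALSE)
  }
  block <- marker_block(config, target_type)
  if (k > length(block)) {
    stop("k exceeds the marker block size", call. = FALSE)
  }
  picked <- with_seed(seed, sort(sample(block, k)))
  gene_clique(sprintf("planted_type_%d", target_type),
              panel$gene_ids[picked])
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper running [generate_panel()],
#' [generate_density_field()], [compose_atlas()], and [plant_clique()].
#'
#' @param config A [synthetic_config()].
#' @param target_type 1-based index of the type the clique is planted in.
#' @param clique_size Number of genes in the planted clique.
#' @return A list: `panel`, `field` (ground-truth densities), `masks`,
#'   `atlas`, `clique`, `config`.
#' @export
synthesize_dataset <- function(config = synthetic_config(), target_type = 1L,
                               clique_size = 6L) {
  panel <- generate_panel(config)
  df <- generate_density_field(config)
  atlas <- compose_atlas(df$field, panel, config)
  clique <- plant_clique(panel, config, target_type, clique_size)
  list(panel = panel, field = df$field, masks = df$masks, atlas = atlas,
       clique = clique, config = config)
}
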