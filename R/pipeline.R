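# End-to-end orchestration: synthetic generation (optional), density
# deconvolution, clique scoring with threshold sweep, Monte Carlo
# significance, pair analysis, and region scoring, with every stage's TSV
# written under one output directory plus a run manifest. One top-level
# seed fans out to stage-specific child seeds by fixed offsets so stages
# can be re-run independently yet reproducibly.

#' Pipeline configuration
#'
#' Either `synthetic = TRUE` (a [synthetic_config()] world is generated)
#' or paths to an atlas, panel, clique, and optional mask on disk.
#'
#' @param output_dir Directory for result TSVs (created if missing).
#' @param synthetic Generate the inputs with the synthetic module.
#' @param synth_config A [synthetic_config()] used when `synthetic`.
#' @param target_type,clique_size Planted-clique settings (synthetic mode).
#' @param atlas_path,panel_path,clique_path,mask_path Input files
#'   (file mode).
#' @param mc A [monte_carlo_config()].
#' @param deconv [deconvolution_options()].
#' @param sweep_steps Threshold-sweep grid size.
#' @param report_threshold Pairs with `P_R` at or above this enter the
#'   significant-pair report (default 0.99).
#' @param seed Top-level seed; stage seeds are derived by fixed offsets.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(output_dir, synthetic = TRUE,
                            synth_config = NULL, target_type = 1L,
                            clique_size = 6L, atlas_path = NULL,
                            panel_path = NULL, clique_path = NULL,
                            mask_path = NULL, mc = NULL, deconv = NULL,
                            sweep_steps = 101L, report_threshold = 0.99,
                            seed = 1L) {
  if (report_threshold <= 0 || report_threshold >= 1) {
    stop("report_threshold must be in (0, 1)", call. = FALSE)
  }
  seed <- as.integer(seed)
  if (is.null(synth_config)) synth_config <- synthetic_config(seed = seed)
  if (is.null(mc)) mc <- monte_carlo_config(seed = seed + 10L)
  if (is.null(deconv)) deconv <- deconvolution_options()
  if (!synthetic) {
    for (p in c(atlas_path, panel_path, clique_path)) {
      if (is.null(p) || !file.exists(p)) {
        stop("file mode requires existing atlas/panel/clique paths",
             call. = FALSE)
      }
    }
  }
  structure(list(output_dir = output_dir, synthetic = synthetic,
                 synth_config = synth_config,
                 target_type = as.integer(target_type),
                 clique_size = as.integer(clique_size),
                 atlas_path = atlas_path, panel_path = panel_path,
                 clique_path = clique_path, mask_path = mask_path,
                 mc = mc, deconv = deconv,
                 sweep_steps = as.integer(sweep_steps),
                 report_threshold = report_threshold, seed = seed),
            class = "pipeline_config")
}

stage_log <- function(stage, t0) {
  message(sprintf("[%s] done in %.2fs", stage,
                  as.numeric(Sys.time()) - t0))
}

significance_report <- function(sig_table) {
  data.frame(cell_type = sig_table$type_label, rank = sig_table$rank,
             index_t = sig_table$type_index,
             P_R_pct = 100 * sig_table$P_R,
             psi_pct = 100 * sig_table$psi,
             stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes (synthetic generation), deconvolution, clique scoring with a
#' threshold sweep, Monte Carlo significance, pair fitting with pair
#' significance, and region scoring; writes all result TSVs plus a
#' `manifest.tsv` (seed, R, package version) under the output directory.
#' Output is identical for identical config and seed.
#'
#' @param config A [pipeline_config()].
#' @return A list of in-memory results (invisibly): `atlas`, `panel`,
#'   `fitted_field`, `profile`, `sweep`, `significance`, `pair_matrix`,
#'   `better`, `region_ranking`, `paths`.
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(name) file.path(config$output_dir, name)
  paths <- character(0)

  t0 <- as.numeric(Sys.time())
  masks <- NULL
  if (config$synthetic) {
    ds <- synthesize_dataset(config$synth_config, config$target_type,
                             config$clique_size)
    atlas <- ds$atlas; panel <- ds$panel; clique <- ds$clique
    masks <- ds$masks
    write_matrix(atlas, out("atlas.tsv"))
    write_matrix(panel, out("panel.tsv"))
    write_matrix(ds$field, out("true_densities.tsv"))
    write_gene_list(clique, out("clique.txt"))
    for (m in ds$masks) write_mask(m, out(sprintf("%s.mask", m$name)))
    paths <- c(paths, out(c("atlas.tsv", "panel.tsv", "true_densities.tsv",
                            "clique.txt")))
    stage_log("synth", t0)
  } else {
    atlas <- read_matrix(config$atlas_path, "voxels")
    panel <- read_matrix(config$panel_path, "types")
    aligned <- align_genes(atlas, panel)
    atlas <- aligned$atlas; panel <- aligned$panel
    clique <- read_gene_list(config$clique_path)
    if (!is.null(config$mask_path)) {
      masks <- list(read_mask(config$mask_path, atlas = atlas))
    }
  }

  t0 <- as.numeric(Sys.time())
  fitted <- fit_density_field(atlas, panel, config$deconv)
  write_matrix(fitted, out("fitted_densities.tsv"))
  stage_log("deconvolve", t0)

  t0 <- as.numeric(Sys.time())
  profile <- sum_expression(atlas, clique)
  ranking <- rank_by_similarity(profile, fitted)
  write_table(data.frame(cell_type = ranking$type_label,
                         index_t = ranking$type_index,
                         psi_pct = 100 * ranking$psi),
              out("similarity_ranking.tsv"))
  sweep <- threshold_sweep(profile, fitted, config$sweep_steps)
  sweep_df <- data.frame(tau = sweep$thresholds, sweep$similarities,
                         check.names = FALSE)
  write_table(sweep_df, out("threshold_sweep.tsv"))
  stage_log("cliquescore", t0)

  t0 <- as.numeric(Sys.time())
  observed <- numeric(ncol(fitted$values))
  observed[ranking$type_index] <- ranking$psi
  null <- simulate_null(atlas, fitted, profile$n_genes, config$mc)
  sig <- significance(observed, null)
  write_table(significance_report(sig), out("significance.tsv"))
  stage_log("significance", t0)

  t0 <- as.numeric(Sys.time())
  pm <- pair_similarity_matrix(profile, fitted)
  utils::write.table(round(pm, 6), out("pair_matrix.tsv"), sep = "\t",
                     quote = FALSE, col.names = NA)
  bp <- better_pairs(pm)
  bp <- pair_significance(atlas, fitted, bp, profile$n_genes, config$mc,
                          profile = profile)
  alphas <- t(vapply(seq_len(nrow(bp)), function(r) {
    fit_pair(profile, fitted$values[, bp$t1[r]],
             fitted$values[, bp$t2[r]])$alpha
  }, numeric(2)))
  bp_report <- data.frame(
    t1 = bp$t1, t2 = bp$t2,
    label_t1 = fitted$type_labels[bp$t1],
    label_t2 = fitted$type_labels[bp$t2],
    alpha1 = if (nrow(bp)) round(alphas[, 1], 4) else numeric(0),
    alpha2 = if (nrow(bp)) round(alphas[, 2], 4) else numeric(0),
    psi_pair_pct = 100 * bp$psi_pair, P_R_pct = 100 * bp$P_R,
    stringsAsFactors = FALSE)
  write_table(bp_report, out("better_pairs.tsv"))
  significant <- bp[bp$P_R >= config$report_threshold, , drop = FALSE]
  hist_counts <- pair_occurrence_histogram(significant,
                                           ncol(fitted$values))
  write_table(data.frame(index_t = seq_along(hist_counts),
                         count = hist_counts),
              out("pair_histogram.tsv"))
  stage_log("pairs", t0)

  region_ranking <- NULL
  if (!is.null(masks) && length(masks)) {
    t0 <- as.numeric(Sys.time())
    region_ranking <- rank_types_by_region(fitted, masks[[1L]])
    write_table(data.frame(cell_type = region_ranking$type_label,
                           index_t = region_ranking$type_index,
                           phi_pct = 100 * region_ranking$phi),
                out("region_ranking.tsv"))
    stage_log("regionscore", t0)
  }

  manifest <- data.frame(
    key = c("seed", "n_draws", "clique", "clique_size", "package_version"),
    value = c(config$seed, config$mc$n_draws, clique$name,
              profile$n_genes,
              as.character(utils::packageVersion("cliquecell"))))
  write_table(manifest, out("manifest.tsv"))

  invisible(list(atlas = atlas, panel = panel, fitted_field = fitted,
                 profile = profile, sweep = sweep, significance = sig,
                 pair_matrix = pm, better = bp,
                 region_ranking = region_ranking,
                 paths = list.files(config$output_dir, full.names = TRUE)))
}

#' Export a 2D grid slice as a portable graymap
#'
#' Writes one axis-aligned slice of a voxel-gridded field or profile as an
#' ASCII PGM (P2) image, values min-max scaled to 0..255.
#'
#' @param values Voxel vector (grid order: x fastest, then y, then z).
#' @param grid_dims Grid dimensions `(nx, ny, nz)`.
#' @param axis Slicing axis, 1 (x), 2 (y), or 3 (z).
#' @param index 0-based slice index along the axis.
#' @param path Output `.pgm` path.
#' @return `path`, invisibly.
#' @export
export_slices <- function(values, grid_dims, axis, index, path) {
  grid_dims <- as.integer(grid_dims)
  if (axis < 1L || axis > 3L) stop("axis must be 1, 2, or 3", call. = FALSE)
  if (index < 0L || index >= grid_dims[axis]) {
    stop("slice index out of range", call. = FALSE)
  }
  arr <- array(values, dim = grid_dims)
  slice <- switch(axis,
                  arr[index + 1L, , ],
                  arr[, index + 1L, ],
                  arr[, , index + 1L])
  rng <- range(slice)
  scaled <- if (rng[2] > rng[1]) {
    round(255 * (slice - rng[1]) / (rng[2] - rng[1]))
  } else {
    matrix(0L, nrow(slice), ncol(slice))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(scaled), nrow(scaled)), "255"), con)
  writeLines(apply(scaled, 1L, paste, collapse = " "), con)
  invisible(path)
}
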