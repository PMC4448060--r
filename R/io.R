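# On-disk formats are tab-delimited text with one header row: human
# inspectable and diff-friendly. Matrices carry one leading label column
# ("x:y:z" voxel coordinate triples, or type labels); gene lists and masks
# are one token per line.

format_coord_label <- function(coords) {
  apply(coords, 1L, paste, collapse = ":")
}

parse_coord_labels <- function(labels, path) {
  parts <- strsplit(labels, ":", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad)) {
    stop(sprintf("%s: row %d label '%s' is not an x:y:z triple",
                 path, bad[1L], labels[bad[1L]]), call. = FALSE)
  }
  coords <- suppressWarnings(
    matrix(as.integer(unlist(parts)), ncol = 3L, byrow = TRUE))
  if (anyNA(coords)) {
    stop(sprintf("%s: non-integer voxel coordinate label", path),
         call. = FALSE)
  }
  coords
}

#' Read a matrix file as an atlas or a panel
#'
#' Parses a tab-delimited text file with a header row of gene identifiers
#' and a leading label column: `"x:y:z"` voxel coordinates when
#' `orientation = "voxels"`, cell-type labels when `orientation = "types"`.
#'
#' @param path File path.
#' @param orientation `"voxels"` (rows are voxels, returns an
#'   [expression_atlas()]) or `"types"` (rows are cell types, returns a
#'   [cell_type_panel()]).
#' @param grid_dims Grid dimensions for the atlas; inferred as
#'   `max(coord) + 1` per axis when `NULL`.
#'
#' @return An `expression_atlas` or `cell_type_panel`.
#' @export
read_matrix <- function(path, orientation = c("voxels", "types"),
                        grid_dims = NULL) {
  orientation <- match.arg(orientation)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
  if (length(header) < 2L) {
    stop(sprintf("%s: header must hold a label column plus gene ids", path),
         call. = FALSE)
  }
  gene_ids <- header[-1L]
  if (anyDuplicated(gene_ids)) {
    stop(sprintf("%s: duplicate gene id '%s' in header", path,
                 gene_ids[duplicated(gene_ids)][1L]), call. = FALSE)
  }
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           colClasses = c("character",
                                          rep("numeric", length(gene_ids))),
                           stringsAsFactors = FALSE)
  labels <- tab[[1L]]
  values <- as.matrix(tab[, -1L, drop = FALSE])
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("%s: non-numeric value at row %d, column '%s'",
                 path, idx[1L], gene_ids[idx[2L]]), call. = FALSE)
  }
  if (any(values < 0)) {
    idx <- which(values < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("%s: negative value at row %d, column '%s'",
                 path, idx[1L], gene_ids[idx[2L]]), call. = FALSE)
  }
  if (orientation == "voxels") {
    coords <- parse_coord_labels(labels, path)
    if (is.null(grid_dims)) grid_dims <- apply(coords, 2L, max) + 1L
    expression_atlas(values, gene_ids, coords, grid_dims)
  } else {
    cell_type_panel(values, labels, gene_ids)
  }
}

#' Write an atlas, panel, or density field to tab-delimited text
#'
#' Inverse of [read_matrix()]; `read_matrix(write_matrix(x))` reproduces
#' `x` to full printed precision (values are written with 17 significant
#' digits). Density fields use type labels as the header.
#'
#' @param x An `expression_atlas`, `cell_type_panel`, or `density_field`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path) {
  if (inherits(x, "expression_atlas")) {
    labels <- format_coord_label(x$voxel_coords)
    header <- c("voxel", x$gene_ids)
  } else if (inherits(x, "cell_type_panel")) {
    labels <- x$type_labels
    header <- c("type", x$gene_ids)
  } else if (inherits(x, "density_field")) {
    labels <- as.character(seq_len(nrow(x$values)) - 1L)
    header <- c("voxel_index", x$type_labels)
  } else {
    stop("unsupported object for write_matrix", call. = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = "\t"), con)
  body <- cbind(labels, format(x$values, digits = 17, trim = TRUE,
                               scientific = FALSE))
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a gene clique from a one-symbol-per-line file
#'
#' @param path File path; one gene symbol per line, no duplicates.
#' @param name Clique name; default is the file's base name.
#' @return A [gene_clique()].
#' @export
read_gene_list <- function(path, name = tools::file_path_sans_ext(basename(path))) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    stop(sprintf("%s: empty gene list", path), call. = FALSE)
  }
  if (anyDuplicated(lines)) {
    stop(sprintf("%s: duplicate gene '%s'", path,
                 lines[duplicated(lines)][1L]), call. = FALSE)
  }
  gene_clique(name, lines)
}

#' @rdname read_gene_list
#' @param clique A [gene_clique()] to write.
#' @export
write_gene_list <- function(clique, path) {
  stopifnot(inherits(clique, "gene_clique"))
  writeLines(clique$gene_ids, path)
  invisible(path)
}

#' Read a region mask from a one-voxel-per-line file
#'
#' Each line is either a 0-based voxel row index or an `"x:y:z"` coordinate
#' triple (the latter requires `atlas` to resolve row indices).
#'
#' @param path File path.
#' @param n_voxels Atlas voxel count, for range validation.
#' @param atlas Optional [expression_atlas()] used to resolve `"x:y:z"`
#'   lines and to supply `n_voxels`.
#' @param name Mask name; default is the file's base name.
#' @return A [region_mask()].
#' @export
read_mask <- function(path, n_voxels = NULL, atlas = NULL,
                      name = tools::file_path_sans_ext(basename(path))) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop(sprintf("%s: empty mask", path), call. = FALSE)
  if (!is.null(atlas)) n_voxels <- nrow(atlas$values)
  if (any(grepl(":", lines, fixed = TRUE))) {
    if (is.null(atlas)) {
      stop(sprintf("%s: coordinate-triple mask needs an atlas", path),
           call. = FALSE)
    }
    coords <- parse_coord_labels(lines, path)
    key <- format_coord_label(coords)
    atlas_key <- format_coord_label(atlas$voxel_coords)
    idx <- match(key, atlas_key) - 1L
    if (anyNA(idx)) {
      stop(sprintf("%s: coordinate '%s' not in atlas", path,
                   key[which(is.na(idx))[1L]]), call. = FALSE)
    }
  } else {
    idx <- suppressWarnings(as.integer(lines))
    if (anyNA(idx)) {
      stop(sprintf("%s: non-integer voxel index '%s'", path,
                   lines[which(is.na(idx))[1L]]), call. = FALSE)
    }
    if (!is.null(n_voxels) && any(idx >= n_voxels)) {
      stop(sprintf("%s: voxel index %d out of range", path,
                   max(idx)), call. = FALSE)
    }
  }
  region_mask(name, idx, n_voxels)
}

#' @rdname read_mask
#' @param mask A [region_mask()] to write (one 0-based index per line).
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "region_mask"))
  writeLines(as.character(mask$voxel_indices), path)
  invisible(path)
}

#' Write a result table as TSV
#'
#' Tab-delimited output with a header row; numeric columns whose names end
#' in `_pct` are printed with one decimal, matching the layout of the
#' significance and pair reports.
#'
#' @param rows A data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  out <- rows
  for (nm in names(out)) {
    if (grepl("_pct$", nm) && is.numeric(out[[nm]])) {
      out[[nm]] <- sprintf("%.1f", out[[nm]])
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  utils::read.delim(path, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}
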