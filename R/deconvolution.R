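# Per-voxel nonnegative least squares against the transcriptome panel.
# The solver is Lawson-Hanson active-set on the normal equations: the
# type-by-type Gram matrix C C' is shared across all voxels, so a field fit
# costs one T x G product per voxel plus small T x T solves. Panel rows are
# fitted raw (no normalization); an optional L1 penalty enters the normal
# equations as a constant shift of the linear term.

#' Options for the density deconvolution
#'
#' @param l1_penalty Nonnegative coefficient of an optional L1 (sparsity)
#'   term added to the least-squares objective; 0 (the default) is the
#'   plain nonnegativity-constrained fit used for the main analysis.
#' @param tolerance Convergence tolerance on the residual-gradient
#'   (dual feasibility) criterion, relative to the problem scale.
#' @param max_iterations Cap on active-set iterations per voxel; defaults
#'   to `3 * n_types` at solve time when `NULL`.
#'
#' @return A `deconvolution_options` list.
#' @export
deconvolution_options <- function(l1_penalty = 0, tolerance = 1e-10,
                                  max_iterations = NULL) {
  if (l1_penalty < 0) stop("l1_penalty must be >= 0", call. = FALSE)
  if (tolerance <= 0) stop("tolerance must be > 0", call. = FALSE)
  structure(list(l1_penalty = as.numeric(l1_penalty),
                 tolerance = as.numeric(tolerance),
                 max_iterations = max_iterations),
            class = "deconvolution_options")
}

# Lawson-Hanson active-set NNLS posed on the normal equations:
#   min 0.5 nu' Q nu - b' nu  s.t. nu >= 0,
# with Q = C C' (types x types) and b = C e - l1/2. Deterministic: the
# entering variable is the largest gradient component, ties broken by the
# smallest index (R's which.max).
nnls_normal_eq <- function(Q, b, tolerance = 1e-10, max_iterations = NULL) {
  n <- length(b)
  if (is.null(max_iterations)) max_iterations <- max(3L * n, 30L)
  scale <- max(abs(b), diag(Q), 1e-300)
  tol <- tolerance * scale
  nu <- numeric(n)
  passive <- logical(n)
  w <- b            # gradient of -objective at nu = 0
  iter <- 0L
  repeat {
    free <- !passive
    if (!any(free) || max(w[free]) <= tol) break
    iter <- iter + 1L
    if (iter > max_iterations) break
    j <- which(free)[which.max(w[free])]
    passive[j] <- TRUE
    repeat {
      p <- which(passive)
      s <- numeric(n)
      sol <- tryCatch(solve(Q[p, p, drop = FALSE], b[p]),
                      error = function(e) NULL)
      if (is.null(sol)) {
        # singular passive block (duplicate panel rows): drop the entering
        # variable and move on
        passive[j] <- FALSE
        break
      }
      s[p] <- sol
      if (all(s[p] > 0)) {
        nu <- s
        break
      }
      neg <- p[s[p] <= 0]
      alpha <- min(nu[neg] / (nu[neg] - s[neg]))
      nu <- nu + alpha * (s - nu)
      passive[p][abs(nu[p]) <= .Machine$double.eps * scale] <- FALSE
      nu[!passive] <- 0
    }
    w <- b - drop(Q %*% nu)
  }
  pmax(nu, 0)
}

#' Fit the cell-type density of one voxel
#'
#' Solves the voxel-wise quadratic program
#' \deqn{\min_{\nu \ge 0} \sum_g (E(v,g) - \sum_t \nu(t) C(t,g))^2
#'       + \lambda \sum_t \nu(t)}
#' by the Lawson–Hanson active-set method.
#'
#' @param expression_row Numeric vector over genes (one atlas row).
#' @param panel A [cell_type_panel()], genes aligned with the row.
#' @param options [deconvolution_options()].
#' @return Nonnegative numeric vector of densities, one per type.
#' @export
fit_voxel_density <- function(expression_row, panel,
                              options = deconvolution_options()) {
  stopifnot(inherits(panel, "cell_type_panel"))
  expression_row <- as.numeric(expression_row)
  if (length(expression_row) != ncol(panel$values)) {
    stop("expression row length must equal panel gene count", call. = FALSE)
  }
  if (!all(is.finite(expression_row))) {
    stop("non-finite expression values", call. = FALSE)
  }
  if (all(panel$values == 0)) stop("all-zero panel", call. = FALSE)
  Q <- tcrossprod(panel$values)
  b <- drop(panel$values %*% expression_row) - options$l1_penalty / 2
  nu <- nnls_normal_eq(Q, b, options$tolerance, options$max_iterations)
  names(nu) <- panel$type_labels
  nu
}

#' Estimate the full density field
#'
#' Applies [fit_voxel_density()] independently at every voxel; rows of the
#' result depend only on the corresponding atlas row, so permuting voxels
#' permutes the output identically.
#'
#' @param atlas An [expression_atlas()], gene columns aligned with `panel`.
#' @param panel A [cell_type_panel()].
#' @param options [deconvolution_options()].
#' @return A [density_field()] of estimated densities.
#' @export
fit_density_field <- function(atlas, panel,
                              options = deconvolution_options()) {
  stopifnot(inherits(atlas, "expression_atlas"),
            inherits(panel, "cell_type_panel"))
  if (!identical(atlas$gene_ids, panel$gene_ids)) {
    stop("gene columns are not aligned; call align_genes() first",
         call. = FALSE)
  }
  if (all(panel$values == 0)) stop("all-zero panel", call. = FALSE)
  Q <- tcrossprod(panel$values)                  # T x T, shared
  B <- panel$values %*% t(atlas$values)          # T x V
  B <- B - options$l1_penalty / 2
  n_types <- nrow(panel$values)
  out <- matrix(0, nrow = nrow(atlas$values), ncol = n_types)
  for (v in seq_len(nrow(out))) {
    nu <- tryCatch(
      nnls_normal_eq(Q, B[, v], options$tolerance, options$max_iterations),
      error = function(e) {
        stop(sprintf("voxel %d (0-based %d): %s", v, v - 1L,
                     conditionMessage(e)), call. = FALSE)
      })
    out[v, ] <- nu
  }
  density_field(out, panel$type_labels)
}

#' Relative residual of a deconvolution
#'
#' Frobenius norm of `E - rho %*% C` divided by the Frobenius norm of `E`;
#' 0 for an exact fit, and 0 by convention when the atlas is all zeros.
#'
#' @param atlas An [expression_atlas()].
#' @param panel A [cell_type_panel()].
#' @param field A [density_field()].
#' @return Scalar in `[0, Inf)` (in `[0, 1]` whenever the zero field is a
#'   feasible competitor, e.g. for any least-squares fit).
#' @export
residual_fraction <- function(atlas, panel, field) {
  stopifnot(inherits(atlas, "expression_atlas"),
            inherits(panel, "cell_type_panel"),
            inherits(field, "density_field"))
  denom <- sqrt(sum(atlas$values^2))
  if (denom == 0) return(0)
  resid <- atlas$values - field$values %*% panel$values
  sqrt(sum(resid^2)) / denom
}
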