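# ---------------------------------------------------------------------------
# Spot deconvolution: regularized nonnegative least squares against
# cell-type expression signatures.
#
# This is a deliberately deterministic, desk-scale estimator of the
# spot x cell-type abundance matrix. It keeps the inputs (single-cell
# reference signatures on the gene intersection of the two modalities) and
# the output (nonnegative abundances per spot) of a full Bayesian
# deconvolution, while replacing the inference with a strictly convex
# least-squares problem solved exactly. The expected-cells-per-spot prior
# (default 8) sets the abundance scale and the uniform prior mass; the
# detection-sensitivity convention alpha = 20 maps to the relative ridge
# weight 1 / alpha (weaker pull to the prior for higher sensitivity). The
# effective lambda is 1/alpha times the mean squared signature norm, so the
# strength of the prior is invariant to panel size.
# ---------------------------------------------------------------------------

#' Deconvolution configuration
#'
#' @param expected_cells_per_spot prior number of cells mixed per spot
#'   (default 8); sets the scale of abundances and of the uniform prior.
#' @param alpha_sensitivity detection-sensitivity convention; the relative
#'   ridge weight defaults to `1 / alpha_sensitivity`.
#' @param regularization_weight nonnegative relative ridge weight pulling
#'   abundances toward the uniform prior; overrides `alpha_sensitivity`
#'   when given. The effective weight in the objective is this value times
#'   the mean squared column norm of the signature matrix, making the
#'   prior's strength independent of panel size.
#' @param tol convergence tolerance on the largest coordinate update.
#' @param max_iter iteration cap per spot; non-converged spots are flagged
#'   but their abundances still returned.
#' @return A list of class `deconvolution_config`.
#' @export
deconvolution_config <- function(expected_cells_per_spot = 8,
                                 alpha_sensitivity = 20,
                                 regularization_weight = NULL,
                                 tol = 1e-8, max_iter = 10000L) {
  stopifnot(expected_cells_per_spot > 0)
  if (is.null(regularization_weight))
    regularization_weight <- 1 / alpha_sensitivity
  stopifnot(regularization_weight >= 0)
  structure(list(expected_cells_per_spot = expected_cells_per_spot,
                 alpha_sensitivity = alpha_sensitivity,
                 regularization_weight = regularization_weight,
                 tol = tol, max_iter = as.integer(max_iter)),
            class = "deconvolution_config")
}

#' Build cell-type expression signatures on the shared gene set
#'
#' Each cell's raw counts are rescaled to a relative per-cell profile over
#' the genes shared between the single-cell and spatial panels; the
#' signature of a cell type is the mean relative profile of its cells
#' (columns sum to 1). All conditions are pooled, matching a reference
#' built once per tissue.
#'
#' @param cells a [cell_matrix()] (raw counts).
#' @param spot_genes character vector of genes on the spatial panel; the
#'   signature is restricted to `intersect(cell genes, spot_genes)`.
#' @param marker_genes_per_type optional integer: restrict the signature to
#'   the union over types of the `marker_genes_per_type` most
#'   discriminative genes per type (largest log fold of the type's mean
#'   relative expression over the mean of the other types). The default
#'   (`NULL`) keeps all shared genes. Restriction decorrelates the
#'   signatures, which sharpens presence/absence calls downstream at the
#'   cost of discarding shared expression.
#' @return A genes-by-types matrix of class `signature_matrix` whose columns
#'   sum to 1.
#' @export
build_signatures <- function(cells, spot_genes, marker_genes_per_type = NULL) {
  shared <- intersect(cells$gene_ids, spot_genes)
  if (!length(shared))
    stop("no genes shared between cell and spot panels", call. = FALSE)
  sub <- cells$counts[, shared, drop = FALSE]
  totals <- Matrix::rowSums(sub)
  if (any(totals == 0))
    stop("cells with zero counts on the shared gene set; filter them first",
         call. = FALSE)
  rel <- methods::as(Matrix::Diagonal(x = 1 / totals) %*% sub, "CsparseMatrix")
  types <- sort(unique(cells$cell_type))
  sig <- vapply(types, function(ty) {
    Matrix::colMeans(rel[cells$cell_type == ty, , drop = FALSE])
  }, numeric(length(shared)))
  sig <- matrix(sig, nrow = length(shared),
                dimnames = list(shared, types))
  if (!is.null(marker_genes_per_type)) {
    eps <- 1e-12
    keep <- unique(unlist(lapply(seq_along(types), function(t) {
      other <- rowMeans(sig[, -t, drop = FALSE])
      lfc <- log((sig[, t] + eps) / (other + eps))
      rownames(sig)[order(lfc, decreasing = TRUE)][
        seq_len(min(marker_genes_per_type, nrow(sig)))]
    })))
    sig <- sig[keep, , drop = FALSE]
    sig <- sweep(sig, 2, colSums(sig), "/")
  }
  structure(sig, class = c("signature_matrix", "matrix"))
}

# Projected coordinate descent for
#   min_{a >= 0} ||y - S a||^2 + lambda ||a - abar||^2
# using the precomputed Gram matrix G = S'S and b = S'y. Strictly convex for
# lambda > 0 (and for lambda = 0 when S has full column rank), so the
# solution is unique and the objective non-increasing across sweeps.
nnls_ridge <- function(b, G, abar, lambda, yty, init = abar,
                       tol = 1e-8, max_iter = 10000L, trace = FALSE) {
  a <- init
  K <- length(a)
  den <- diag(G) + lambda
  obj <- function(a) {
    yty - 2 * sum(b * a) + drop(crossprod(a, G %*% a)) +
      lambda * sum((a - abar)^2)
  }
  path <- if (trace) obj(a) else NULL
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    delta_max <- 0
    for (k in seq_len(K)) {
      num <- b[k] - sum(G[k, ] * a) + G[k, k] * a[k] + lambda * abar[k]
      ak_new <- if (den[k] > 0) max(0, num / den[k]) else 0
      delta_max <- max(delta_max, abs(ak_new - a[k]))
      a[k] <- ak_new
    }
    if (trace) path <- c(path, obj(a))
    if (delta_max < tol) { converged <- TRUE; break }
  }
  list(a = a, iterations = it, converged = converged, objective = path)
}

#' Deconvolve spots into cell-type abundances
#'
#' Per spot, the abundance vector `a` minimizes
#' `||y - S a||^2 + lambda ||a - abar||^2` subject to `a >= 0`, where `y`
#' is the spot's counts on the shared genes scaled to
#' `expected_cells_per_spot` cells' worth of signal, `S` the signature
#' matrix and `abar` the uniform prior summing to `expected_cells_per_spot`.
#' Solved to stationarity by projected coordinate descent.
#'
#' @param spots a [spot_matrix()] (raw counts).
#' @param signatures a [build_signatures()] result.
#' @param config a [deconvolution_config()].
#' @return A list of class `abundance_matrix` with `abundance` (spots x
#'   types), `sample_id`, `condition`, `converged` flags and the config.
#' @export
deconvolve <- function(spots, signatures, config = deconvolution_config()) {
  shared <- rownames(signatures)
  missing <- setdiff(shared, spots$gene_ids)
  if (length(missing))
    stop("signature genes absent from spot panel: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  S <- unclass(signatures)
  K <- ncol(S)
  n_cells <- config$expected_cells_per_spot
  abar <- rep(n_cells / K, K)
  G <- crossprod(S)
  lambda <- config$regularization_weight * mean(diag(G))
  Y <- Matrix::t(spots$counts[, shared, drop = FALSE])  # genes x spots
  totals <- Matrix::colSums(Y)
  scale <- ifelse(totals > 0, n_cells / totals, 0)
  Ys <- methods::as(Y %*% Matrix::Diagonal(x = scale), "CsparseMatrix")
  B <- as.matrix(crossprod(S, Ys))                       # K x spots
  yty <- Matrix::colSums(Ys^2)
  n_spots <- ncol(B)
  A <- matrix(0, nrow = n_spots, ncol = K,
              dimnames = list(spots$spot_ids, colnames(S)))
  converged <- logical(n_spots)
  for (i in seq_len(n_spots)) {
    if (totals[i] == 0) {
      # no data: the prior is the whole estimate
      A[i, ] <- abar
      converged[i] <- TRUE
      next
    }
    fit <- nnls_ridge(B[, i], G, abar, lambda, yty[i],
                      tol = config$tol, max_iter = config$max_iter)
    A[i, ] <- fit$a
    converged[i] <- fit$converged
  }
  if (any(!converged))
    warning(sum(!converged), " spots did not reach the solver tolerance",
            call. = FALSE)
  structure(list(abundance = A, sample_id = spots$sample_id,
                 condition = spots$condition, converged = converged,
                 config = config),
            class = "abundance_matrix")
}

#' Row-normalized cell-type proportions of an abundance matrix
#'
#' @param x an `abundance_matrix`.
#' @return spots-by-types matrix with rows summing to 1 (rows with zero
#'   total abundance stay zero).
#' @export
abundance_proportions <- function(x) {
  A <- x$abundance
  rs <- rowSums(A)
  P <- A / ifelse(rs > 0, rs, 1)
  P
}

#' @exportS3Method base::print
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("<abundance_matrix> %d spots x %d cell types | %d/%d converged\n",
              nrow(x$abundance), ncol(x$abundance), sum(x$converged),
              length(x$converged)))
  invisible(x)
}
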