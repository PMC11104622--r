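# ---------------------------------------------------------------------------
# Quality control and normalization. The same four thresholds are applied to
# cells and spots, whichever the technology delivers.
# ---------------------------------------------------------------------------

#' Quality-control thresholds
#'
#' A unit (cell or spot) is kept iff it has at least `min_counts` total
#' counts, at least `min_genes` expressed genes, a mitochondrial percentage
#' strictly below `max_mito_pct`, and a ratio
#' `log10(genes) / log10(counts)` of at least
#' `min_log10_genes_over_log10_counts`. The mitochondrial filter is strict
#' ("less than"); the other three are inclusive ("at least").
#'
#' @param min_counts minimum total counts per unit (default 500).
#' @param min_genes minimum expressed genes per unit (default 250).
#' @param max_mito_pct maximum mitochondrial percentage, exclusive
#'   (default 20).
#' @param min_log10_genes_over_log10_counts minimum of
#'   `log10(genes)/log10(counts)` (default 0.80).
#' @param mito_gene_prefix prefix identifying mitochondrial genes
#'   (default `"MT-"`, the human convention; set to a prefix absent from
#'   synthetic gene names to disable).
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_counts = 500, min_genes = 250,
                          max_mito_pct = 20,
                          min_log10_genes_over_log10_counts = 0.80,
                          mito_gene_prefix = "MT-") {
  stopifnot(is.finite(min_counts), is.finite(min_genes),
            is.finite(max_mito_pct), max_mito_pct >= 0, max_mito_pct <= 100,
            is.finite(min_log10_genes_over_log10_counts))
  structure(list(min_counts = min_counts, min_genes = min_genes,
                 max_mito_pct = max_mito_pct,
                 min_log10_genes_over_log10_counts =
                   min_log10_genes_over_log10_counts,
                 mito_gene_prefix = mito_gene_prefix),
            class = "qc_thresholds")
}

unit_ids <- function(x) if (inherits(x, "cell_matrix")) x$cell_ids else x$spot_ids

subset_units <- function(x, keep) {
  if (inherits(x, "cell_matrix")) {
    cell_matrix(x$counts[keep, , drop = FALSE], x$cell_type[keep],
                x$condition[keep], x$sample_id[keep])
  } else {
    spot_matrix(x$counts[keep, , drop = FALSE], x$xy[keep, , drop = FALSE],
                x$sample_id[keep], x$condition[keep])
  }
}

#' Filter cells or spots by the four quality-control thresholds
#'
#' Units with one or fewer counts are removed by the count filter and never
#' evaluated for the log ratio (which would be undefined there). The report
#' counts a unit once per criterion it fails, so per-criterion counts can
#' exceed the number of removed units.
#'
#' @param x a [cell_matrix()] or [spot_matrix()].
#' @param thresholds a [qc_thresholds()].
#' @return A list of class `qc_result` with elements `filtered` (same class
#'   as `x`), `report` (per-unit data.frame: unit_id, counts, genes,
#'   mito_pct, ratio, kept, reasons) and `summary` (per-criterion removal
#'   counts).
#' @export
qc_filter <- function(x, thresholds = qc_thresholds()) {
  th <- thresholds
  counts <- Matrix::rowSums(x$counts)
  genes <- Matrix::rowSums(x$counts > 0)
  mito <- startsWith(x$gene_ids, th$mito_gene_prefix)
  mito_pct <- if (any(mito)) {
    100 * Matrix::rowSums(x$counts[, mito, drop = FALSE]) / pmax(counts, 1)
  } else rep(0, length(counts))
  ratio <- rep(NA_real_, length(counts))
  ok_ratio_domain <- counts > 1
  ratio[ok_ratio_domain] <- log10(genes[ok_ratio_domain]) /
    log10(counts[ok_ratio_domain])
  fail_counts <- counts < th$min_counts
  fail_genes <- genes < th$min_genes
  fail_mito <- mito_pct >= th$max_mito_pct
  fail_ratio <- ok_ratio_domain &
    ratio < th$min_log10_genes_over_log10_counts
  kept <- !fail_counts & !fail_genes & !fail_mito & !fail_ratio &
    ok_ratio_domain
  reasons <- mapply(function(a, b, c, d) {
    paste(c("min_counts", "min_genes", "max_mito_pct", "min_ratio")[c(a, b, c, d)],
          collapse = ";")
  }, fail_counts, fail_genes, fail_mito,
     fail_ratio | (!ok_ratio_domain & !fail_counts))
  report <- data.frame(unit_id = unit_ids(x), counts = counts, genes = genes,
                       mito_pct = mito_pct, ratio = ratio, kept = kept,
                       reasons = unname(reasons), stringsAsFactors = FALSE)
  summary <- c(min_counts = sum(fail_counts), min_genes = sum(fail_genes),
               max_mito_pct = sum(fail_mito), min_ratio = sum(fail_ratio),
               removed = sum(!kept), kept = sum(kept))
  structure(list(filtered = subset_units(x, which(kept)), report = report,
                 summary = summary),
            class = "qc_result")
}

#' @exportS3Method base::print
print.qc_result <- function(x, ...) {
  cat(sprintf("<qc_result> kept %d of %d units (removed %d)\n",
              x$summary[["kept"]], nrow(x$report), x$summary[["removed"]]))
  invisible(x)
}

#' Library-size normalize and log-transform counts
#'
#' Each unit's counts are scaled to a common total (`scale_factor`, default
#' 10,000) and transformed with the natural `log1p`:
#' `value = ln(1 + scale_factor * count / row_total)`. Zero counts stay zero,
#' so sparsity is preserved. Unit annotations (type, condition, sample,
#' coordinates) are carried along so downstream stages need only this
#' object.
#'
#' @param x a [cell_matrix()] or [spot_matrix()] that passed QC (all row
#'   totals positive).
#' @param scale_factor common library size after scaling.
#' @return A list of class `normalized_matrix` with `values` (units x genes,
#'   sparse), `scale_factor`, `unit_kind` ("cell" or "spot") and the source
#'   annotations.
#' @export
normalize_counts <- function(x, scale_factor = 1e4) {
  totals <- Matrix::rowSums(x$counts)
  if (any(totals == 0))
    stop("cannot normalize units with zero total counts; run qc_filter first",
         call. = FALSE)
  scaled <- methods::as(Matrix::Diagonal(x = scale_factor / totals) %*% x$counts,
                        "CsparseMatrix")
  dimnames(scaled) <- dimnames(x$counts)
  scaled@x <- log1p(scaled@x)
  out <- structure(list(values = scaled, scale_factor = scale_factor,
                        gene_ids = x$gene_ids, unit_ids = unit_ids(x)),
                   class = "normalized_matrix")
  if (inherits(x, "cell_matrix")) {
    out$unit_kind <- "cell"
    out$cell_type <- x$cell_type
  } else {
    out$unit_kind <- "spot"
    out$xy <- x$xy
  }
  out$condition <- x$condition
  out$sample_id <- x$sample_id
  out
}
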