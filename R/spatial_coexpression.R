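# ---------------------------------------------------------------------------
# Minimum-principle spatial co-expression and per-slide spatial
# correlation.
# ---------------------------------------------------------------------------

#' Minimum-principle co-expression of a gene set across spots
#'
#' A spot's co-expression of a gene set is the minimum of the genes'
#' normalized expression there — the set is expressed at least at the level
#' of its weakest member. Scores below the noise threshold `t` are reported
#' as 0. For two-gene sets, each spot is additionally assigned a channel:
#' `co-expressed` when both genes exceed `t`, `gene1-only` / `gene2-only`
#' when exactly one does, `none` otherwise.
#'
#' A gene absent from the spot panel is an error naming the gene — absence
#' from the panel is a reportable finding, never a silent skip.
#'
#' @param spots_norm a `normalized_matrix` of spots (see
#'   [normalize_counts()]).
#' @param gene_set character vector of gene symbols (length >= 1).
#' @param threshold noise threshold `t >= 0` (default 0).
#' @return A data.frame of class `coexpression_map` with columns `spot_id,
#'   sample_id, condition, score` (and `channel` for two-gene sets);
#'   attributes `gene_set` and `threshold`.
#' @export
min_coexpression <- function(spots_norm, gene_set, threshold = 0) {
  stopifnot(threshold >= 0, length(gene_set) >= 1)
  absent <- setdiff(gene_set, spots_norm$gene_ids)
  if (length(absent))
    stop("gene(s) absent from spot panel: ", paste(absent, collapse = ", "),
         call. = FALSE)
  X <- as.matrix(spots_norm$values[, gene_set, drop = FALSE])
  score <- do.call(pmin, as.data.frame(X))
  score[score < threshold] <- 0
  out <- data.frame(spot_id = spots_norm$unit_ids,
                    sample_id = spots_norm$sample_id,
                    condition = spots_norm$condition,
                    score = score, stringsAsFactors = FALSE)
  if (length(gene_set) == 2) {
    p1 <- X[, 1] > threshold; p2 <- X[, 2] > threshold
    out$channel <- ifelse(p1 & p2, "co-expressed",
                          ifelse(p1, "gene1-only",
                                 ifelse(p2, "gene2-only", "none")))
  }
  attr(out, "gene_set") <- gene_set
  attr(out, "threshold") <- threshold
  class(out) <- c("coexpression_map", "data.frame")
  out
}

#' Co-expression map and per-slide summary for a ligand-receptor pair
#'
#' The gene set is the ligand plus every receptor subunit; the score is the
#' minimum over all of them and a spot counts as co-expressed when every
#' gene exceeds the threshold. The summary is the co-expressed fraction of
#' spots per slide.
#'
#' @param spots_norm a `normalized_matrix` of spots.
#' @param lr_record one-row subset of an [lr_database()].
#' @param threshold noise threshold (default 0).
#' @return List with `map` (a `coexpression_map`), and
#'   `fraction_by_slide` (data.frame `sample_id, condition, fraction`).
#' @export
pair_coexpression_for_hit <- function(spots_norm, lr_record, threshold = 0) {
  gene_set <- unique(c(lr_record$ligand, lr_record$receptor_subunits[[1]]))
  map <- min_coexpression(spots_norm, gene_set, threshold)
  X <- as.matrix(spots_norm$values[, gene_set, drop = FALSE])
  coexp <- rowSums(X > threshold) == length(gene_set)
  agg <- stats::aggregate(coexp,
                   by = list(sample_id = map$sample_id,
                             condition = map$condition),
                   FUN = mean)
  names(agg)[3] <- "fraction"
  list(map = map, fraction_by_slide = agg[order(agg$sample_id), ])
}

#' Per-slide Pearson correlation of two spot-level vectors
#'
#' Computes the Pearson correlation of `vector_a` and `vector_b` within
#' each slide (sample) separately; slides where either vector is constant
#' are reported missing and excluded from aggregation. The aggregate is the
#' median r across slides, overall and per condition.
#'
#' @param spots_norm a `normalized_matrix` of spots giving the slide and
#'   condition of each spot.
#' @param vector_a,vector_b numeric vectors aligned with the spots (e.g. a
#'   gene's normalized expression or a co-expression score).
#' @return A list of class `spatial_correlation` with `per_slide`
#'   (data.frame `sample_id, condition, r, n_spots`) and `aggregate`
#'   (data.frame `group, median_r, n_slides`; groups are `"all"` and each
#'   condition).
#' @export
spatial_correlation <- function(spots_norm, vector_a, vector_b) {
  n <- length(spots_norm$unit_ids)
  stopifnot(length(vector_a) == n, length(vector_b) == n)
  slides <- unique(data.frame(sample_id = spots_norm$sample_id,
                              condition = spots_norm$condition,
                              stringsAsFactors = FALSE))
  per <- do.call(rbind, lapply(seq_len(nrow(slides)), function(i) {
    idx <- spots_norm$sample_id == slides$sample_id[i]
    a <- vector_a[idx]; b <- vector_b[idx]
    r <- if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_
    else stats::cor(a, b)
    data.frame(sample_id = slides$sample_id[i],
               condition = slides$condition[i], r = r, n_spots = sum(idx),
               stringsAsFactors = FALSE)
  }))
  groups <- c("all", unique(per$condition))
  agg <- do.call(rbind, lapply(groups, function(g) {
    sub <- if (g == "all") per else per[per$condition == g, , drop = FALSE]
    ok <- !is.na(sub$r)
    data.frame(group = g,
               median_r = if (any(ok)) stats::median(sub$r[ok]) else NA_real_,
               n_slides = sum(ok), stringsAsFactors = FALSE)
  }))
  structure(list(per_slide = per, aggregate = agg),
            class = "spatial_correlation")
}

#' @exportS3Method base::print
print.spatial_correlation <- function(x, ...) {
  cat("<spatial_correlation>\n")
  print(x$aggregate, row.names = FALSE)
  invisible(x)
}
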