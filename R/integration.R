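# ---------------------------------------------------------------------------
# The filter chain: differential L-R results are intersected with spatial
# co-occurrence evidence and annotated with spatial co-expression, yielding
# ranked integrated hits with a full evidence trail.
# ---------------------------------------------------------------------------

#' Keep differential interactions whose cell types co-occur in space
#'
#' A row survives when its unordered (source, target) pair is classified
#' `positive` in at least one selected cluster (`"union"`, the default) or
#' in all of them (`"intersection"`). Self-pairs always survive: autocrine
#' signaling is not subject to the co-occurrence filter. Rows whose source
#' or target type is absent from the spatial cell-type set are dropped with
#' a warning.
#'
#' @param diff a `differential_lr` (see [differential_lr()]).
#' @param cooc_list list of `cooccurrence_result` tables, one per selected
#'   cluster.
#' @param combine_rule `"union"` or `"intersection"`.
#' @return The filtered `differential_lr`, with a `cooccurrence_class` and
#'   `supporting_clusters` column appended.
#' @export
apply_cooccurrence_filter <- function(diff, cooc_list,
                                      combine_rule = c("union",
                                                       "intersection")) {
  combine_rule <- match.arg(combine_rule)
  if (!length(cooc_list)) stop("no co-occurrence results given", call. = FALSE)
  spatial_types <- unique(unlist(lapply(cooc_list, function(cc)
    c(cc$type_a, cc$type_b))))
  pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  pos_by_cluster <- lapply(cooc_list, function(cc) {
    pos <- cc[cc$classification == "positive", , drop = FALSE]
    pair_key(pos$type_a, pos$type_b)
  })
  cluster_ids <- vapply(cooc_list, function(cc) cc$cluster_id[1], numeric(1))
  if (!nrow(diff)) {
    diff$cooccurrence_class <- character(0)
    diff$supporting_clusters <- character(0)
    return(diff)
  }
  known <- diff$source_type %in% spatial_types &
    diff$target_type %in% spatial_types
  if (any(!known)) {
    warning(sum(!known), " rows dropped: cell type absent from spatial set",
            call. = FALSE)
    diff <- diff[known, , drop = FALSE]
  }
  if (!nrow(diff)) {
    diff$cooccurrence_class <- character(0)
    diff$supporting_clusters <- character(0)
    return(diff)
  }
  keys <- pair_key(diff$source_type, diff$target_type)
  pos_mat <- vapply(pos_by_cluster, function(pk) keys %in% pk,
                    logical(nrow(diff)))
  pos_mat <- matrix(pos_mat, nrow = nrow(diff))
  is_self <- diff$source_type == diff$target_type
  n_pos <- rowSums(pos_mat)
  keep <- is_self |
    if (combine_rule == "union") n_pos >= 1 else n_pos == length(cooc_list)
  diff$cooccurrence_class <- ifelse(is_self, "positive",
                                    ifelse(n_pos > 0, "positive", "not-positive"))
  diff$supporting_clusters <- apply(pos_mat, 1, function(v)
    paste(cluster_ids[v], collapse = ";"))
  out <- diff[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build integrated hits with spatial co-expression evidence
#'
#' One hit per surviving differential interaction. Spatial co-expression is
#' attempted for each pair; a ligand or receptor subunit absent from the
#' spot panel becomes an evidence flag on the hit (mirroring probe-absence
#' findings) rather than an exclusion. When marker genes are supplied, the
#' hit is annotated with the median per-slide Pearson correlation between
#' its co-expression score and the markers' minimum-principle score. Hits
#' are ranked by `|ligand_lnFC| + |receptor_lnFC|` descending, ties broken
#' by `pair_id`.
#'
#' @param filtered_diff a `differential_lr` that passed
#'   [apply_cooccurrence_filter()].
#' @param spots_norm a `normalized_matrix` of spots.
#' @param lr_db an [lr_database()].
#' @param markers optional character vector of marker genes.
#' @param threshold co-expression noise threshold.
#' @param strict drop flagged hits instead of keeping them (default FALSE).
#' @return A data.frame of class `integrated_hits`.
#' @export
build_hits <- function(filtered_diff, spots_norm, lr_db, markers = NULL,
                       threshold = 0, strict = FALSE) {
  marker_score <- NULL
  if (!is.null(markers) && length(markers)) {
    marker_score <- tryCatch(
      min_coexpression(spots_norm, markers, threshold)$score,
      error = function(e) NULL)
  }
  rows <- lapply(seq_len(nrow(filtered_diff)), function(i) {
    row <- filtered_diff[i, , drop = FALSE]
    rec <- lr_db[lr_db$pair_id == row$pair_id, , drop = FALSE]
    class(rec) <- "data.frame"
    flags <- character()
    coexp_fraction <- NA_real_
    marker_r <- NA_real_
    res <- tryCatch(pair_coexpression_for_hit(spots_norm, rec, threshold),
                    error = function(e) e)
    if (inherits(res, "error")) {
      absent <- setdiff(c(rec$ligand, rec$receptor_subunits[[1]]),
                        spots_norm$gene_ids)
      flags <- c(flags,
                 if (rec$ligand %in% absent) "ligand-absent-from-panel",
                 if (length(setdiff(absent, rec$ligand)))
                   "receptor-subunit-absent-from-panel")
    } else {
      coexp_fraction <- mean(res$fraction_by_slide$fraction)
      if (!is.null(marker_score)) {
        sc <- spatial_correlation(spots_norm, res$map$score, marker_score)
        marker_r <- sc$aggregate$median_r[sc$aggregate$group == "all"]
      }
    }
    data.frame(row,
               coexpressed_fraction = coexp_fraction,
               marker_correlation = marker_r,
               evidence_flags = paste(flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  hits <- if (length(rows)) do.call(rbind, rows) else
    cbind(filtered_diff,
          data.frame(coexpressed_fraction = numeric(0),
                     marker_correlation = numeric(0),
                     evidence_flags = character(0)))
  if (strict && nrow(hits)) hits <- hits[hits$evidence_flags == "", ,
                                         drop = FALSE]
  if (nrow(hits)) {
    ord <- order(-(abs(hits$ligand_lnFC) + abs(hits$receptor_lnFC)),
                 hits$pair_id)
    hits <- hits[ord, , drop = FALSE]
  }
  rownames(hits) <- NULL
  class(hits) <- c("integrated_hits", "data.frame")
  hits
}

#' Pipeline configuration
#'
#' Composite of the stage configurations plus the study design: which
#' comparisons to run, which conditions count as diseased, which cell
#' types and markers drive cluster selection and spatial validation.
#'
#' @param qc a [qc_thresholds()].
#' @param deconv a [deconvolution_config()].
#' @param comm a [communication_config()].
#' @param comparisons list of length-2 character vectors.
#' @param pooled named list of pooled condition definitions.
#' @param diseased_conditions condition labels counted as diseased; default
#'   all but the first condition seen among the cells.
#' @param types_of_interest cell types driving automatic cluster selection;
#'   default all spatial types.
#' @param k_range candidate cluster numbers.
#' @param n_selected_clusters clusters carried into co-occurrence.
#' @param manual_clusters optional manual cluster selection.
#' @param presence_threshold,cooccurrence_alpha co-occurrence parameters.
#' @param combine_rule `"union"` or `"intersection"` across selected
#'   clusters.
#' @param markers marker genes for spatial correlation annotation.
#' @param coexpression_threshold noise threshold for co-expression maps.
#' @param strict drop hits with failed spatial co-expression.
#' @param seed master seed; every stochastic stage derives from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(qc = qc_thresholds(),
                            deconv = deconvolution_config(),
                            comm = communication_config(),
                            comparisons = list(),
                            pooled = list(),
                            diseased_conditions = NULL,
                            types_of_interest = NULL,
                            k_range = 1:15,
                            n_selected_clusters = 2,
                            manual_clusters = NULL,
                            presence_threshold = 0.05,
                            cooccurrence_alpha = 0.05,
                            combine_rule = "union",
                            markers = NULL,
                            coexpression_threshold = 0,
                            strict = FALSE,
                            seed = 1L) {
  if (!length(comparisons))
    stop("pipeline_config needs at least one comparison", call. = FALSE)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full discovery pipeline
#'
#' QC and normalize both modalities; score per-condition communication and
#' differential L-R on the cells; deconvolve, cluster and classify
#' co-occurrence on the spots; intersect; annotate surviving pairs with
#' spatial co-expression. Every stage's table is written under `out_dir`
#' along with a JSON run manifest; the run is deterministic given the
#' config seed.
#'
#' @param cells a [cell_matrix()].
#' @param spots a [spot_matrix()].
#' @param lr_db an [lr_database()].
#' @param config a [pipeline_config()].
#' @param out_dir output directory for stage TSVs and the manifest
#'   (`NULL` to skip writing).
#' @return List with `hits` (named by comparison), `communication`,
#'   `differential`, `summary`, `clustering`, `selected_clusters`,
#'   `cooccurrence`, `abundance`, `qc` reports and `manifest_path`.
#' @export
run_pipeline <- function(cells, spots, lr_db, config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- character()
  emit <- function(name, df) {
    stages <<- c(stages, name)
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write_tsv(as.data.frame(df), file.path(out_dir, paste0(name, ".tsv")))
    }
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  # --- quality control and normalization
  qc_cells <- run_stage("qc_cells", qc_filter(cells, config$qc))
  qc_spots <- run_stage("qc_spots", qc_filter(spots, config$qc))
  emit("qc_cells", qc_cells$report)
  emit("qc_spots", qc_spots$report)
  cells_f <- qc_cells$filtered
  spots_f <- qc_spots$filtered
  cells_norm <- run_stage("normalize_cells", normalize_counts(cells_f))
  spots_norm <- run_stage("normalize_spots", normalize_counts(spots_f))
  stages <- c(stages, "normalize_cells", "normalize_spots")
  # --- communication + differential L-R
  cmp <- run_stage("communication",
                   run_comparisons(cells_norm, config$comparisons, lr_db,
                                   config$comm, config$pooled,
                                   seed = config$seed))
  emit("communication", cmp$communication)
  emit("differential_summary", cmp$summary)
  # --- spatial side
  sig <- run_stage("signatures", build_signatures(cells_f, spots_f$gene_ids))
  ab <- run_stage("deconvolve", deconvolve(spots_f, sig, config$deconv))
  emit("abundance", data.frame(spot_id = rownames(ab$abundance),
                               sample_id = ab$sample_id,
                               condition = ab$condition, ab$abundance,
                               check.names = FALSE))
  clustering <- run_stage("compose",
                          cluster_compositions(ab, config$k_range,
                                               seed = config$seed))
  emit("wss", data.frame(k = clustering$k, wss = clustering$wss))
  emit("clusters", data.frame(spot_id = rownames(ab$abundance),
                              cluster = clustering$labels))
  diseased <- config$diseased_conditions
  if (is.null(diseased))
    diseased <- setdiff(unique(cells$condition), unique(cells$condition)[1])
  toi <- config$types_of_interest
  if (is.null(toi)) toi <- colnames(ab$abundance)
  selected <- run_stage("select_clusters",
                        select_clusters(clustering, ab,
                                        diseased_conditions = diseased,
                                        types_of_interest = toi,
                                        m = config$n_selected_clusters,
                                        manual = config$manual_clusters))
  cooc <- run_stage("cooccur", lapply(selected, function(cl)
    cooccurrence(ab, clustering, cl, config$presence_threshold,
                 config$cooccurrence_alpha)))
  emit("cooccurrence", do.call(rbind, cooc))
  # --- filter chain + hits
  hits <- list()
  for (nm in names(cmp$differential)) {
    filt <- run_stage("cooccurrence_filter",
                      apply_cooccurrence_filter(cmp$differential[[nm]], cooc,
                                                config$combine_rule))
    h <- run_stage("build_hits",
                   build_hits(filt, spots_norm, lr_db,
                              markers = config$markers,
                              threshold = config$coexpression_threshold,
                              strict = config$strict))
    h <- cbind(comparison = rep(nm, nrow(h)), h)
    hits[[nm]] <- h
  }
  stages <- c(stages, "cooccurrence_filter", "build_hits")
  all_hits <- do.call(rbind, c(lapply(hits, as.data.frame),
                               list(make.row.names = FALSE)))
  emit("hits", all_hits)
  manifest_path <- NULL
  if (!is.null(out_dir)) {
    manifest_path <- file.path(out_dir, "manifest.json")
    cfg_snapshot <- config
    cfg_snapshot$comparisons <- lapply(config$comparisons, paste,
                                       collapse = " vs ")
    write_manifest(manifest_path,
                   config = lapply(cfg_snapshot, function(x)
                     if (is.list(x) && !is.null(class(x))) unclass(x) else x),
                   stages = stages, seed = config$seed)
  }
  list(hits = hits, all_hits = all_hits, communication = cmp$communication,
       differential = cmp$differential, summary = cmp$summary,
       clustering = clustering, selected_clusters = selected,
       cooccurrence = cooc, abundance = ab,
       qc = list(cells = qc_cells, spots = qc_spots),
       manifest_path = manifest_path)
}

#' Join two runs' hit tables on shared interactions
#'
#' Cross-tissue comparison: inner join of two hit tables on `pair_id`, with
#' each side's direction kept, flagging whether the shared interaction
#' moves the same way in both tissues.
#'
#' @param hits_a,hits_b `integrated_hits` tables.
#' @param suffixes length-2 character suffixes for the two sides.
#' @return data.frame of shared pairs with directions from both runs.
#' @export
common_interactions <- function(hits_a, hits_b, suffixes = c("_a", "_b")) {
  shared <- intersect(unique(hits_a$pair_id), unique(hits_b$pair_id))
  a <- hits_a[hits_a$pair_id %in% shared,
              c("pair_id", "source_type", "target_type", "direction")]
  b <- hits_b[hits_b$pair_id %in% shared,
              c("pair_id", "source_type", "target_type", "direction")]
  out <- merge(a, b, by = "pair_id", suffixes = suffixes)
  out$same_direction <- out[[paste0("direction", suffixes[1])]] ==
    out[[paste0("direction", suffixes[2])]]
  out
}
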