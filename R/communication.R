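# ---------------------------------------------------------------------------
# Cell-cell communication scoring and differential ligand-receptor
# analysis.
#
# The scoring follows the documented defaults of the standard communication
# inference toolkit: group expression summarized by Tukey's trimean,
# multi-subunit receptor complexes combined by geometric mean (zero if any
# subunit is absent), interaction intensity by a bounded Hill mass-action
# term L*R / (Kh + L*R), and significance by a cell-type label permutation
# null with an add-one p-value.
# ---------------------------------------------------------------------------

#' Communication scoring configuration
#'
#' @param hill_constant half-saturation constant `Kh` of the mass-action
#'   score (default 0.5).
#' @param n_permutations label permutations for the null (default 100).
#' @param significance_alpha p-value threshold for a significant
#'   interaction (default 0.05).
#' @param min_cells_per_type cell types with fewer cells in a condition are
#'   excluded from scoring (default 10).
#' @param lnfc_threshold minimum absolute natural-log fold change for
#'   differential ligands and receptors (default 0.1).
#' @param padj_threshold Benjamini-Hochberg adjusted p-value threshold for
#'   differential ligands and receptors (default 0.05).
#' @param epsilon guard added to de-logged means before taking logs in the
#'   fold-change estimator.
#' @return A list of class `communication_config`.
#' @export
communication_config <- function(hill_constant = 0.5,
                                 n_permutations = 100L,
                                 significance_alpha = 0.05,
                                 min_cells_per_type = 10L,
                                 lnfc_threshold = 0.1,
                                 padj_threshold = 0.05,
                                 epsilon = 1e-9) {
  stopifnot(hill_constant > 0, n_permutations >= 1)
  structure(list(hill_constant = hill_constant,
                 n_permutations = as.integer(n_permutations),
                 significance_alpha = significance_alpha,
                 min_cells_per_type = as.integer(min_cells_per_type),
                 lnfc_threshold = lnfc_threshold,
                 padj_threshold = padj_threshold,
                 epsilon = epsilon),
            class = "communication_config")
}

#' Tukey trimean
#'
#' `(Q1 + 2 Q2 + Q3) / 4` with quartiles by linear interpolation of order
#' statistics (R's default quantile definition).
#'
#' @param x numeric vector.
#' @return The trimean.
#' @export
trimean <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  (q[1] + 2 * q[2] + q[3]) / 4
}

# column-wise trimean of a dense matrix, vectorized over columns
trimean_cols <- function(X) {
  n <- nrow(X)
  if (n == 1L) return(X[1, ])
  Xs <- apply(X, 2, sort.int, method = "quick")
  qrow <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    Xs[lo, ] + (h - lo) * (Xs[hi, ] - Xs[lo, ])
  }
  (qrow(0.25) + 2 * qrow(0.5) + qrow(0.75)) / 4
}

#' Summarize a gene's expression in a cell type
#'
#' @param cells_norm a `normalized_matrix` of cells (see
#'   [normalize_counts()]).
#' @param gene gene symbol.
#' @param cell_type cell-type label.
#' @param config a [communication_config()]; types with fewer than
#'   `min_cells_per_type` cells raise an error.
#' @return The trimean of the gene's normalized expression over the type's
#'   cells.
#' @export
group_expression <- function(cells_norm, gene, cell_type,
                             config = communication_config()) {
  if (!gene %in% cells_norm$gene_ids)
    stop("gene not in panel: ", gene, call. = FALSE)
  idx <- cells_norm$cell_type == cell_type
  if (sum(idx) < config$min_cells_per_type)
    stop(sprintf("cell type %s has %d cells, fewer than min_cells_per_type = %d",
                 cell_type, sum(idx), config$min_cells_per_type),
         call. = FALSE)
  trimean(as.numeric(cells_norm$values[idx, gene]))
}

#' Combine receptor subunit levels into a complex level
#'
#' Geometric mean of the subunit levels; zero if any subunit level is zero
#' (a complex missing a subunit cannot signal).
#'
#' @param levels numeric vector of subunit levels (length >= 1).
#' @return The complex level.
#' @export
complex_level <- function(levels) {
  stopifnot(length(levels) >= 1)
  if (any(levels == 0)) return(0)
  exp(mean(log(levels)))
}

#' Hill mass-action interaction score
#'
#' `score = L R / (Kh + L R)`: zero when either side is absent, saturating
#' toward 1 as the ligand-receptor product grows.
#'
#' @param L,R nonnegative ligand and receptor levels.
#' @param config a [communication_config()] providing `Kh`.
#' @return Score in `[0, 1)`.
#' @export
score_interaction <- function(L, R, config = communication_config()) {
  p <- L * R
  p / (config$hill_constant + p)
}

# ligand and receptor level matrices (types x pairs) from a trimean matrix
# M (types x genes, with gene columns named)
lr_levels <- function(M, lr_db) {
  Lmat <- M[, lr_db$ligand, drop = FALSE]
  Rmat <- matrix(0, nrow = nrow(M), ncol = nrow(lr_db),
                 dimnames = list(rownames(M), lr_db$pair_id))
  for (i in seq_len(nrow(lr_db))) {
    su <- lr_db$receptor_subunits[[i]]
    if (length(su) == 1L) {
      Rmat[, i] <- M[, su]
    } else {
      block <- M[, su, drop = FALSE]
      r <- exp(rowMeans(log(pmax(block, .Machine$double.xmin))))
      r[apply(block == 0, 1, any)] <- 0
      Rmat[, i] <- r
    }
  }
  colnames(Lmat) <- lr_db$pair_id
  list(L = Lmat, R = Rmat)
}

#' Score all ligand-receptor interactions per condition with a permutation
#' null
#'
#' For every condition, every ordered (source type, target type) pair of
#' eligible cell types and every database record, computes the Hill
#' mass-action score from trimean-summarized normalized expression, and an
#' add-one permutation p-value obtained by shuffling cell-type labels
#' within the condition `n_permutations` times:
#' `p = (#(perm score >= observed) + 1) / (n_permutations + 1)`.
#'
#' @param cells_norm a `normalized_matrix` of cells.
#' @param lr_db an [lr_database()]; records whose ligand or subunits are
#'   absent from the cell panel are dropped with a warning.
#' @param config a [communication_config()].
#' @param seed integer seed for the permutations.
#' @param conditions conditions to score (default: all present). A named
#'   list entry of several labels defines a pooled condition scored on the
#'   union of its cells.
#' @return A data.frame of class `communication_result` with columns
#'   `condition, source_type, target_type, pair_id, ligand_level,
#'   receptor_level, score, p_value`.
#' @export
communication_scores <- function(cells_norm, lr_db,
                                 config = communication_config(),
                                 seed = 1L, conditions = NULL) {
  genes_needed <- unique(c(lr_db$ligand, unlist(lr_db$receptor_subunits)))
  present <- genes_needed %in% cells_norm$gene_ids
  if (any(!present)) {
    drop <- vapply(seq_len(nrow(lr_db)), function(i) {
      any(!c(lr_db$ligand[i], lr_db$receptor_subunits[[i]]) %in%
            cells_norm$gene_ids)
    }, logical(1))
    warning(sum(drop), " L-R records dropped: genes absent from cell panel",
            call. = FALSE)
    lr_db <- lr_db[!drop, , drop = FALSE]
    class(lr_db) <- c("lr_database", "data.frame")
  }
  if (!nrow(lr_db)) stop("no scorable L-R records", call. = FALSE)
  genes_used <- unique(c(lr_db$ligand, unlist(lr_db$receptor_subunits)))
  if (is.null(conditions)) conditions <- unique(cells_norm$condition)
  if (!is.list(conditions))
    conditions <- stats::setNames(as.list(conditions), conditions)
  if (is.null(names(conditions)))
    names(conditions) <- vapply(conditions, paste, character(1),
                                collapse = "+")
  set.seed(seed)
  out <- list()
  for (cname in names(conditions)) {
    in_cond <- cells_norm$condition %in% conditions[[cname]]
    labels <- cells_norm$cell_type[in_cond]
    tab <- table(labels)
    types <- sort(names(tab)[tab >= config$min_cells_per_type])
    if (length(types) < 1) next
    eligible <- labels %in% types
    X <- as.matrix(cells_norm$values[which(in_cond)[eligible], genes_used,
                                     drop = FALSE])
    labs <- labels[eligible]
    tri_by_type <- function(lb) {
      M <- t(vapply(types, function(ty)
        trimean_cols(X[lb == ty, , drop = FALSE]), numeric(ncol(X))))
      dimnames(M) <- list(types, genes_used)
      M
    }
    M_obs <- tri_by_type(labs)
    lv <- lr_levels(M_obs, lr_db)
    n_t <- length(types); n_p <- nrow(lr_db)
    prod_obs <- array(0, dim = c(n_t, n_t, n_p))
    for (i in seq_len(n_p))
      prod_obs[, , i] <- outer(lv$L[, i], lv$R[, i])
    exceed <- array(0L, dim = dim(prod_obs))
    for (b in seq_len(config$n_permutations)) {
      Mp <- tri_by_type(sample(labs))
      lvp <- lr_levels(Mp, lr_db)
      for (i in seq_len(n_p)) {
        pp <- outer(lvp$L[, i], lvp$R[, i])
        exceed[, , i] <- exceed[, , i] + (pp >= prod_obs[, , i])
      }
    }
    pval <- (exceed + 1) / (config$n_permutations + 1)
    score <- prod_obs / (config$hill_constant + prod_obs)
    grid <- expand.grid(source_type = types, target_type = types,
                        pair_idx = seq_len(n_p), stringsAsFactors = FALSE)
    out[[cname]] <- data.frame(
      condition = cname,
      source_type = grid$source_type,
      target_type = grid$target_type,
      pair_id = lr_db$pair_id[grid$pair_idx],
      ligand_level = lv$L[cbind(match(grid$source_type, types),
                                grid$pair_idx)],
      receptor_level = lv$R[cbind(match(grid$target_type, types),
                                  grid$pair_idx)],
      score = as.vector(score),
      p_value = as.vector(pval),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("communication_result", "data.frame")
  res
}

#' Permutation p-value for a single interaction
#'
#' Reference implementation for one (source, target, pair) triple: shuffles
#' cell-type labels within the given condition and compares permuted Hill
#' scores against the observed one with the add-one estimator.
#'
#' @param cells_norm a `normalized_matrix` of cells.
#' @param lr_record one-row subset of an [lr_database()].
#' @param source_type,target_type cell-type labels.
#' @param config a [communication_config()].
#' @param seed integer seed.
#' @param condition condition label to restrict to (default: use all cells).
#' @return List with `score` and `p_value`.
#' @export
permutation_test <- function(cells_norm, lr_record, source_type, target_type,
                             config = communication_config(), seed = 1L,
                             condition = NULL) {
  in_cond <- if (is.null(condition)) rep(TRUE, length(cells_norm$condition))
  else cells_norm$condition == condition
  labels <- cells_norm$cell_type[in_cond]
  for (ty in unique(c(source_type, target_type)))
    if (sum(labels == ty) < config$min_cells_per_type)
      stop("too few cells of type ", ty, call. = FALSE)
  genes <- c(lr_record$ligand, lr_record$receptor_subunits[[1]])
  X <- as.matrix(cells_norm$values[in_cond, genes, drop = FALSE])
  score_of <- function(lb) {
    L <- trimean(X[lb == source_type, 1])
    R <- complex_level(vapply(seq_along(lr_record$receptor_subunits[[1]]),
                              function(k) trimean(X[lb == target_type, k + 1]),
                              numeric(1)))
    score_interaction(L, R, config)
  }
  obs <- score_of(labels)
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(config$n_permutations))
    if (score_of(sample(labels)) >= obs) exceed <- exceed + 1L
  list(score = obs, p_value = (exceed + 1) / (config$n_permutations + 1))
}

resolve_condition <- function(name, pooled, available) {
  if (!is.null(pooled[[name]])) {
    labs <- pooled[[name]]
  } else {
    labs <- name
  }
  unknown <- setdiff(labs, available)
  if (length(unknown))
    stop("unknown condition label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  labs
}

#' Differential ligand-receptor analysis between two conditions
#'
#' For each candidate interaction, the ligand is tested in the source type
#' and every receptor subunit in the target type: a two-sided Wilcoxon
#' rank-sum test of normalized expression between the two conditions, with
#' the natural-log fold change estimated on de-logged means,
#' `lnFC = ln(mean(expm1(B)) + eps) - ln(mean(expm1(A)) + eps)` (second
#' condition over first, so positive means up in the second-named,
#' diseased, condition). P-values are Benjamini-Hochberg adjusted over all
#' genes tested within a cell type. An interaction is kept when ligand and
#' all receptor subunits pass `|lnFC| >= lnfc_threshold` and
#' `padj < padj_threshold` with one shared sign; the complex fold change is
#' the subunit mean and the complex adjusted p the subunit maximum.
#'
#' @param cells_norm a `normalized_matrix` of cells.
#' @param comparison length-2 character vector `(condA, condB)`; pooled
#'   names are resolved through `pooled`.
#' @param significant_interactions data.frame with columns `source_type`,
#'   `target_type`, `pair_id` — the interactions to test (normally those
#'   significant in at least one of the two conditions).
#' @param lr_db an [lr_database()].
#' @param config a [communication_config()].
#' @param pooled named list mapping pooled condition names to vectors of
#'   primitive condition labels (e.g. `list(MASH = c("F1-F2", "F3-F4"))`).
#' @return A data.frame of class `differential_lr` with the kept rows
#'   (`source_type, target_type, pair_id, ligand_lnFC, receptor_lnFC,
#'   ligand_padj, receptor_padj, direction`); the full per-interaction test
#'   table is in `attr(, "tested")`.
#' @export
differential_lr <- function(cells_norm, comparison, significant_interactions,
                            lr_db, config = communication_config(),
                            pooled = list()) {
  stopifnot(length(comparison) == 2)
  avail <- unique(cells_norm$condition)
  labsA <- resolve_condition(comparison[1], pooled, avail)
  labsB <- resolve_condition(comparison[2], pooled, avail)
  inA <- cells_norm$condition %in% labsA
  inB <- cells_norm$condition %in% labsB
  si <- unique(significant_interactions[, c("source_type", "target_type",
                                            "pair_id")])
  si <- si[si$pair_id %in% lr_db$pair_id, , drop = FALSE]
  empty <- data.frame(source_type = character(), target_type = character(),
                      pair_id = character(), ligand_lnFC = numeric(),
                      receptor_lnFC = numeric(), ligand_padj = numeric(),
                      receptor_padj = numeric(), direction = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(si)) {
    class(empty) <- c("differential_lr", "data.frame")
    attr(empty, "comparison") <- comparison
    attr(empty, "tested") <- empty
    return(empty)
  }
  rec <- match(si$pair_id, lr_db$pair_id)
  # unique (cell type, gene) tasks
  tasks <- unique(rbind(
    data.frame(type = si$source_type, gene = lr_db$ligand[rec],
               stringsAsFactors = FALSE),
    do.call(rbind, lapply(seq_len(nrow(si)), function(i)
      data.frame(type = si$target_type[i],
                 gene = lr_db$receptor_subunits[[rec[i]]],
                 stringsAsFactors = FALSE)))))
  missing <- setdiff(unique(tasks$gene), cells_norm$gene_ids)
  if (length(missing))
    stop("genes absent from cell panel: ", paste(missing, collapse = ", "),
         call. = FALSE)
  tasks$p <- NA_real_; tasks$lnfc <- NA_real_; tasks$padj <- NA_real_
  eps <- config$epsilon
  for (ty in unique(tasks$type)) {
    rows <- which(tasks$type == ty)
    selA <- inA & cells_norm$cell_type == ty
    selB <- inB & cells_norm$cell_type == ty
    XA <- as.matrix(cells_norm$values[selA, tasks$gene[rows], drop = FALSE])
    XB <- as.matrix(cells_norm$values[selB, tasks$gene[rows], drop = FALSE])
    for (k in seq_along(rows)) {
      a <- XA[, k]; b <- XB[, k]
      tasks$p[rows[k]] <-
        if (length(a) < 2 || length(b) < 2) NA_real_
      else stats::wilcox.test(b, a, exact = FALSE)$p.value
      tasks$lnfc[rows[k]] <- log(mean(expm1(b)) + eps) -
        log(mean(expm1(a)) + eps)
    }
    tasks$padj[rows] <- stats::p.adjust(tasks$p[rows], method = "BH")
  }
  key <- function(type, gene) paste(type, gene, sep = "\r")
  tkey <- key(tasks$type, tasks$gene)
  tested <- do.call(rbind, lapply(seq_len(nrow(si)), function(i) {
    lig <- tasks[match(key(si$source_type[i], lr_db$ligand[rec[i]]), tkey), ]
    sub <- tasks[match(key(si$target_type[i],
                           lr_db$receptor_subunits[[rec[i]]]), tkey), ,
                 drop = FALSE]
    data.frame(source_type = si$source_type[i],
               target_type = si$target_type[i],
               pair_id = si$pair_id[i],
               ligand_lnFC = lig$lnfc,
               receptor_lnFC = mean(sub$lnfc),
               ligand_padj = lig$padj,
               receptor_padj = max(sub$padj),
               subunits_pass = all(!is.na(sub$padj)) &&
                 all(abs(sub$lnfc) >= config$lnfc_threshold &
                       sub$padj < config$padj_threshold) &&
                 length(unique(sign(sub$lnfc))) == 1,
               stringsAsFactors = FALSE)
  }))
  keep <- !is.na(tested$ligand_padj) &
    abs(tested$ligand_lnFC) >= config$lnfc_threshold &
    tested$ligand_padj < config$padj_threshold &
    tested$subunits_pass &
    sign(tested$ligand_lnFC) == sign(tested$receptor_lnFC) &
    tested$ligand_lnFC != 0
  out <- tested[keep, setdiff(names(tested), "subunits_pass"), drop = FALSE]
  out$direction <- ifelse(out$ligand_lnFC > 0, "up", "down")
  rownames(out) <- NULL
  class(out) <- c("differential_lr", "data.frame")
  attr(out, "comparison") <- comparison
  attr(out, "tested") <- tested
  out
}

#' Run a list of pairwise condition comparisons
#'
#' Scores communication per condition (including pooled conditions named in
#' the comparisons), takes per comparison the interactions significant
#' (`p < significance_alpha`) in at least one of its two conditions, and
#' runs [differential_lr()] on each. The summary mirrors the up/down count
#' tables of a differential L-R screen.
#'
#' @param cells_norm a `normalized_matrix` of cells.
#' @param comparisons list of length-2 character vectors `(condA, condB)`.
#' @param lr_db an [lr_database()].
#' @param config a [communication_config()].
#' @param pooled named list of pooled condition definitions.
#' @param seed integer seed for the permutation nulls.
#' @return List with `communication` (one `communication_result` covering
#'   all conditions used), `differential` (named list of
#'   `differential_lr`), and `summary` (data.frame comparison, n_up,
#'   n_down).
#' @export
run_comparisons <- function(cells_norm, comparisons, lr_db,
                            config = communication_config(),
                            pooled = list(), seed = 1L) {
  if (!length(comparisons)) stop("no comparisons given", call. = FALSE)
  avail <- unique(cells_norm$condition)
  cond_names <- unique(unlist(comparisons))
  cond_sets <- stats::setNames(
    lapply(cond_names, resolve_condition, pooled = pooled, available = avail),
    cond_names)
  comm <- communication_scores(cells_norm, lr_db, config, seed = seed,
                               conditions = cond_sets)
  sig <- comm[comm$p_value < config$significance_alpha, , drop = FALSE]
  differential <- list(); summ <- list()
  for (cmp in comparisons) {
    cmp_name <- paste(cmp[1], "vs", cmp[2])
    si <- sig[sig$condition %in% cmp, , drop = FALSE]
    de <- differential_lr(cells_norm, cmp, si, lr_db, config, pooled)
    differential[[cmp_name]] <- de
    summ[[cmp_name]] <- data.frame(comparison = cmp_name,
                                   n_up = sum(de$direction == "up"),
                                   n_down = sum(de$direction == "down"),
                                   stringsAsFactors = FALSE)
  }
  list(communication = comm, differential = differential,
       summary = do.call(rbind, c(summ, list(make.row.names = FALSE))))
}
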