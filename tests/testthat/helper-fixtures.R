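# Shared fixtures and independent oracles, all built in code.

# tiny dense cell matrix with explicit labels
tiny_cells <- function() {
  counts <- matrix(c(5, 0, 2,
                     0, 3, 1,
                     4, 4, 0), nrow = 3, byrow = TRUE,
                   dimnames = list(c("c1", "c2", "c3"),
                                   c("gA", "gB", "gC")))
  cell_matrix(counts, cell_type = c("T1", "T1", "T2"),
              condition = c("H", "H", "D"),
              sample_id = c("s1", "s1", "s2"))
}

# 4-spot 2x2 grid
tiny_spots <- function() {
  counts <- matrix(c(3, 1,
                     0, 2,
                     5, 5,
                     1, 0), nrow = 4, byrow = TRUE,
                   dimnames = list(sprintf("sp%d", 1:4), c("gA", "gB")))
  spot_matrix(counts, xy = cbind(x = c(0, 0, 1, 1), y = c(0, 1, 0, 1)),
              sample_id = rep("sl1", 4), condition = rep("H", 4))
}

# QC thresholds adapted to small synthetic gene panels (the clinical
# defaults assume genome-wide panels)
panel_qc <- function() {
  qc_thresholds(min_counts = 500, min_genes = 50,
                min_log10_genes_over_log10_counts = 0.4,
                mito_gene_prefix = "ZZNOMITO-")
}

# small simulated paired dataset used across modules
small_dataset <- function(seed = 1, planted = NULL, coloc = list(),
                          seg = list(), n_per = 100, conditions = c("Healthy", "CKD"),
                          db = NULL, ...) {
  if (is.null(db)) db <- simulate_lr_database(n_pairs = 20, seed = 3)
  cfg <- simulation_config(n_cell_types = 5, n_genes = 120,
                           n_cells_per_type_per_condition = n_per,
                           conditions = conditions,
                           n_spots_per_sample = 100,
                           n_samples_per_condition = 2,
                           lr_db = db, planted_lr = planted,
                           colocalized_pairs = coloc,
                           segregated_pairs = seg,
                           seed = seed, ...)
  simulate_dataset(cfg)
}

# brute-force co-occurrence tail probabilities by enumerating every way of
# placing the two types' presences over N spots (independent of phyper)
brute_cooccurrence <- function(N, N1, N2, j_obs) {
  sites <- seq_len(N)
  placements1 <- utils::combn(N, N1, simplify = FALSE)
  placements2 <- utils::combn(N, N2, simplify = FALSE)
  overlaps <- unlist(lapply(placements1, function(a)
    vapply(placements2, function(b) length(intersect(a, b)), integer(1))))
  c(p_gt = mean(overlaps >= j_obs), p_lt = mean(overlaps <= j_obs))
}

# independent trimean oracle through R's quantile (type 7), computed the
# slow way
trimean_oracle <- function(x) {
  unname(stats::quantile(x, 0.25) + 2 * stats::quantile(x, 0.5) +
           stats::quantile(x, 0.75)) / 4
}

# adjusted Rand index from the contingency table (Hubert & Arabie)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxidx <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxidx - expected)
}

norm_from_values <- function(values, cell_type, condition = NULL) {
  n <- nrow(values)
  structure(list(values = Matrix::Matrix(values, sparse = TRUE),
                 scale_factor = 1e4,
                 gene_ids = colnames(values),
                 unit_ids = rownames(values),
                 unit_kind = "cell",
                 cell_type = cell_type,
                 condition = if (is.null(condition)) rep("H", n) else condition,
                 sample_id = rep("s1", n)),
            class = "normalized_matrix")
}

spots_norm_from_values <- function(values, sample_id = NULL,
                                   condition = NULL) {
  n <- nrow(values)
  structure(list(values = Matrix::Matrix(values, sparse = TRUE),
                 scale_factor = 1e4,
                 gene_ids = colnames(values),
                 unit_ids = rownames(values),
                 unit_kind = "spot",
                 xy = cbind(x = seq_len(n), y = 0),
                 sample_id = if (is.null(sample_id)) rep("sl1", n) else sample_id,
                 condition = if (is.null(condition)) rep("H", n) else condition),
            class = "normalized_matrix")
}
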