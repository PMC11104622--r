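# ---------------------------------------------------------------------------
# Synthetic paired single-cell + spatial data with known ground truth.
#
# The generator emulates the structure the pipeline is built for: cell-type
# expression programs with marker genes, negative-binomial counts, Visium-
# like spots mixing ~8 cells drawn from Dirichlet compositions organised
# into spatially contiguous neighbourhood archetypes, and planted
# condition-dependent ligand-receptor programs between chosen source and
# target cell types.
# ---------------------------------------------------------------------------

#' Simulate a ligand-receptor interaction database
#'
#' Generates `n_pairs` records with ligand genes `LIG01..` and receptor
#' genes `RECxx`; a fraction of receptors are two-subunit complexes
#' (`RECxxA`/`RECxxB`), mirroring complexes such as ITGAV-ITGB1.
#'
#' @param n_pairs number of interaction records.
#' @param complex_fraction fraction of receptors that are two-subunit
#'   complexes.
#' @param seed integer seed.
#' @return An [lr_database()].
#' @export
simulate_lr_database <- function(n_pairs = 60, complex_fraction = 0.2,
                                 seed = 1L) {
  set.seed(seed)
  idx <- seq_len(n_pairs)
  ligands <- sprintf("LIG%02d", idx)
  is_complex <- stats::runif(n_pairs) < complex_fraction
  subunits <- lapply(idx, function(i) {
    if (is_complex[i]) sprintf("REC%02d%s", i, c("A", "B"))
    else sprintf("REC%02d", i)
  })
  pair_id <- vapply(idx, function(i)
    paste0(ligands[i], "_", paste(subunits[[i]], collapse = "")), character(1))
  lr_database(pair_id, ligands, subunits,
              pathway = sprintf("PW%02d", ((idx - 1) %% 8) + 1))
}

#' Configuration for the paired-data simulator
#'
#' Defaults follow the study design the pipeline targets: an average of 8
#' cells mixed per spot, three disease conditions, spot compositions drawn
#' from Dirichlet archetypes laid out as contiguous neighbourhood blocks,
#' and negative-binomial counts with a single shared dispersion.
#'
#' @param n_cell_types number of cell types (`T1..`).
#' @param n_genes total genes, including markers, ligand/receptor genes from
#'   `lr_db`, and background filler.
#' @param n_cells_per_type_per_condition cells simulated per type and
#'   condition.
#' @param conditions ordered condition labels; the first is the reference
#'   (healthy) state.
#' @param cells_per_spot_mean expected cells mixed per spot (zero-truncated
#'   Poisson mean).
#' @param n_spots_per_sample spots per spatial sample (laid on a square grid).
#' @param n_samples_per_condition spatial samples (slides) per condition.
#' @param n_archetypes number of neighbourhood archetypes (contiguous grid
#'   blocks with their own Dirichlet composition).
#' @param dirichlet_base Dirichlet concentration for non-dominant types in an
#'   archetype.
#' @param dirichlet_dominant Dirichlet concentration for an archetype's
#'   dominant types.
#' @param colocalized_pairs list of 2-vectors of cell-type names planted as
#'   a co-occurring niche: inside one shared host archetype, a fraction
#'   `niche_fraction` of spots get both members' Dirichlet concentration
#'   raised by `dirichlet_coloc`, the rest neither — so the two members'
#'   presence co-varies across the spots of that neighbourhood instead of
#'   saturating it (saturated marginals carry no co-occurrence signal).
#' @param segregated_pairs list of 2-vectors of cell-type names never
#'   allowed to co-dominate an archetype; each member dominates a distinct
#'   archetype.
#' @param dirichlet_coloc concentration added to both members of a
#'   colocalized pair in niche spots of the host archetype.
#' @param niche_fraction fraction of the host archetype's spots forming the
#'   niche of a colocalized pair.
#' @param planted_lr `NULL` or a data.frame with columns `pair_id`,
#'   `source_type`, `target_type`, `affected_condition`, `ligand_lnfc`,
#'   `receptor_lnfc`: the ligand mean in the source type and the receptor
#'   subunit means in the target type are multiplied by `exp(lnfc)` in the
#'   affected condition only.
#' @param planted_baseline_fold baseline elevation of a planted pair's
#'   ligand in its source type and receptor subunits in its target type,
#'   across all conditions: a disease-modulated channel is a real
#'   communication channel in the healthy state too, so the pair is
#'   detectable as significant communication before the condition effect is
#'   applied on top.
#' @param lr_db an [lr_database()]; defaults to [simulate_lr_database()]
#'   with this config's seed.
#' @param n_markers_per_type marker genes elevated per cell type.
#' @param marker_fold fold elevation of a marker in its own type.
#' @param lr_gene_fold baseline fold elevation of all database ligand and
#'   receptor genes in every type (so interaction scores are informative
#'   even under the null).
#' @param type_jitter_sdlog log-sd of the per-type multiplicative jitter
#'   applied to every gene's baseline mean (cell types differ mildly in all
#'   genes, as real types do). Set to 0 for a fully null simulation in
#'   which cell-type labels are exchangeable with respect to
#'   ligand/receptor genes.
#' @param nb_dispersion negative-binomial size parameter shared by all genes;
#'   larger values approach the Poisson limit.
#' @param library_size_mean mean per-cell library size (log-normal).
#' @param library_size_sdlog log-sd of the per-cell library size.
#' @param seed integer seed; all `simulate_*` operations are deterministic
#'   given the config.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_cell_types = 5,
                              n_genes = 200,
                              n_cells_per_type_per_condition = 300,
                              conditions = c("Healthy", "AKI", "CKD"),
                              cells_per_spot_mean = 8,
                              n_spots_per_sample = 200,
                              n_samples_per_condition = 2,
                              n_archetypes = 3,
                              dirichlet_base = 0.15,
                              dirichlet_dominant = 6,
                              colocalized_pairs = list(),
                              segregated_pairs = list(),
                              dirichlet_coloc = 2.5,
                              niche_fraction = 0.5,
                              planted_lr = NULL,
                              planted_baseline_fold = 3,
                              lr_db = NULL,
                              n_markers_per_type = 10,
                              marker_fold = 15,
                              lr_gene_fold = 4,
                              type_jitter_sdlog = 0.3,
                              nb_dispersion = 2,
                              library_size_mean = 2500,
                              library_size_sdlog = 0.25,
                              seed = 1L) {
  cfg <- as.list(environment())
  if (is.null(cfg$lr_db)) cfg$lr_db <- simulate_lr_database(seed = seed)
  cfg$cell_types <- sprintf("T%d", seq_len(n_cell_types))
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  if (cfg$cells_per_spot_mean <= 0)
    stop("cells_per_spot_mean must be positive", call. = FALSE)
  if (cfg$dirichlet_base <= 0 || cfg$dirichlet_dominant <= 0)
    stop("Dirichlet concentrations must be positive", call. = FALSE)
  if (length(cfg$conditions) < 2)
    stop("at least two conditions are required", call. = FALSE)
  if (cfg$library_size_mean <= 0)
    stop("library_size_mean must be positive", call. = FALSE)
  pkey <- function(p) paste(sort(unlist(p)), collapse = "|")
  if (length(cfg$colocalized_pairs) && length(cfg$segregated_pairs)) {
    if (length(intersect(vapply(cfg$colocalized_pairs, pkey, character(1)),
                         vapply(cfg$segregated_pairs, pkey, character(1)))))
      stop("a cell-type pair cannot be both colocalized and segregated",
           call. = FALSE)
  }
  for (p in c(cfg$colocalized_pairs, cfg$segregated_pairs))
    if (!all(p %in% cfg$cell_types))
      stop("unknown cell type in spatial pair constraint: ",
           paste(setdiff(p, cfg$cell_types), collapse = ", "), call. = FALSE)
  if (!is.null(cfg$planted_lr)) {
    need <- c("pair_id", "source_type", "target_type", "affected_condition",
              "ligand_lnfc", "receptor_lnfc")
    if (!all(need %in% names(cfg$planted_lr)))
      stop("planted_lr needs columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    if (!all(cfg$planted_lr$pair_id %in% cfg$lr_db$pair_id))
      stop("planted pair_id not in lr_db", call. = FALSE)
    if (!all(cfg$planted_lr$affected_condition %in% cfg$conditions))
      stop("planted affected_condition not in conditions", call. = FALSE)
    if (!all(c(cfg$planted_lr$source_type, cfg$planted_lr$target_type)
             %in% cfg$cell_types))
      stop("planted source/target type unknown", call. = FALSE)
  }
  invisible(cfg)
}

# gene universe: per-type markers, then DB ligand/receptor genes, then filler
simulation_genes <- function(cfg) {
  markers <- unlist(lapply(seq_len(cfg$n_cell_types), function(t)
    sprintf("MRK%s_%02d", cfg$cell_types[t], seq_len(cfg$n_markers_per_type))))
  lr_genes <- unique(c(cfg$lr_db$ligand, unlist(cfg$lr_db$receptor_subunits)))
  n_fill <- cfg$n_genes - length(markers) - length(lr_genes)
  if (n_fill < 0)
    stop("n_genes too small for markers plus ligand/receptor genes",
         call. = FALSE)
  c(markers, lr_genes, sprintf("BG%04d", seq_len(n_fill)))
}

#' Simulate ground-truth expression programs per cell type and condition
#'
#' Baseline gene means are log-normal and shared across types; marker genes
#' are elevated in their own type; every ligand/receptor gene in the
#' database is moderately elevated in all types so communication scores are
#' informative; planted interactions multiply the ligand mean in the source
#' type and the receptor subunit means in the target type by
#' `exp(lnfc)` in the affected condition only.
#'
#' @param config a [simulation_config()].
#' @return A list of class `ground_truth` with element `means`: a 3-d array
#'   (gene x cell type x condition) of expected expression, plus the gene
#'   and type labels and the planted interaction table.
#' @export
simulate_cell_programs <- function(config) {
  set.seed(config$seed)
  genes <- simulation_genes(config)
  types <- config$cell_types
  base <- stats::rlnorm(length(genes), meanlog = 0, sdlog = 1)
  names(base) <- genes
  # per-type multiplier: mild lognormal jitter everywhere, markers elevated
  mult <- matrix(stats::rlnorm(length(genes) * length(types),
                               meanlog = 0, sdlog = config$type_jitter_sdlog),
                 nrow = length(genes), dimnames = list(genes, types))
  for (t in seq_along(types)) {
    mk <- sprintf("MRK%s_%02d", types[t], seq_len(config$n_markers_per_type))
    mult[mk, t] <- mult[mk, t] * config$marker_fold
  }
  lr_genes <- unique(c(config$lr_db$ligand,
                       unlist(config$lr_db$receptor_subunits)))
  mult[lr_genes, ] <- mult[lr_genes, ] * config$lr_gene_fold
  if (!is.null(config$planted_lr)) {
    # baseline channel specialization, applied once per (gene, type)
    boosted <- character()
    boost <- function(gene, type) {
      key <- paste(gene, type)
      if (!key %in% boosted) {
        boosted <<- c(boosted, key)
        mult[gene, type] <<- mult[gene, type] * config$planted_baseline_fold
      }
    }
    for (i in seq_len(nrow(config$planted_lr))) {
      p <- config$planted_lr[i, ]
      rec <- match(p$pair_id, config$lr_db$pair_id)
      boost(config$lr_db$ligand[rec], p$source_type)
      for (su in config$lr_db$receptor_subunits[[rec]])
        boost(su, p$target_type)
    }
  }
  means <- array(rep(base * mult, length(config$conditions)),
                 dim = c(length(genes), length(types),
                         length(config$conditions)),
                 dimnames = list(genes, types, config$conditions))
  # planted condition effects; a gene planted twice with the same effect in
  # the same (type, condition) slot is applied once; conflicting effects err
  if (!is.null(config$planted_lr)) {
    effects <- new.env(parent = emptyenv())
    add_effect <- function(gene, type, cond, lnfc) {
      key <- paste(gene, type, cond, sep = "\r")
      prev <- effects[[key]]
      if (!is.null(prev)) {
        if (!isTRUE(all.equal(prev, lnfc)))
          stop(sprintf(
            "gene %s planted twice in %s/%s with conflicting effects (%g vs %g)",
            gene, type, cond, prev, lnfc), call. = FALSE)
        return(invisible())
      }
      effects[[key]] <- lnfc
      means[gene, type, cond] <<- means[gene, type, cond] * exp(lnfc)
      invisible()
    }
    for (i in seq_len(nrow(config$planted_lr))) {
      p <- config$planted_lr[i, ]
      rec <- match(p$pair_id, config$lr_db$pair_id)
      add_effect(config$lr_db$ligand[rec], p$source_type,
                 p$affected_condition, p$ligand_lnfc)
      for (su in config$lr_db$receptor_subunits[[rec]])
        add_effect(su, p$target_type, p$affected_condition, p$receptor_lnfc)
    }
  }
  structure(list(means = means, genes = genes, cell_types = types,
                 conditions = config$conditions,
                 planted_lr = config$planted_lr),
            class = "ground_truth")
}

# log-normal library sizes with the requested arithmetic mean
draw_library_sizes <- function(n, mean, sdlog) {
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# NB count block for n units whose expected profiles are the columns of mu
rnbinom_matrix <- function(mu, size) {
  cnt <- stats::rnbinom(length(mu), size = size, mu = as.vector(mu))
  matrix(cnt, nrow = nrow(mu), dimnames = dimnames(mu))
}

#' Simulate single-cell counts from ground-truth programs
#'
#' Each cell's expected profile is its type/condition program rescaled to a
#' log-normal library size; counts are negative binomial with the shared
#' dispersion `nb_dispersion` (Poisson limit as dispersion grows).
#'
#' @param config a [simulation_config()].
#' @param truth result of [simulate_cell_programs()].
#' @return A [cell_matrix()] with cells from every type, condition and
#'   sample.
#' @export
simulate_cells <- function(config, truth) {
  set.seed(config$seed + 1L)
  n_per <- config$n_cells_per_type_per_condition
  blocks <- list(); meta <- list()
  cell_counter <- 0L
  for (cond in config$conditions) {
    for (type in config$cell_types) {
      prog <- truth$means[, type, cond]
      prog <- prog / sum(prog)
      lib <- draw_library_sizes(n_per, config$library_size_mean,
                                config$library_size_sdlog)
      mu <- outer(prog, lib)           # genes x cells
      cnt <- rnbinom_matrix(mu, config$nb_dispersion)
      ids <- sprintf("CELL%06d", cell_counter + seq_len(n_per))
      cell_counter <- cell_counter + n_per
      colnames(cnt) <- ids
      blocks[[length(blocks) + 1L]] <- cnt
      meta[[length(meta) + 1L]] <- data.frame(
        barcode = ids, cell_type = type, condition = cond,
        sample_id = paste0("SC_", cond, "_S",
                           rep_len(seq_len(config$n_samples_per_condition),
                                   n_per)),
        stringsAsFactors = FALSE)
    }
  }
  counts <- do.call(cbind, blocks)     # genes x cells
  meta <- do.call(rbind, meta)
  cell_matrix(Matrix::t(Matrix::Matrix(counts, sparse = TRUE)),
              cell_type = meta$cell_type, condition = meta$condition,
              sample_id = meta$sample_id)
}

# ---- archetype construction ------------------------------------------------

# Assign dominant cell types to archetypes and colocalized pairs to host
# archetypes, honouring segregation constraints. Members of colocalized
# pairs are never archetype dominants: they enter as niche boosts inside
# their host archetype, so their presence varies across its spots.
# Returns the archetype x type base concentration matrix `alpha` and
# `coloc_hosts`, the host archetype of each colocalized pair.
build_archetypes <- function(cfg) {
  K <- cfg$n_archetypes
  types <- cfg$cell_types
  coloc_members <- unique(unlist(cfg$colocalized_pairs))
  dominant <- rep(list(character()), K)
  seg_partner <- function(ty) unlist(lapply(cfg$segregated_pairs, function(p)
    if (ty %in% p) setdiff(p, ty)))
  seg_conflict <- function(k, newtypes) {
    cand <- c(dominant[[k]], newtypes)
    for (p in cfg$segregated_pairs)
      if (all(p %in% cand)) return(TRUE)
    FALSE
  }
  place <- function(ty) {
    ok <- which(!vapply(seq_len(K), seg_conflict, logical(1), newtypes = ty))
    if (!length(ok))
      stop("n_archetypes too small to honour colocalization/segregation ",
           "constraints", call. = FALSE)
    k <- ok[which.min(lengths(dominant)[ok])]
    dominant[[k]] <<- unique(c(dominant[[k]], ty))
    k
  }
  for (p in cfg$segregated_pairs)
    for (ty in unlist(p))
      if (!any(vapply(dominant, function(d) ty %in% d, logical(1))))
        place(ty)
  for (ty in setdiff(types, coloc_members))
    if (!any(vapply(dominant, function(d) ty %in% d, logical(1)))) {
      ok <- which(!vapply(seq_len(K), seg_conflict, logical(1), newtypes = ty))
      if (length(ok))
        dominant[[ok[which.min(lengths(dominant)[ok])]]] <-
          unique(c(dominant[[ok[which.min(lengths(dominant)[ok])]]], ty))
    }
  # host archetypes for colocalized niches: avoid archetypes dominated by a
  # segregation partner of either member
  n_hosted <- integer(K)
  coloc_hosts <- vapply(cfg$colocalized_pairs, function(p) {
    partners <- unique(c(seg_partner(p[1]), seg_partner(p[2])))
    ok <- which(!vapply(seq_len(K), function(k)
      any(partners %in% dominant[[k]]), logical(1)))
    if (!length(ok))
      stop("n_archetypes too small to honour colocalization/segregation ",
           "constraints", call. = FALSE)
    k <- ok[which.min(n_hosted[ok])]
    n_hosted[k] <<- n_hosted[k] + 1L
    k
  }, integer(1))
  alpha <- matrix(cfg$dirichlet_base, nrow = K, ncol = length(types),
                  dimnames = list(sprintf("A%d", seq_len(K)), types))
  for (k in seq_len(K)) alpha[k, dominant[[k]]] <- cfg$dirichlet_dominant
  list(alpha = alpha, coloc_hosts = coloc_hosts)
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

# zero-truncated Poisson draws (redraw zeros)
rpois_truncated <- function(n, lambda) {
  x <- stats::rpois(n, lambda)
  while (any(x == 0L)) x[x == 0L] <- stats::rpois(sum(x == 0L), lambda)
  x
}

#' Simulate spatial spots as mixtures of latent single cells
#'
#' Spots are laid on a square grid per sample; contiguous vertical blocks of
#' the grid belong to neighbourhood archetypes, each with its own Dirichlet
#' composition over cell types. Per spot, the number of mixed cells is
#' zero-truncated Poisson (mean `cells_per_spot_mean`), cell types are
#' multinomial in the spot's composition, and the spot's counts are the sum
#' of independent negative-binomial single-cell draws — the same generative
#' model the deconvolution stage assumes.
#'
#' @param config a [simulation_config()].
#' @param truth result of [simulate_cell_programs()].
#' @return A list with elements `spots` (a [spot_matrix()]) and `truth`
#'   (the input ground truth completed with `composition` — realized
#'   per-spot cell-type proportions — `archetype` and `cells_per_spot` per
#'   spot, and the archetype concentration matrix `alpha`).
#' @export
simulate_spots <- function(config, truth) {
  set.seed(config$seed + 2L)
  arch <- build_archetypes(config)
  alpha <- arch$alpha
  coloc_hosts <- arch$coloc_hosts
  K <- nrow(alpha)
  types <- config$cell_types
  genes <- truth$genes
  side <- ceiling(sqrt(config$n_spots_per_sample))
  blocks <- list(); meta <- list(); comp <- list(); arch_labels <- c()
  cellcounts <- c()
  spot_counter <- 0L
  for (cond in config$conditions) {
    for (s in seq_len(config$n_samples_per_condition)) {
      sample_id <- paste0("ST_", cond, "_S", s)
      n_spots <- config$n_spots_per_sample
      gx <- (seq_len(n_spots) - 1L) %% side
      gy <- (seq_len(n_spots) - 1L) %/% side
      # contiguous vertical strips of the grid per archetype
      a_of_spot <- pmin(K, gx %/% max(1L, ceiling(side / K)) + 1L)
      ncells <- rpois_truncated(n_spots, config$cells_per_spot_mean)
      prog <- truth$means[, , cond, drop = TRUE]   # genes x types
      prog_norm <- sweep(prog, 2, colSums(prog), "/")
      cnt <- matrix(0, nrow = length(genes), ncol = n_spots)
      composition <- matrix(0, nrow = n_spots, ncol = length(types),
                            dimnames = list(NULL, types))
      for (i in seq_len(n_spots)) {
        avec <- alpha[a_of_spot[i], ]
        if (length(coloc_hosts)) {
          hosted <- which(coloc_hosts == a_of_spot[i])
          for (h in hosted)
            if (stats::runif(1) < config$niche_fraction) {
              members <- unlist(config$colocalized_pairs[[h]])
              avec[members] <- avec[members] + config$dirichlet_coloc
            }
        }
        cvec <- rdirichlet1(avec)
        tcount <- as.vector(stats::rmultinom(1, ncells[i], cvec))
        composition[i, ] <- tcount / ncells[i]
        lib <- draw_library_sizes(ncells[i], config$library_size_mean,
                                  config$library_size_sdlog)
        cell_types_i <- rep(seq_along(types), tcount)
        mu <- prog_norm[, cell_types_i, drop = FALSE] *
          rep(lib, each = length(genes))
        cnt[, i] <- rowSums(rnbinom_matrix(mu, config$nb_dispersion))
      }
      ids <- sprintf("SPOT%06d", spot_counter + seq_len(n_spots))
      spot_counter <- spot_counter + n_spots
      dimnames(cnt) <- list(genes, ids)
      blocks[[length(blocks) + 1L]] <- cnt
      meta[[length(meta) + 1L]] <- data.frame(
        barcode = ids, x = gx, y = gy, sample_id = sample_id,
        condition = cond, stringsAsFactors = FALSE)
      rownames(composition) <- ids
      comp[[length(comp) + 1L]] <- composition
      arch_labels <- c(arch_labels, stats::setNames(a_of_spot, ids))
      cellcounts <- c(cellcounts, stats::setNames(ncells, ids))
    }
  }
  counts <- do.call(cbind, blocks)
  meta <- do.call(rbind, meta)
  spots <- spot_matrix(Matrix::t(Matrix::Matrix(counts, sparse = TRUE)),
                       xy = cbind(x = meta$x, y = meta$y),
                       sample_id = meta$sample_id,
                       condition = meta$condition)
  truth$composition <- do.call(rbind, comp)
  truth$archetype <- arch_labels
  truth$cells_per_spot <- cellcounts
  truth$alpha <- alpha
  truth$coloc_hosts <- coloc_hosts
  list(spots = spots, truth = truth)
}

#' Simulate a complete paired dataset
#'
#' Convenience wrapper running [simulate_cell_programs()],
#' [simulate_cells()] and [simulate_spots()] on one config.
#'
#' @param config a [simulation_config()].
#' @return List with `cells`, `spots`, `truth`, `lr_db`, `config`.
#' @export
simulate_dataset <- function(config) {
  truth <- simulate_cell_programs(config)
  cells <- simulate_cells(config, truth)
  sp <- simulate_spots(config, truth)
  list(cells = cells, spots = sp$spots, truth = sp$truth,
       lr_db = config$lr_db, config = config)
}
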