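#' @import Matrix
#' @import methods
#' @importFrom stats median quantile cor sd aggregate rnbinom rpois rlnorm
#'   rmultinom rgamma runif kmeans phyper p.adjust wilcox.test setNames
#' @importFrom utils read.delim read.csv write.table packageVersion
NULL

# ---------------------------------------------------------------------------
# Domain containers
#
# All downstream modules consume only these in-memory types. Counts are held
# as sparse dgCMatrix with units (cells or spots) in rows and genes in
# columns; dimnames carry the ids.
# ---------------------------------------------------------------------------

#' Construct a cell-level expression container
#'
#' Bundles a cells-by-genes count matrix with the per-cell annotations every
#' downstream stage needs: the cell type, the disease condition and the
#' sample of origin.
#'
#' @param counts cells-by-genes matrix of non-negative integer counts
#'   (dense or sparse; coerced to `dgCMatrix`). Row names are cell barcodes,
#'   column names gene symbols.
#' @param cell_type,condition,sample_id character vectors, one entry per cell.
#' @return An object of class `cell_matrix`: a list with elements `counts`,
#'   `gene_ids`, `cell_ids`, `cell_type`, `condition`, `sample_id`.
#' @export
cell_matrix <- function(counts, cell_type, condition, sample_id) {
  counts <- as_sparse_counts(counts)
  n <- nrow(counts)
  stopifnot(length(cell_type) == n, length(condition) == n,
            length(sample_id) == n)
  x <- structure(list(
    counts    = counts,
    gene_ids  = colnames(counts),
    cell_ids  = rownames(counts),
    cell_type = as.character(cell_type),
    condition = as.character(condition),
    sample_id = as.character(sample_id)
  ), class = "cell_matrix")
  validate_cell_matrix(x)
  x
}

#' Construct a spot-level expression container
#'
#' @param counts spots-by-genes count matrix; row names are spot barcodes.
#' @param xy two-column numeric matrix of array coordinates (x, y), one row
#'   per spot. Coordinates follow the image convention: origin top-left,
#'   y increasing downward; only relative positions matter.
#' @param sample_id,condition character vectors, one entry per spot; every
#'   sample must carry exactly one condition.
#' @return An object of class `spot_matrix`.
#' @export
spot_matrix <- function(counts, xy, sample_id, condition) {
  counts <- as_sparse_counts(counts)
  n <- nrow(counts)
  xy <- as.matrix(xy)
  stopifnot(nrow(xy) == n, ncol(xy) == 2,
            length(sample_id) == n, length(condition) == n)
  colnames(xy) <- c("x", "y")
  x <- structure(list(
    counts    = counts,
    gene_ids  = colnames(counts),
    spot_ids  = rownames(counts),
    xy        = xy,
    sample_id = as.character(sample_id),
    condition = as.character(condition)
  ), class = "spot_matrix")
  validate_spot_matrix(x)
  x
}

as_sparse_counts <- function(counts) {
  dn <- dimnames(counts)
  if (is.null(dn)) dn <- list(NULL, NULL)
  if (is.null(dn[[1]]) && nrow(counts) == 0) dn[[1]] <- character(0)
  if (is.null(dn[[2]]) && ncol(counts) == 0) dn[[2]] <- character(0)
  if (is.null(dn[[1]]) || is.null(dn[[2]]))
    stop("counts must carry row (unit) and column (gene) names", call. = FALSE)
  counts <- methods::as(methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                                "dMatrix"), "generalMatrix"), "CsparseMatrix")
  dimnames(counts) <- dn
  counts
}

validate_cell_matrix <- function(x) {
  if (any(x$counts@x < 0)) stop("counts contain negative entries", call. = FALSE)
  if (anyDuplicated(x$gene_ids)) stop("gene_ids are not unique", call. = FALSE)
  if (anyDuplicated(x$cell_ids)) stop("duplicate cell barcodes", call. = FALSE)
  if (anyNA(x$cell_type) || anyNA(x$condition) || anyNA(x$sample_id))
    stop("every cell needs a cell_type, condition and sample_id", call. = FALSE)
  invisible(x)
}

validate_spot_matrix <- function(x) {
  if (any(x$counts@x < 0)) stop("counts contain negative entries", call. = FALSE)
  if (anyDuplicated(x$gene_ids)) stop("gene_ids are not unique", call. = FALSE)
  if (!all(is.finite(x$xy))) stop("spot coordinates must be finite", call. = FALSE)
  # one condition per sample
  cond_per_sample <- tapply(x$condition, x$sample_id,
                            function(v) length(unique(v)))
  if (any(cond_per_sample > 1))
    stop("a sample maps to more than one condition: ",
         paste(names(cond_per_sample)[cond_per_sample > 1], collapse = ", "),
         call. = FALSE)
  # spot ids unique within sample
  if (anyDuplicated(paste(x$sample_id, x$spot_ids)))
    stop("duplicate spot barcodes within a sample", call. = FALSE)
  invisible(x)
}

#' @exportS3Method base::print
print.cell_matrix <- function(x, ...) {
  cat(sprintf("<cell_matrix> %d cells x %d genes | %d cell types | conditions: %s\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$cell_type)),
              paste(unique(x$condition), collapse = ", ")))
  invisible(x)
}

#' @exportS3Method base::print
print.spot_matrix <- function(x, ...) {
  cat(sprintf("<spot_matrix> %d spots x %d genes | %d samples | conditions: %s\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$sample_id)),
              paste(unique(x$condition), collapse = ", ")))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Ligand-receptor interaction database
# ---------------------------------------------------------------------------

#' Construct a ligand-receptor interaction database
#'
#' Each record pairs a ligand gene with a receptor that may be a
#' multi-subunit complex (for example the two-subunit integrin complex
#' ITGAV-ITGB1). Subunit order is preserved.
#'
#' @param pair_id unique identifiers for each interaction.
#' @param ligand ligand gene symbol per record.
#' @param receptor_subunits list of character vectors of receptor subunit
#'   gene symbols (each of length >= 1).
#' @param pathway free-text pathway label per record.
#' @return An object of class `lr_database`: a data.frame with a list column
#'   `receptor_subunits`.
#' @export
lr_database <- function(pair_id, ligand, receptor_subunits, pathway = NA_character_) {
  if (!is.list(receptor_subunits)) receptor_subunits <- as.list(receptor_subunits)
  if (anyDuplicated(pair_id))
    stop("duplicate pair_id: ",
         paste(unique(pair_id[duplicated(pair_id)]), collapse = ", "),
         call. = FALSE)
  if (any(lengths(receptor_subunits) == 0) ||
      any(vapply(receptor_subunits, function(s) any(!nzchar(s)), logical(1))))
    stop("every receptor needs at least one non-empty subunit", call. = FALSE)
  db <- data.frame(pair_id = as.character(pair_id),
                   ligand = as.character(ligand),
                   pathway = rep_len(as.character(pathway), length(pair_id)),
                   stringsAsFactors = FALSE)
  db$receptor_subunits <- lapply(receptor_subunits, as.character)
  class(db) <- c("lr_database", "data.frame")
  db
}

#' Read a ligand-receptor database from TSV
#'
#' Expected columns: `pair_id`, `ligand`, `receptor` (subunits joined by
#' `subunit_sep`), `pathway`.
#'
#' @param path TSV file path.
#' @param subunit_sep separator between receptor subunit symbols
#'   (default `";"`).
#' @return An [lr_database()].
#' @export
read_lr_database <- function(path, subunit_sep = ";") {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("pair_id", "ligand", "receptor", "pathway")
  if (!all(need %in% names(tab)))
    stop("L-R database must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  receptor <- as.character(tab$receptor)
  receptor[is.na(receptor)] <- ""
  subunits <- strsplit(receptor, subunit_sep, fixed = TRUE)
  subunits <- lapply(subunits, trimws)
  lr_database(trimws(tab$pair_id), trimws(tab$ligand), subunits,
              trimws(tab$pathway))
}

#' Write a ligand-receptor database to TSV
#'
#' @param db an [lr_database()].
#' @param path output TSV path.
#' @param subunit_sep separator used to join receptor subunits.
#' @export
write_lr_database <- function(db, path, subunit_sep = ";") {
  out <- data.frame(
    pair_id = db$pair_id, ligand = db$ligand,
    receptor = vapply(db$receptor_subunits, paste, character(1),
                      collapse = subunit_sep),
    pathway = db$pathway, stringsAsFactors = FALSE)
  write_tsv(out, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Matrix Market triplet readers/writers (10x-style layout)
# ---------------------------------------------------------------------------

read_mm_counts <- function(matrix_path, features_path, barcodes_path,
                           genes_in_rows = TRUE) {
  m <- Matrix::readMM(matrix_path)
  genes <- readLines(features_path)
  barcodes <- readLines(barcodes_path)
  if (genes_in_rows) m <- Matrix::t(m)
  if (nrow(m) != length(barcodes) || ncol(m) != length(genes))
    stop(sprintf(
      "matrix dimensions (%d units x %d genes) do not match barcodes (%d) / features (%d)",
      nrow(m), ncol(m), length(barcodes), length(genes)), call. = FALSE)
  if (anyDuplicated(barcodes))
    stop("duplicate barcodes in ", barcodes_path, call. = FALSE)
  dimnames(m) <- list(barcodes, genes)
  methods::as(methods::as(methods::as(m, "dMatrix"), "generalMatrix"),
              "CsparseMatrix")
}

write_mm_counts <- function(counts, dir, genes_in_rows = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- if (genes_in_rows) Matrix::t(counts) else counts
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(colnames(counts), file.path(dir, "features.tsv"))
  writeLines(rownames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a cell matrix from Matrix Market triplet files plus metadata
#'
#' @param matrix_path Matrix Market coordinate file.
#' @param features_path,barcodes_path one gene symbol / barcode per line.
#' @param metadata_path TSV with columns `barcode`, `cell_type`, `condition`,
#'   `sample_id`; every barcode in the matrix must be present.
#' @param genes_in_rows orientation of the Matrix Market file; `TRUE`
#'   (default) follows the 10x genes-in-rows convention.
#' @return A [cell_matrix()].
#' @export
read_cell_matrix <- function(matrix_path, features_path, barcodes_path,
                             metadata_path, genes_in_rows = TRUE) {
  counts <- read_mm_counts(matrix_path, features_path, barcodes_path,
                           genes_in_rows)
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  need <- c("barcode", "cell_type", "condition", "sample_id")
  if (!all(need %in% names(meta)))
    stop("metadata must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  missing <- setdiff(rownames(counts), meta$barcode)
  if (length(missing))
    stop("barcodes absent from metadata: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  idx <- match(rownames(counts), meta$barcode)
  cell_matrix(counts,
              cell_type = meta$cell_type[idx],
              condition = meta$condition[idx],
              sample_id = meta$sample_id[idx])
}

#' Write a cell matrix as Matrix Market triplet files plus metadata
#'
#' @param x a [cell_matrix()].
#' @param dir output directory (created if needed); writes `matrix.mtx`,
#'   `features.tsv`, `barcodes.tsv`, `metadata.tsv`.
#' @param genes_in_rows orientation of the Matrix Market file.
#' @export
write_cell_matrix <- function(x, dir, genes_in_rows = TRUE) {
  write_mm_counts(x$counts, dir, genes_in_rows)
  meta <- data.frame(barcode = x$cell_ids, cell_type = x$cell_type,
                     condition = x$condition, sample_id = x$sample_id,
                     stringsAsFactors = FALSE)
  write_tsv(meta, file.path(dir, "metadata.tsv"))
  invisible(dir)
}

#' Read a spot matrix from Matrix Market triplet files plus positions
#'
#' @inheritParams read_cell_matrix
#' @param positions_path CSV with columns `barcode`, `x`, `y`; must cover all
#'   barcodes in the matrix (extra barcodes are ignored with a warning).
#' @param sample_meta_path TSV with columns `barcode`, `sample_id`,
#'   `condition`; each sample must carry one condition.
#' @return A [spot_matrix()].
#' @export
read_spot_matrix <- function(matrix_path, features_path, barcodes_path,
                             positions_path, sample_meta_path,
                             genes_in_rows = TRUE) {
  counts <- read_mm_counts(matrix_path, features_path, barcodes_path,
                           genes_in_rows)
  pos <- utils::read.csv(positions_path, stringsAsFactors = FALSE)
  if (!all(c("barcode", "x", "y") %in% names(pos)))
    stop("positions file must have columns barcode, x, y", call. = FALSE)
  missing <- setdiff(rownames(counts), pos$barcode)
  if (length(missing))
    stop("spot barcodes without coordinates: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  extra <- setdiff(pos$barcode, rownames(counts))
  if (length(extra))
    warning(length(extra), " position rows have no matching spot; ignored",
            call. = FALSE)
  meta <- utils::read.delim(sample_meta_path, stringsAsFactors = FALSE)
  if (!all(c("barcode", "sample_id", "condition") %in% names(meta)))
    stop("sample metadata must have columns barcode, sample_id, condition",
         call. = FALSE)
  mmiss <- setdiff(rownames(counts), meta$barcode)
  if (length(mmiss))
    stop("spot barcodes without sample metadata: ",
         paste(utils::head(mmiss, 5), collapse = ", "), call. = FALSE)
  pidx <- match(rownames(counts), pos$barcode)
  midx <- match(rownames(counts), meta$barcode)
  spot_matrix(counts,
              xy = cbind(x = pos$x[pidx], y = pos$y[pidx]),
              sample_id = meta$sample_id[midx],
              condition = meta$condition[midx])
}

#' Write a spot matrix as Matrix Market triplet files plus positions
#'
#' @param x a [spot_matrix()].
#' @param dir output directory; writes `matrix.mtx`, `features.tsv`,
#'   `barcodes.tsv`, `positions.csv`, `sample_meta.tsv`.
#' @param genes_in_rows orientation of the Matrix Market file.
#' @export
write_spot_matrix <- function(x, dir, genes_in_rows = TRUE) {
  write_mm_counts(x$counts, dir, genes_in_rows)
  pos <- data.frame(barcode = x$spot_ids, x = x$xy[, 1], y = x$xy[, 2],
                    stringsAsFactors = FALSE)
  utils::write.table(pos, file.path(dir, "positions.csv"), sep = ",",
                     quote = FALSE, row.names = FALSE)
  meta <- data.frame(barcode = x$spot_ids, sample_id = x$sample_id,
                     condition = x$condition, stringsAsFactors = FALSE)
  write_tsv(meta, file.path(dir, "sample_meta.tsv"))
  invisible(dir)
}

# ---------------------------------------------------------------------------
# Tabular output + run manifest
# ---------------------------------------------------------------------------

#' Write a data frame as TSV with a header line
#'
#' Floating-point columns are written with 6 significant digits; this is the
#' single choke point for all tabular pipeline outputs.
#'
#' @param df data frame to write.
#' @param path output path.
#' @export
write_tsv <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- signif(df[[j]], 6)
    if (is.list(df[[j]]))
      df[[j]] <- vapply(df[[j]], paste, character(1), collapse = ";")
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest atomically
#'
#' Records the configuration snapshot, executed stage names, input file
#' checksums (MD5), the random seed and the package version. The file is
#' written to a temporary path and renamed, so a partially written manifest
#' is never observed.
#'
#' @param path output JSON path.
#' @param config configuration list snapshot.
#' @param stages character vector of stage names executed so far.
#' @param input_paths named character vector of input files to checksum.
#' @param seed integer random seed of the run.
#' @export
write_manifest <- function(path, config, stages, input_paths = character(),
                           seed = NA_integer_) {
  checksums <- if (length(input_paths)) {
    sums <- tools::md5sum(input_paths)
    as.list(stats::setNames(unname(sums), names(input_paths)))
  } else list()
  manifest <- list(
    config = config,
    stages = as.list(stages),
    input_checksums = checksums,
    seed = seed,
    versions = list(
      lrcrosstalk = as.character(utils::packageVersion("lrcrosstalk")),
      R = paste(R.version$major, R.version$minor, sep = ".")
    )
  )
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  file.rename(tmp, path)
  invisible(path)
}
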