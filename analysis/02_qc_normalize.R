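#!/usr/bin/env Rscript
# Stage 2 — quality control and normalization of both modalities.
#
# The four QC thresholds are applied identically to cells and spots. The
# count and mito thresholds keep their clinical defaults; the gene-count
# and log-ratio thresholds are rescaled to the 200-gene synthetic panel
# (the defaults of 250 genes / ratio 0.80 assume genome-wide panels and
# would empty a small panel for arithmetic, not quality, reasons).

suppressPackageStartupMessages(library(lrcrosstalk))

dat <- "results/data"
out <- "results/qc"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cells <- read_cell_matrix(file.path(dat, "cells/matrix.mtx"),
                          file.path(dat, "cells/features.tsv"),
                          file.path(dat, "cells/barcodes.tsv"),
                          file.path(dat, "cells/metadata.tsv"))
spots <- read_spot_matrix(file.path(dat, "spots/matrix.mtx"),
                         file.path(dat, "spots/features.tsv"),
                         file.path(dat, "spots/barcodes.tsv"),
                         file.path(dat, "spots/positions.csv"),
                         file.path(dat, "spots/sample_meta.tsv"))

th <- qc_thresholds(min_counts = 500, min_genes = 50,
                    min_log10_genes_over_log10_counts = 0.4,
                    mito_gene_prefix = "MT-")

qc_cells <- qc_filter(cells, th)
qc_spots <- qc_filter(spots, th)
print(qc_cells)
print(qc_spots)
write_tsv(qc_cells$report, file.path(out, "qc_cells.tsv"))
write_tsv(qc_spots$report, file.path(out, "qc_spots.tsv"))

write_cell_matrix(qc_cells$filtered, file.path(out, "cells"))
write_spot_matrix(qc_spots$filtered, file.path(out, "spots"))
write_manifest(file.path(out, "manifest.json"),
               config = unclass(th), stages = c("qc", "write"))
cat("QC removed", qc_cells$summary[["removed"]], "cells and",
    qc_spots$summary[["removed"]], "spots\n")
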