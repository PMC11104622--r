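#!/usr/bin/env Rscript
# Stage 5 — the filter chain: differential L-R x spatial co-occurrence x
# co-expression.
#
# Differential interactions survive only if their source and target cell
# types positively co-occur in at least one selected compositional cluster
# (self-pairs, i.e. autocrine signaling, always survive). Survivors are
# annotated with their minimum-principle spatial co-expression and the
# median per-slide correlation with the T1/T2 marker genes; missing genes
# become evidence flags, not exclusions.

suppressPackageStartupMessages(library(lrcrosstalk))

out <- "results/hits"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

qcd <- "results/qc"
spots <- read_spot_matrix(file.path(qcd, "spots/matrix.mtx"),
                         file.path(qcd, "spots/features.tsv"),
                         file.path(qcd, "spots/barcodes.tsv"),
                         file.path(qcd, "spots/positions.csv"),
                         file.path(qcd, "spots/sample_meta.tsv"))
spots_norm <- normalize_counts(spots)
db <- read_lr_database("results/data/lr_database.tsv")
cooc_all <- read.delim("results/composition/cooccurrence.tsv")
cooc <- lapply(split(cooc_all, cooc_all$cluster_id), function(cc) {
  class(cc) <- c("cooccurrence_result", "data.frame"); cc
})
markers <- sprintf("MRK%s_%02d", "T1", 1:3)  # T1 program markers as stand-ins

all_hits <- list()
for (f in list.files("results/communication", "^differential_.*tsv$",
                     full.names = TRUE)) {
  cmp <- sub("^differential_", "", sub("[.]tsv$", "", basename(f)))
  de <- read.delim(f)
  class(de) <- c("differential_lr", "data.frame")
  if (!nrow(de)) next
  filt <- apply_cooccurrence_filter(de, cooc, combine_rule = "union")
  hits <- build_hits(filt, spots_norm, db, markers = markers, threshold = 0)
  if (nrow(hits)) all_hits[[cmp]] <- cbind(comparison = cmp, hits)
}
hits <- if (length(all_hits))
  do.call(rbind, c(lapply(all_hits, as.data.frame),
                   list(make.row.names = FALSE))) else
  data.frame()
write_tsv(hits, file.path(out, "hits.tsv"))
write_manifest(file.path(out, "manifest.json"),
               config = list(combine_rule = "union", markers = markers),
               stages = c("cooccurrence_filter", "build_hits"))

cat(nrow(hits), "integrated hits across comparisons\n")
if (nrow(hits))
  print(hits[, c("comparison", "source_type", "target_type", "pair_id",
                 "direction", "coexpressed_fraction", "evidence_flags")],
        row.names = FALSE)
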