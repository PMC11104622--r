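#!/usr/bin/env Rscript
# Stage 1 — generate the paired study dataset.
#
# Builds a synthetic cohort mirroring the study design the pipeline
# targets: three kidney-style conditions (Healthy, AKI, CKD), five cell
# types, spatial samples whose spots mix ~8 cells from neighbourhood
# archetypes, one colocalized cell-type pair (T1-T2, sharing a niche), one
# segregated pair (T3-T4, dominating disjoint archetypes), and six planted
# ligand-receptor programs with |lnFC| in the range reported for real
# disease-modulated channels (0.1-1.1). Everything is written to
# results/data/ through the package's readers/writers, so later stages
# consume files exactly as an external user would.

suppressPackageStartupMessages(library(lrcrosstalk))

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

db <- simulate_lr_database(n_pairs = 40, complex_fraction = 0.2, seed = 3)
planted <- data.frame(
  pair_id            = db$pair_id[c(1, 4, 7, 10, 13, 16)],
  source_type        = c("T1", "T2", "T1", "T3", "T4", "T5"),
  target_type        = c("T2", "T1", "T1", "T4", "T3", "T5"),
  affected_condition = c("CKD", "CKD", "AKI", "CKD", "AKI", "CKD"),
  ligand_lnfc        = c(0.5, -0.5, 0.4, 0.6, -0.4, 0.3),
  receptor_lnfc      = c(0.5, -0.5, 0.4, 0.6, -0.4, 0.3))

cfg <- simulation_config(
  n_cell_types = 5, n_genes = 200,
  n_cells_per_type_per_condition = 200,
  conditions = c("Healthy", "AKI", "CKD"),
  n_spots_per_sample = 150, n_samples_per_condition = 2,
  lr_db = db, planted_lr = planted,
  colocalized_pairs = list(c("T1", "T2")),
  segregated_pairs = list(c("T3", "T4")),
  seed = 2024L)

ds <- simulate_dataset(cfg)
write_cell_matrix(ds$cells, file.path(out, "cells"))
write_spot_matrix(ds$spots, file.path(out, "spots"))
write_lr_database(db, file.path(out, "lr_database.tsv"))
saveRDS_free <- function(x, path) {      # ground truth as plain JSON
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
}
saveRDS_free(list(planted = planted,
                  archetype = as.list(ds$truth$archetype),
                  coloc_hosts = ds$truth$coloc_hosts),
             file.path(out, "ground_truth.json"))
write_tsv(data.frame(spot_id = rownames(ds$truth$composition),
                     ds$truth$composition, check.names = FALSE),
          file.path(out, "true_composition.tsv"))
write_manifest(file.path(out, "manifest.json"),
               config = list(stage = "simulate", seed = cfg$seed,
                             conditions = cfg$conditions,
                             cells_per_spot_mean = cfg$cells_per_spot_mean),
               stages = "simulate")

print(ds$cells)
print(ds$spots)
cat(sprintf("planted %d L-R programs; wrote %s\n", nrow(planted), out))
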