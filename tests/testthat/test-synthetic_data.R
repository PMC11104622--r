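test_that("null condition effects leave programs identical across conditions", {
  db <- simulate_lr_database(n_pairs = 10, seed = 2)
  planted0 <- data.frame(pair_id = db$pair_id[1:2],
                         source_type = c("T1", "T2"),
                         target_type = c("T2", "T3"),
                         affected_condition = "CKD",
                         ligand_lnfc = 0, receptor_lnfc = 0)
  cfg <- simulation_config(n_cell_types = 3, n_genes = 80, lr_db = db,
                           conditions = c("Healthy", "CKD"),
                           planted_lr = planted0, seed = 5)
  truth <- simulate_cell_programs(cfg)
  expect_equal(truth$means[, , "Healthy"], truth$means[, , "CKD"])
})

test_that("a planted ln fold change shifts the mean by exactly exp(lnfc)", {
  db <- simulate_lr_database(n_pairs = 10, seed = 2)
  planted <- data.frame(pair_id = db$pair_id[1],
                        source_type = "T1", target_type = "T2",
                        affected_condition = "CKD",
                        ligand_lnfc = 0.30, receptor_lnfc = 0.20)
  cfg <- simulation_config(n_cell_types = 3, n_genes = 80, lr_db = db,
                           conditions = c("Healthy", "CKD"),
                           planted_lr = planted, seed = 5)
  truth <- simulate_cell_programs(cfg)
  lig <- db$ligand[1]
  su <- db$receptor_subunits[[1]]
  expect_equal(truth$means[lig, "T1", "CKD"] / truth$means[lig, "T1", "Healthy"],
               exp(0.30))
  expect_equal(unname(truth$means[su, "T2", "CKD"] /
                        truth$means[su, "T2", "Healthy"]),
               rep(exp(0.20), length(su)))
  # no other type or condition touched
  expect_equal(truth$means[lig, "T2", "CKD"], truth$means[lig, "T2", "Healthy"])
})

test_that("shared planted genes merge when effects agree and err otherwise", {
  db <- lr_database(c("P1", "P2"), c("LIGX", "LIGX"),
                    list("RECA", "RECB"))
  base <- list(pair_id = c("P1", "P2"), source_type = "T1",
               target_type = c("T2", "T3"), affected_condition = "CKD")
  agree <- data.frame(base, ligand_lnfc = 0.4, receptor_lnfc = 0.4)
  cfg <- simulation_config(n_cell_types = 3, n_genes = 60, lr_db = db,
                           conditions = c("Healthy", "CKD"),
                           planted_lr = agree, seed = 5)
  truth <- simulate_cell_programs(cfg)
  expect_equal(truth$means["LIGX", "T1", "CKD"] /
                 truth$means["LIGX", "T1", "Healthy"], exp(0.4))
  conflict <- data.frame(base, ligand_lnfc = c(0.4, -0.4),
                         receptor_lnfc = 0.4)
  cfg2 <- simulation_config(n_cell_types = 3, n_genes = 60, lr_db = db,
                            conditions = c("Healthy", "CKD"),
                            planted_lr = conflict, seed = 5)
  expect_error(simulate_cell_programs(cfg2), "conflicting")
})

test_that("counts approach the Poisson limit as dispersion grows", {
  cfg <- simulation_config(n_cell_types = 1, n_genes = 60,
                           n_cells_per_type_per_condition = 5000,
                           conditions = c("Healthy", "CKD"),
                           lr_db = simulate_lr_database(5, seed = 1),
                           nb_dispersion = 1e6, library_size_sdlog = 1e-8,
                           seed = 8)
  truth <- simulate_cell_programs(cfg)
  cells <- simulate_cells(cfg, truth)
  X <- as.matrix(cells$counts[cells$condition == "Healthy", ])
  m <- colMeans(X); v <- apply(X, 2, var)
  top <- m > 5   # enough counts for a stable variance ratio
  expect_true(all(abs(v[top] / m[top] - 1) < 0.10))
  # and with real overdispersion the NB variance m + m^2/size shows up
  cfg2 <- simulation_config(n_cell_types = 1, n_genes = 60,
                            n_cells_per_type_per_condition = 5000,
                            conditions = c("Healthy", "CKD"),
                            lr_db = simulate_lr_database(5, seed = 1),
                            nb_dispersion = 2, library_size_sdlog = 1e-8,
                            seed = 8)
  cells2 <- simulate_cells(cfg2, simulate_cell_programs(cfg2))
  X2 <- as.matrix(cells2$counts[cells2$condition == "Healthy", ])
  m2 <- colMeans(X2); v2 <- apply(X2, 2, var)
  top2 <- m2 > 5
  expect_true(all(v2[top2] / m2[top2] > 1.5))
})

test_that("simulation is bit-identical under a fixed seed", {
  ds1 <- small_dataset(seed = 31)
  ds2 <- small_dataset(seed = 31)
  expect_identical(as.matrix(ds1$cells$counts), as.matrix(ds2$cells$counts))
  expect_identical(as.matrix(ds1$spots$counts), as.matrix(ds2$spots$counts))
  expect_identical(ds1$truth$composition, ds2$truth$composition)
})

test_that("degenerate configs are rejected", {
  expect_error(simulation_config(library_size_mean = 0), "library_size_mean")
  expect_error(simulation_config(cells_per_spot_mean = 0), "cells_per_spot")
  expect_error(simulation_config(conditions = "OnlyOne"), "two conditions")
  expect_error(simulation_config(colocalized_pairs = list(c("T1", "T2")),
                                 segregated_pairs = list(c("T2", "T1"))),
               "both colocalized and segregated")
  # too few archetypes for three mutually segregated types
  cfg_bad <- simulation_config(n_archetypes = 1,
                               segregated_pairs = list(c("T1", "T2")))
  truth <- simulate_cell_programs(cfg_bad)
  expect_error(simulate_spots(cfg_bad, truth), "n_archetypes too small")
})

test_that("single uniform archetype yields uniform long-run compositions", {
  cfg <- simulation_config(n_cell_types = 4, n_genes = 60,
                           n_cells_per_type_per_condition = 20,
                           conditions = c("Healthy", "CKD"),
                           n_archetypes = 1, n_spots_per_sample = 1250,
                           n_samples_per_condition = 2,
                           dirichlet_base = 1, dirichlet_dominant = 1,
                           lr_db = simulate_lr_database(5, seed = 1),
                           seed = 13)
  truth <- simulate_cell_programs(cfg)
  sp <- simulate_spots(cfg, truth)
  mean_comp <- colMeans(sp$truth$composition)   # 5,000 spots
  expect_true(all(abs(mean_comp - 0.25) < 0.02))
})

test_that("spots mix the configured number of cells and segregated pairs avoid each other", {
  cfg <- simulation_config(n_cell_types = 4, n_genes = 60,
                           n_cells_per_type_per_condition = 20,
                           conditions = c("Healthy", "CKD"),
                           n_spots_per_sample = 2500,
                           n_samples_per_condition = 2,
                           segregated_pairs = list(c("T1", "T2")),
                           lr_db = simulate_lr_database(5, seed = 1),
                           seed = 21)
  truth <- simulate_cell_programs(cfg)
  sp <- simulate_spots(cfg, truth)
  # mean cells per spot within 2% of 8 over 10,000 spots
  expect_gte(length(sp$truth$cells_per_spot), 10000)
  expect_lt(abs(mean(sp$truth$cells_per_spot) / 8 - 1), 0.02)
  expect_true(all(sp$truth$cells_per_spot >= 1))
  # segregated pair co-presence is rarer than independence would predict
  pres <- sp$truth$composition > 0.05
  both <- mean(pres[, "T1"] & pres[, "T2"])
  indep <- mean(pres[, "T1"]) * mean(pres[, "T2"])
  expect_lt(both, indep)
})
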