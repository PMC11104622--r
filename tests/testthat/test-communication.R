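test_that("group expression is the Tukey trimean with interpolated quartiles", {
  expect_equal(trimean(rep(3.7, 9)), 3.7)          # constant data
  expect_equal(trimean(c(1, 2, 3, 4, 5)), 3)       # symmetric
  x <- c(0, 0, 0, 0, 8)
  expect_equal(trimean(x), trimean_oracle(x))      # independent quantile math
  y <- c(0.3, 1.2, 5, 2.2, 0, 0, 7.5, 3.3)
  expect_equal(trimean(y), trimean_oracle(y))
  values <- matrix(c(x, y[1:5]), ncol = 2,
                   dimnames = list(sprintf("c%d", 1:5), c("g1", "g2")))
  nm <- norm_from_values(values, cell_type = rep("T1", 5))
  cfg <- communication_config(min_cells_per_type = 3)
  expect_equal(group_expression(nm, "g1", "T1", cfg), trimean_oracle(x))
  expect_error(group_expression(nm, "g1", "T2", cfg), "T2")
})

test_that("complex level is a zero-annihilating geometric mean", {
  expect_equal(complex_level(5), 5)
  expect_equal(complex_level(c(4, 1)), 2)
  expect_equal(complex_level(c(4, 0, 9)), 0)
  expect_equal(complex_level(c(2, 2, 2)), 2)
})

test_that("the Hill mass-action score behaves at its anchors", {
  cfg <- communication_config(hill_constant = 0.5)
  expect_equal(score_interaction(0, 3, cfg), 0)
  expect_equal(score_interaction(3, 0, cfg), 0)
  expect_equal(score_interaction(1, 1, cfg), 1 / 1.5)
  expect_equal(score_interaction(1e6, 1e6, cfg), 1, tolerance = 1e-6)
  # monotone in both arguments
  L <- seq(0, 4, by = 0.5)
  s <- score_interaction(L, 2, cfg)
  expect_true(all(diff(s) > 0))
  expect_true(all(s >= 0 & s < 1))
})

test_that("permutation p-value is 1 under constant expression and add-one bounded", {
  set.seed(1)
  values <- matrix(1.3, nrow = 40, ncol = 2,
                   dimnames = list(sprintf("c%d", 1:40), c("LIG", "REC")))
  nm <- norm_from_values(values, rep(c("T1", "T2"), each = 20))
  db <- lr_database("P1", "LIG", list("REC"))
  res <- permutation_test(nm, db[1, ], "T1", "T2",
                          communication_config(n_permutations = 50), seed = 2)
  expect_equal(res$p_value, 1)
  # a strong planted difference drives p to its add-one floor 1/(B+1)
  values2 <- values
  values2[1:20, "LIG"] <- 6
  values2[21:40, "REC"] <- 6
  values2[21:40, "LIG"] <- 0.01
  values2[1:20, "REC"] <- 0.01
  nm2 <- norm_from_values(values2, rep(c("T1", "T2"), each = 20))
  res2 <- permutation_test(nm2, db[1, ], "T1", "T2",
                           communication_config(n_permutations = 100), seed = 2)
  expect_equal(res2$p_value, 1 / 101)
})

test_that("p-values are invariant to relabeling cell ids", {
  ds <- small_dataset(seed = 41, n_per = 40)
  qc <- qc_filter(ds$cells, panel_qc())
  nm <- normalize_counts(qc$filtered)
  cs1 <- communication_scores(nm, ds$lr_db[1:4, ],
                              communication_config(n_permutations = 30),
                              seed = 6, conditions = "Healthy")
  nm2 <- nm
  nm2$unit_ids <- rev(nm2$unit_ids)   # ids are labels, not data
  cs2 <- communication_scores(nm2, ds$lr_db[1:4, ],
                              communication_config(n_permutations = 30),
                              seed = 6, conditions = "Healthy")
  expect_equal(cs1$p_value, cs2$p_value)
  expect_equal(cs1$score, cs2$score)
  expect_true(all(cs1$score >= 0 & cs1$score < 1))
  expect_true(all(cs1$p_value > 0 & cs1$p_value <= 1))
})

test_that("differential L-R applies thresholds, signs and the direction rule", {
  set.seed(8)
  n <- 120
  mk <- function(lnfc_lig, lnfc_rec) {
    # two conditions, one source type T1 (ligand) and target T2 (receptor)
    base_l <- rlnorm(2 * n, log(1), 0.1)
    base_r <- rlnorm(2 * n, log(1), 0.1)
    eff <- rep(c(0, 1), each = n)
    values <- cbind(LIG = log1p(expm1(base_l) * exp(lnfc_lig * eff)),
                    REC = log1p(expm1(base_r) * exp(lnfc_rec * eff)))
    rownames(values) <- sprintf("c%d", seq_len(2 * n))
    norm_from_values(rbind(values, values),
                     cell_type = rep(c("T1", "T2"), each = 2 * n),
                     condition = rep(rep(c("H", "D"), each = n), 2))
  }
  db <- lr_database("P1", "LIG", list("REC"))
  si <- data.frame(source_type = "T1", target_type = "T2", pair_id = "P1")
  up <- differential_lr(mk(0.30, 0.10), c("H", "D"), si, db,
                        communication_config())
  expect_equal(nrow(up), 1)
  expect_identical(up$direction, "up")
  expect_equal(up$ligand_lnFC, 0.30, tolerance = 0.1)
  down <- differential_lr(mk(-0.8, -0.39), c("H", "D"), si, db,
                          communication_config())
  expect_identical(down$direction, "down")
  mixed <- differential_lr(mk(0.2, -0.3), c("H", "D"), si, db,
                           communication_config())
  expect_equal(nrow(mixed), 0)
  weak <- differential_lr(mk(0.3, 0.05), c("H", "D"), si, db,
                          communication_config())
  expect_equal(nrow(weak), 0)   # receptor below the 0.1 lnFC threshold
})

test_that("reversing a comparison negates fold changes and swaps directions", {
  ds <- small_dataset(seed = 43, n_per = 80,
                      planted = data.frame(pair_id = "LIG01_REC01AREC01B",
                                           source_type = "T1",
                                           target_type = "T2",
                                           affected_condition = "CKD",
                                           ligand_lnfc = 0.6,
                                           receptor_lnfc = 0.6))
  nm <- normalize_counts(qc_filter(ds$cells, panel_qc())$filtered)
  si <- expand.grid(source_type = c("T1", "T2"), target_type = c("T1", "T2"),
                    pair_id = ds$lr_db$pair_id[1:3], stringsAsFactors = FALSE)
  fwd <- attr(differential_lr(nm, c("Healthy", "CKD"), si, ds$lr_db), "tested")
  rev <- attr(differential_lr(nm, c("CKD", "Healthy"), si, ds$lr_db), "tested")
  key <- paste(fwd$source_type, fwd$target_type, fwd$pair_id)
  rkey <- paste(rev$source_type, rev$target_type, rev$pair_id)
  idx <- match(key, rkey)
  expect_equal(fwd$ligand_lnFC, -rev$ligand_lnFC[idx], tolerance = 1e-6)
  expect_equal(fwd$receptor_lnFC, -rev$receptor_lnFC[idx], tolerance = 1e-6)
})

test_that("run_comparisons handles pooled conditions and unknown names", {
  ds <- small_dataset(seed = 44, n_per = 40,
                      conditions = c("Healthy", "F1-F2", "F3-F4"))
  nm <- normalize_counts(qc_filter(ds$cells, panel_qc())$filtered)
  cfgc <- communication_config(n_permutations = 20)
  out <- run_comparisons(nm, list(c("Healthy", "F1-F2"),
                                  c("Healthy", "MASH")),
                         ds$lr_db[1:5, ], cfgc,
                         pooled = list(MASH = c("F1-F2", "F3-F4")), seed = 3)
  expect_equal(nrow(out$summary), 2)
  expect_setequal(unique(out$communication$condition),
                  c("Healthy", "F1-F2", "MASH"))
  # pooled condition pools the cells of its member labels
  expect_error(run_comparisons(nm, list(c("Healthy", "Nope")), ds$lr_db,
                               cfgc, seed = 3), "Nope")
})
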