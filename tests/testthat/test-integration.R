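cooc_stub <- function(cluster_id, rows) {
  out <- do.call(rbind, lapply(rows, function(r)
    data.frame(cluster_id = cluster_id, type_a = r[[1]], type_b = r[[2]],
               N = 50, N1 = 25, N2 = 25, j = 20, p_gt = 0.001, p_lt = 1,
               classification = r[[3]], stringsAsFactors = FALSE)))
  class(out) <- c("cooccurrence_result", "data.frame")
  out
}

diff_stub <- function(...) {
  rows <- list(...)
  out <- do.call(rbind, lapply(rows, function(r)
    data.frame(source_type = r[[1]], target_type = r[[2]], pair_id = r[[3]],
               ligand_lnFC = r[[4]], receptor_lnFC = r[[4]],
               ligand_padj = 0.01, receptor_padj = 0.01,
               direction = if (r[[4]] > 0) "up" else "down",
               stringsAsFactors = FALSE)))
  class(out) <- c("differential_lr", "data.frame")
  out
}

test_that("the co-occurrence filter keeps positives, self-pairs, and honours the combine rule", {
  cc1 <- cooc_stub(1, list(list("A", "B", "positive"),
                           list("A", "C", "negative"),
                           list("B", "C", "random")))
  cc2 <- cooc_stub(2, list(list("A", "B", "random"),
                           list("A", "C", "negative"),
                           list("B", "C", "random")))
  diff <- diff_stub(list("A", "B", "P1", 0.5),
                    list("B", "A", "P2", 0.4),   # unordered pair matching
                    list("C", "A", "P3", 0.3),
                    list("C", "C", "P4", -0.2))  # autocrine
  un <- apply_cooccurrence_filter(diff, list(cc1, cc2), "union")
  expect_setequal(un$pair_id, c("P1", "P2", "P4"))
  expect_identical(un$cooccurrence_class[un$pair_id == "P4"], "positive")
  inter <- apply_cooccurrence_filter(diff, list(cc1, cc2), "intersection")
  expect_setequal(inter$pair_id, "P4")   # A-B positive in cluster 1 only
  # a type unknown to the spatial side is dropped with a warning
  diff2 <- diff_stub(list("A", "Zz", "P9", 0.5))
  expect_warning(out <- apply_cooccurrence_filter(diff2, list(cc1)),
                 "absent")
  expect_equal(nrow(out), 0)
})

test_that("hits carry evidence flags instead of dropping on missing genes", {
  values <- rbind(sp1 = c(L1 = 2, R1 = 3), sp2 = c(L1 = 1, R1 = 0))
  nm <- spots_norm_from_values(values)
  db <- lr_database(c("P1", "P2"), c("L1", "LGONE"), list("R1", "R1"))
  filtered <- diff_stub(list("A", "B", "P1", 0.2),
                        list("A", "B", "P2", 0.9))
  hits <- build_hits(filtered, nm, db)
  expect_equal(nrow(hits), 2)
  # ranked by summed |lnFC| descending: the flagged hit is larger
  expect_identical(hits$pair_id, c("P2", "P1"))
  expect_match(hits$evidence_flags[hits$pair_id == "P2"],
               "ligand-absent-from-panel")
  expect_equal(hits$coexpressed_fraction[hits$pair_id == "P1"], 0.5)
  # strict mode drops the flagged hit
  strict <- build_hits(filtered, nm, db, strict = TRUE)
  expect_identical(strict$pair_id, "P1")
  # zero surviving rows is a valid run
  empty <- build_hits(filtered[0, ], nm, db)
  expect_equal(nrow(empty), 0)
})

test_that("filter order does not matter: DE and co-occurrence are row predicates", {
  cc <- cooc_stub(1, list(list("A", "B", "positive"),
                          list("A", "C", "negative")))
  diff <- diff_stub(list("A", "B", "P1", 0.5), list("A", "C", "P2", 0.5),
                    list("A", "B", "P3", -0.3))
  keep_de <- diff[abs(diff$ligand_lnFC) >= 0.4, ]
  class(keep_de) <- c("differential_lr", "data.frame")
  a <- apply_cooccurrence_filter(keep_de, list(cc))
  b <- apply_cooccurrence_filter(diff, list(cc))
  b <- b[abs(b$ligand_lnFC) >= 0.4, ]
  expect_setequal(paste(a$pair_id), paste(b$pair_id))
})

test_that("the full pipeline runs deterministically end to end", {
  planted <- data.frame(pair_id = "LIG01_REC01AREC01B",
                        source_type = "T1", target_type = "T2",
                        affected_condition = "CKD",
                        ligand_lnfc = 0.6, receptor_lnfc = 0.6)
  ds <- small_dataset(seed = 77, n_per = 60, planted = planted,
                      coloc = list(c("T1", "T2")),
                      seg = list(c("T3", "T4")))
  cfg <- pipeline_config(
    qc = panel_qc(),
    comm = communication_config(n_permutations = 30),
    comparisons = list(c("Healthy", "CKD")),
    diseased_conditions = "CKD",
    types_of_interest = c("T1", "T2"),
    k_range = 1:8,
    seed = 5)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  r1 <- run_pipeline(ds$cells, ds$spots, ds$lr_db, cfg, out_dir = d1)
  r2 <- run_pipeline(ds$cells, ds$spots, ds$lr_db, cfg, out_dir = d2)
  expect_identical(readLines(file.path(d1, "hits.tsv")),
                   readLines(file.path(d2, "hits.tsv")))
  expect_identical(r1$all_hits, r2$all_hits)
  expect_true(file.exists(file.path(d1, "manifest.json")))
  m <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_true("cooccurrence_filter" %in% unlist(m$stages))
  # evidence trail: every hit's differential row exists verbatim upstream
  de <- r1$differential[["Healthy vs CKD"]]
  dekey <- paste(de$source_type, de$target_type, de$pair_id)
  hkey <- paste(r1$all_hits$source_type, r1$all_hits$target_type,
                r1$all_hits$pair_id)
  expect_true(all(hkey %in% dekey))
})

test_that("pipeline configuration is validated before any stage runs", {
  expect_error(pipeline_config(comparisons = list()), "comparison")
})

test_that("cross-run joins flag shared interactions and direction agreement", {
  ha <- data.frame(pair_id = c("P1", "P2"), source_type = "A",
                   target_type = "B", direction = c("up", "down"))
  hb <- data.frame(pair_id = c("P2", "P3"), source_type = "C",
                   target_type = "D", direction = c("up", "up"))
  cj <- common_interactions(ha, hb)
  expect_equal(cj$pair_id, "P2")
  expect_false(cj$same_direction)
})
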