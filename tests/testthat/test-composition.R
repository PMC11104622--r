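abundance_from_matrix <- function(P, condition = NULL, sample_id = NULL) {
  n <- nrow(P)
  if (is.null(rownames(P))) rownames(P) <- sprintf("sp%d", seq_len(n))
  structure(list(abundance = P,
                 sample_id = if (is.null(sample_id)) rep("sl1", n) else sample_id,
                 condition = if (is.null(condition)) rep("H", n) else condition,
                 converged = rep(TRUE, n)),
            class = "abundance_matrix")
}

test_that("hypergeometric tails match brute-force enumeration on small N", {
  # spot check a handful here; the exhaustive sweep lives in the acceptance
  # suite
  cases <- list(c(6, 3, 4, 2), c(7, 5, 2, 2), c(8, 4, 4, 1), c(5, 5, 3, 3))
  for (cs in cases) {
    N <- cs[1]; N1 <- cs[2]; N2 <- cs[3]; j <- cs[4]
    oracle <- brute_cooccurrence(N, N1, N2, j)
    expect_equal(phyper(j - 1, N1, N - N1, N2, lower.tail = FALSE),
                 unname(oracle["p_gt"]), tolerance = 1e-12)
    expect_equal(phyper(j, N1, N - N1, N2), unname(oracle["p_lt"]),
                 tolerance = 1e-12)
  }
  # the worked example: all 5 of one type on the 5 spots of the other
  expect_equal(phyper(4, 5, 5, 5, lower.tail = FALSE), 1 / 252)
})

test_that("co-occurrence classifies, symmetrizes and handles degenerate marginals", {
  set.seed(4)
  P <- matrix(0, nrow = 40, ncol = 4,
              dimnames = list(NULL, c("A", "B", "C", "D")))
  niche <- 1:18
  P[niche, c("A", "B")] <- 0.4          # A and B co-present in the niche
  P[-niche, "C"] <- 0.9                 # C fills the rest
  P[, "D"] <- 0                         # D never present
  P <- P + 0.01
  ab <- abundance_from_matrix(P / rowSums(P))
  cl <- list(labels = rep(1L, 40))
  class(cl) <- "composition_clustering"
  cc <- cooccurrence(ab, cl, 1)
  row <- function(a, b) cc[cc$type_a == a & cc$type_b == b, ]
  expect_identical(row("A", "B")$classification, "positive")
  expect_identical(row("A", "C")$classification, "negative")
  expect_identical(row("A", "D")$classification, "random")  # N2 = 0
  expect_equal(row("A", "D")$p_gt, 1)
  # self pairs pass regardless (autocrine signaling)
  expect_identical(row("D", "D")$classification, "positive")
  # p_gt + p_lt >= 1 (shared point mass)
  expect_true(all(cc$p_gt + cc$p_lt >= 1 - 1e-12))
  # symmetry under swapping the pair: recompute with reordered columns
  cc2 <- cooccurrence(abundance_from_matrix(P[, c(2, 1, 3, 4)] / rowSums(P)),
                      cl, 1)
  swapped <- cc2[(cc2$type_a == "A" & cc2$type_b == "B") |
                   (cc2$type_a == "B" & cc2$type_b == "A"), ]
  expect_equal(row("A", "B")$p_gt, swapped$p_gt)
  expect_equal(row("A", "B")$p_lt, swapped$p_lt)
})

test_that("three separated archetypes give an elbow at k = 3 and high ARI", {
  set.seed(11)
  centers <- rbind(c(0.8, 0.1, 0.05, 0.05),
                   c(0.05, 0.8, 0.1, 0.05),
                   c(0.05, 0.1, 0.05, 0.8))
  lab <- rep(1:3, each = 60)
  P <- centers[lab, ] + matrix(rnorm(180 * 4, sd = 0.02), ncol = 4)
  P <- pmax(P, 0); P <- P / rowSums(P)
  colnames(P) <- sprintf("T%d", 1:4)
  ab <- abundance_from_matrix(P)
  cl <- cluster_compositions(ab, 1:10, seed = 5)
  expect_equal(cl$selected_k, 3)
  # contingency-based adjusted Rand against the generating labels
  expect_gte(adjusted_rand(cl$labels, lab), 0.9)
  # WSS non-increasing in k
  expect_true(all(diff(cl$wss) <= 1e-8))
})

test_that("k equal to the number of distinct spots drives WSS to zero", {
  set.seed(2)
  P <- matrix(runif(12 * 3), ncol = 3, dimnames = list(NULL, c("A", "B", "C")))
  P <- P / rowSums(P)
  ab <- abundance_from_matrix(P)
  cl <- cluster_compositions(ab, c(1, 4, 12), seed = 1)
  expect_equal(cl$wss[cl$k == 12], 0, tolerance = 1e-12)
  expect_warning(cluster_compositions(ab, c(2, 20), seed = 1), "skipping")
})

test_that("cluster selection ranks by disease share and cell types of interest", {
  P <- rbind(matrix(rep(c(0.9, 0.05, 0.05), 10), ncol = 3, byrow = TRUE),
             matrix(rep(c(0.05, 0.9, 0.05), 10), ncol = 3, byrow = TRUE),
             matrix(rep(c(0.05, 0.05, 0.9), 10), ncol = 3, byrow = TRUE))
  colnames(P) <- c("A", "B", "C")
  cond <- c(rep("CKD", 10), rep("Healthy", 10), rep("CKD", 10))
  ab <- abundance_from_matrix(P, condition = cond)
  cl <- list(labels = rep(1:3, each = 10), condition = cond)
  class(cl) <- "composition_clustering"
  # cluster 2 has zero diseased spots: never auto-selected ahead of others
  sel <- select_clusters(cl, ab, diseased_conditions = "CKD",
                         types_of_interest = c("A", "C"), m = 2)
  expect_setequal(sel, c(1, 3))
  # manual override returned verbatim
  expect_identical(select_clusters(cl, ab, manual = c(1, 4)), c(1L, 4L))
  # tie broken toward the lower cluster id
  sel1 <- select_clusters(cl, ab, diseased_conditions = c("CKD", "Healthy"),
                          types_of_interest = c("A", "B", "C"), m = 1)
  expect_identical(sel1, 1L)
  expect_error(select_clusters(cl, ab, diseased_conditions = "CKD",
                               types_of_interest = character()),
               "types_of_interest")
})

test_that("duplicating every spot leaves cluster assignments unchanged", {
  set.seed(9)
  P <- matrix(runif(30 * 3), ncol = 3, dimnames = list(NULL, c("A", "B", "C")))
  P <- P / rowSums(P)
  ab1 <- abundance_from_matrix(P)
  ab2 <- abundance_from_matrix(rbind(P, P))
  cl1 <- cluster_compositions(ab1, 3, seed = 7)
  cl2 <- cluster_compositions(ab2, 3, seed = 7)
  # same optimum: each original spot keeps its companions
  co1 <- outer(cl1$labels, cl1$labels, "==")
  co2 <- outer(cl2$labels[1:30], cl2$labels[1:30], "==")
  expect_identical(co1, co2)
})
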