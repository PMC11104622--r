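test_that("the minimum principle scores and channels spots correctly", {
  values <- rbind(sp1 = c(g1 = 3, g2 = 5),
                  sp2 = c(g1 = 0, g2 = 2),
                  sp3 = c(g1 = 4, g2 = 0))
  nm <- spots_norm_from_values(values)
  m0 <- min_coexpression(nm, c("g1", "g2"), threshold = 0)
  expect_equal(m0$score, c(3, 0, 0))
  expect_identical(m0$channel, c("co-expressed", "gene2-only", "gene1-only"))
  # a noise threshold blanks sub-threshold scores and reassigns channels
  m4 <- min_coexpression(nm, c("g1", "g2"), threshold = 4)
  expect_equal(m4$score[1], 0)
  expect_identical(m4$channel[1], "gene2-only")
  # score never exceeds any member gene, and is permutation invariant
  m0b <- min_coexpression(nm, c("g2", "g1"), threshold = 0)
  expect_equal(m0$score, m0b$score)
  expect_true(all(m0$score <= values[, "g1"] & m0$score <= values[, "g2"]))
})

test_that("genes absent from the spot panel are a named error, not a skip", {
  values <- rbind(sp1 = c(g1 = 3, g2 = 5))
  nm <- spots_norm_from_values(values)
  expect_error(min_coexpression(nm, c("g1", "NRG3like")), "NRG3like")
  db <- lr_database("P1", "g1", list(c("g2", "missingSU")))
  expect_error(pair_coexpression_for_hit(nm, db[1, ]), "missingSU")
})

test_that("raising one gene's expression never lowers the min score", {
  set.seed(3)
  values <- matrix(runif(60, 0, 4), ncol = 3,
                   dimnames = list(sprintf("sp%d", 1:20),
                                   c("g1", "g2", "g3")))
  nm <- spots_norm_from_values(values)
  base <- min_coexpression(nm, c("g1", "g2", "g3"))$score
  values2 <- values; values2[, "g2"] <- values2[, "g2"] + 1
  up <- min_coexpression(spots_norm_from_values(values2),
                         c("g1", "g2", "g3"))$score
  expect_true(all(up >= base))
})

test_that("pair co-expression fractions are per slide and zero without ligand", {
  values <- rbind(sp1 = c(L = 2, R = 3), sp2 = c(L = 0, R = 4),
                  sp3 = c(L = 1, R = 1), sp4 = c(L = 0, R = 0))
  nm <- spots_norm_from_values(values,
                               sample_id = c("a", "a", "b", "b"),
                               condition = c("H", "H", "D", "D"))
  db <- lr_database("P1", "L", list("R"))
  res <- pair_coexpression_for_hit(nm, db[1, ])
  expect_equal(res$fraction_by_slide$fraction,
               c(0.5, 0.5))   # slide a: sp1 only; slide b: sp3 only
  # ligand silenced everywhere: co-expressed fraction 0
  values0 <- values; values0[, "L"] <- 0
  res0 <- pair_coexpression_for_hit(spots_norm_from_values(values0), db[1, ])
  expect_equal(res0$fraction_by_slide$fraction, 0)
})

test_that("spatial correlation is per slide, affine invariant, NA on constants", {
  set.seed(6)
  n <- 30
  a <- runif(2 * n)
  nm <- spots_norm_from_values(matrix(1, nrow = 2 * n, ncol = 1,
                                      dimnames = list(sprintf("sp%d", 1:(2 * n)), "g")),
                               sample_id = rep(c("s1", "s2"), each = n),
                               condition = rep(c("H", "D"), each = n))
  self <- spatial_correlation(nm, a, a)
  expect_equal(self$per_slide$r, c(1, 1))
  anti <- spatial_correlation(nm, a, -a + 2)
  expect_equal(anti$per_slide$r, c(-1, -1))
  affine <- spatial_correlation(nm, a, 3 * a + 1)
  expect_equal(affine$per_slide$r, c(1, 1))
  # constant vector on a slide is reported missing and excluded
  b <- a; b[1:n] <- 5
  con <- spatial_correlation(nm, a, b)
  expect_true(is.na(con$per_slide$r[1]))
  expect_equal(con$aggregate$n_slides[con$aggregate$group == "all"], 1)
})

test_that("a planted condition-linked pair correlates more with markers in disease", {
  # niche spots in the diseased slide express pair and marker together
  set.seed(12)
  n <- 60
  mkslide <- function(link) {
    niche <- rbinom(n, 1, 0.5)
    noise <- function() runif(n, 0, 0.3)
    cbind(L = 2 * niche * link + noise(),
          R = 2 * niche * link + noise(),
          MRK = 2 * niche + noise())
  }
  values <- rbind(mkslide(0), mkslide(1))
  rownames(values) <- sprintf("sp%d", seq_len(2 * n))
  nm <- spots_norm_from_values(values,
                               sample_id = rep(c("h1", "d1"), each = n),
                               condition = rep(c("H", "D"), each = n))
  db <- lr_database("P1", "L", list("R"))
  score <- pair_coexpression_for_hit(nm, db[1, ])$map$score
  sc <- spatial_correlation(nm, score, values[, "MRK"])
  agg <- sc$aggregate
  expect_gt(agg$median_r[agg$group == "D"], agg$median_r[agg$group == "H"])
})
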