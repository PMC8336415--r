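test_that("average divergence is the mean over included genes", {
  PD <- matrix(10, nrow = 3, ncol = 6)
  PD[, 1] <- c(10, 20, 30)
  PD[, 2] <- c(10, NA, 30)
  PD[, 3] <- 0
  dm <- tiny_divergence(PD)
  av <- average_divergence(dm)
  expect_equal(unname(av[1:3]), c(20, 20, 0))

  PD[, 4] <- NA
  expect_error(average_divergence(tiny_divergence(PD)),
               "zero included genes")
})

test_that("clock regression recovers an exact through-origin line", {
  t <- c(60, 70, 96, 104, 158.5)
  fit <- clock_regression(0.13 * t, t)
  expect_equal(fit$k_av, 0.13)
  expect_equal(fit$R2, 1)
  expect_equal(fit$n_pairs, 5)
  expect_equal(fit$residuals, rep(0, 5))

  single <- clock_regression(20.8, 160)
  expect_equal(single$k_av, 0.13)

  expect_error(clock_regression(c(1, 2), c(10, 10), through_origin = FALSE),
               "distinct divergence times")
  free <- clock_regression(5 + 0.1 * t, t, through_origin = FALSE)
  expect_equal(free$k_av, 0.1)
  expect_equal(free$intercept, 5)
})

test_that("normalization divides by the pair average and keeps masks", {
  PD <- matrix(c(2.6, 0, 1.3, 1.3, NA, 2), nrow = 2, ncol = 6)
  dm <- tiny_divergence(PD)
  nd <- normalize_divergence(dm)
  expect_equal(nd$nPD[1, 1], 2.6 / 1.3)
  expect_true(is.na(nd$nPD[1, 3]))

  # all genes equal -> all nPD 1
  dm2 <- tiny_divergence(matrix(7, nrow = 4, ncol = 6))
  expect_true(all(normalize_divergence(dm2)$nPD == 1))

  # degenerate pair
  dm3 <- tiny_divergence(matrix(0, nrow = 2, ncol = 6))
  expect_error(normalize_divergence(dm3), "PDav = 0")
})

test_that("mean nPD over included genes is exactly 1 for every pair", {
  set.seed(41)
  for (i in 1:5) {
    PD <- matrix(runif(40 * 6, 0, 60), nrow = 40)
    PD[sample(length(PD), 30)] <- NA
    nd <- normalize_divergence(tiny_divergence(PD))
    expect_equal(unname(colMeans(nd$nPD, na.rm = TRUE)), rep(1, 6))
  }
})

test_that("nPD is invariant to rescaling a pair's divergences (time removal)", {
  set.seed(42)
  PD <- matrix(runif(30 * 6, 0, 40), nrow = 30)
  nd <- normalize_divergence(tiny_divergence(PD))
  PD2 <- PD
  PD2[, 3] <- PD[, 3] * 2.5  # as if that pair were 2.5x more diverged in time
  nd2 <- normalize_divergence(tiny_divergence(PD2))
  expect_equal(nd2$nPD, nd$nPD)
})

test_that("per-gene class means average over the class pairs only", {
  PD <- matrix(NA_real_, nrow = 2, ncol = 6,
               dimnames = list(c("g1", "g2"), NULL))
  dm <- tiny_divergence(matrix(c(10, 20), nrow = 2, ncol = 6))
  nd <- normalize_divergence(dm)
  # tiny_species: pair 1 (cow-rat) intra-Eutherian, pair 6 (koala-wombat) intra-Metatherian
  expect_equal(dm$pairs$pair_class[1], "intra-Eutherian")
  m <- npd_gene_means(nd, "intra-Eutherian")
  expect_equal(unname(m), c(10, 20) / 15)
  expect_error(npd_gene_means(nd, "no-such-class"), "no pairs of class")
})

test_that("clade-mean landscape of duplicated identical tracks equals each track", {
  set.seed(43)
  ord <- block_order(1, 80)
  rownames_PD <- ord$gene_id
  PD <- matrix(runif(80, 1, 30), nrow = 80, ncol = 6,
               dimnames = list(rownames_PD, NULL))
  nd <- normalize_divergence(tiny_divergence(PD))
  cm <- clade_mean_landscape(nd, ord, "intra-Eutherian", half_width = 10)
  single <- sliding_window(nd$nPD[ord$gene_id, "1"], ord, half_width = 10)
  expect_equal(cm$values, single$values)
})

test_that("window-then-average equals average-then-window on missing-free data", {
  set.seed(44)
  ord <- block_order(1, 120)
  PD <- matrix(runif(120 * 6, 1, 40), nrow = 120,
               dimnames = list(ord$gene_id, NULL))
  nd <- normalize_divergence(tiny_divergence(PD))
  cm <- clade_mean_landscape(nd, ord, "intra-Metatherian", half_width = 15)
  gm <- npd_gene_means(nd, "intra-Metatherian")
  direct <- sliding_window(gm[ord$gene_id], ord, half_width = 15)
  expect_equal(cm$values, direct$values)
})
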