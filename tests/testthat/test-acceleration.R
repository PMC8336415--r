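test_that("a constant metric gives SD 0 and threshold equal to the mean", {
  ord <- block_order(2, 100)
  null <- random_order_null(rep(2, 200), ord, half_width = 10, seed = 1)
  expect_equal(null$sd, 0)
  expect_equal(null$threshold, null$mean)
  expect_equal(null$mean, 2)
})

test_that("the null is reproducible from the seed and label-invariant", {
  set.seed(51)
  ord <- block_order(3, 100)
  v <- stats::setNames(rlnorm(300), ord$gene_id)
  n1 <- random_order_null(v, ord, half_width = 20, seed = 7)
  n2 <- random_order_null(v, ord, half_width = 20, seed = 7)
  expect_identical(n1, n2)
  n3 <- random_order_null(v, ord, half_width = 20, seed = 8)
  expect_false(identical(n1$threshold, n3$threshold))

  # relabeling genes (same value multiset on the same partition) changes nothing
  v_perm <- stats::setNames(unname(v)[sample.int(300)], ord$gene_id)
  n4 <- random_order_null(v_perm, ord, half_width = 20, seed = 7)
  expect_equal(n4$threshold, n1$threshold)
})

test_that("threshold elevation over the mean follows the CLT prediction", {
  set.seed(52)
  n <- 4000
  ord <- block_order(1, n)
  v <- rlnorm(n, 0, 0.6)
  cv <- sd(v) / mean(v)
  null <- random_order_null(v, ord, half_width = 50, n_reps = 40, seed = 3)
  predicted <- 3 * cv / sqrt(101)
  expect_lt(abs((null$threshold / null$mean - 1) / predicted - 1), 0.15)
})

test_that("exceedance uses a strict inequality and reads genes off the order", {
  ord <- block_order(1, 200)
  ls <- landscape(rep(1, 200), ord, window_half_width = 10L)
  null <- list(threshold = 1, n_reps = 1L, mean = 1, sd = 0, sd_multiplier = 3)
  class(null) <- "null_distribution"
  expect_equal(exceedance_set(ls, null)$n, 0)  # equal is not above

  v <- rep(0.5, 200); v[30:40] <- 2; v[100] <- NA
  ls2 <- landscape(v, ord, window_half_width = 10L)
  res <- exceedance_set(ls2, null)
  expect_equal(res$ranks, 30:40)
  expect_equal(res$genes, ord$gene_id[30:40])
  expect_equal(res$n_windows, 199)
})

test_that("exceedance counts shrink as the SD multiplier grows", {
  set.seed(53)
  ord <- block_order(1, 1000)
  v <- rlnorm(1000)
  ls <- sliding_window(v, ord, half_width = 20)
  counts <- vapply(c(0, 1, 2, 3), function(m) {
    null <- random_order_null(v, ord, half_width = 20, sd_multiplier = m,
                              seed = 9)
    exceedance_set(ls, null)$n
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("venn overlap counts are plain set arithmetic", {
  expect_equal(venn_overlap("g1", "g2"), c(a_only = 1, b_only = 1, both = 0))
  expect_equal(venn_overlap(c("g1", "g2"), c("g1", "g2")),
               c(a_only = 0, b_only = 0, both = 2))
  expect_equal(venn_overlap(c("g1", "g2", "g3"), c("g2", "g3", "g4")),
               c(a_only = 1, b_only = 1, both = 2))
})

test_that("subtelomere enrichment reproduces the printed-count arithmetic", {
  # 908 of 1,833 accelerated windows subtelomeric vs 2,300 of 15,757 overall
  exceeding <- c(1:908, 5001:5925)          # 908 inside the labels, 925 outside
  enr <- subtelomere_enrichment(exceeding, labels = seq_len(2300),
                                n_total = 15757)
  expect_equal(enr$n_exceeding, 1833)
  expect_equal(enr$n_subtelomeric_exceeding, 908)
  expect_equal(round(100 * enr$observed), 50)
  expect_equal(round(100 * enr$expected), 15)
  expect_equal(enr$fold, (908 / 1833) / (2300 / 15757))

  all_sub <- subtelomere_enrichment(c(3L, 5L), labels = 1:10, n_total = 100)
  expect_equal(all_sub$observed, 1)
  expect_equal(all_sub$fold, 10)

  empty <- subtelomere_enrichment(integer(0), labels = 1:10, n_total = 100)
  expect_true(empty$empty)
  expect_true(is.na(empty$observed))
})

test_that("a uniformly drawn exceedance set has fold enrichment near 1", {
  set.seed(54)
  labels <- 1:2300
  folds <- replicate(20, {
    picked <- sample.int(15727, 1000)
    subtelomere_enrichment(picked, labels, 15727)$fold
  })
  expect_lt(abs(mean(folds) - 1), 0.1)
})

test_that("null rejects genomes smaller than one window", {
  ord <- block_order(1, 50)
  expect_error(random_order_null(rnorm(50), ord, half_width = 50),
               "smaller than one window")
})
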