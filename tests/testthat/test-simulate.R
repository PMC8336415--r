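small_config <- function(...) {
  sim_config(n_genes = 600,
             order_a_weights = c(chr1 = 3, chr2 = 2, chr3 = 1),
             order_b_weights = c(chr1 = 2, chr2 = 1),
             acceleration_blocks = NULL, ...)
}

test_that("rates are reproducible, heavy-tailed, and degenerate at sigma 0", {
  cfg <- small_config()
  orders <- simulate_genome_orders(cfg, seed = 1)
  r1 <- simulate_rates(cfg, orders, seed = 2)
  r2 <- simulate_rates(cfg, orders, seed = 2)
  expect_identical(r1$k, r2$k)
  expect_false(identical(r1$k, simulate_rates(cfg, orders, seed = 3)$k))

  cfg0 <- small_config(sigma_k = 0)
  r0 <- simulate_rates(cfg0, orders, seed = 2)
  expect_true(all(r0$k == cfg0$mean_clock))

  # default dispersion spans ~two orders of magnitude
  cfg_full <- sim_config()
  ord_full <- simulate_genome_orders(cfg_full, seed = 1)
  k <- simulate_rates(cfg_full, ord_full, seed = 4)$k
  ratio <- unname(quantile(k, 0.99) / quantile(k, 0.01))
  expect_gt(ratio, 50)
  expect_lt(ratio, 500)
})

test_that("acceleration blocks mark the right genes in the right lineage", {
  cfg <- small_config()
  cfg$acceleration_blocks <- data.frame(
    order = "A", chromosome = "chr2", side = "start", n_genes = 50L,
    lineage = "Eutheria", multiplier = 3, stringsAsFactors = FALSE)
  orders <- simulate_genome_orders(cfg, seed = 1)
  truth <- simulate_rates(cfg, orders, seed = 2)
  iv <- chromosome_intervals(orders$order_a)
  expected <- orders$order_a$gene_id[iv$from[2]:(iv$from[2] + 49)]
  expect_setequal(truth$planted_eutherian, expected)
  expect_length(truth$planted_metatherian, 0)
  expect_true(all(truth$mult_eutherian[expected] == 3))
  expect_true(all(truth$mult_metatherian == 1))
})

test_that("divergence is 0 at t ~ 0 and grows with divergence time", {
  cfg <- small_config()
  orders <- simulate_genome_orders(cfg, seed = 1)
  truth <- simulate_rates(cfg, orders, seed = 2)
  sp <- cfg$species
  pairs <- make_pair_table(sp, list(within_clade = 1e-9,
                                    within_metatheria = 1e-9,
                                    boreoeutheria = 1e-9,
                                    afrotheria_split = 1e-9,
                                    eutheria_metatheria = 1e-9))
  dm0 <- simulate_divergences(truth, pairs, cfg, seed = 3)
  expect_true(all(dm0$PD == 0))

  pairs_real <- make_pair_table(sp)
  dm <- simulate_divergences(truth, pairs_real, cfg, seed = 3)
  pd_av <- average_divergence(dm)
  # realized mean divergence increases with separation time across classes
  by_t <- tapply(pd_av, pairs_real$t, mean)
  expect_true(all(diff(by_t[order(as.numeric(names(by_t)))]) > 0))
})

test_that("the whole synthetic study is reproducible from (config, seed)", {
  cfg <- small_config()
  s1 <- simulate_study(cfg, seed = 5)
  s2 <- simulate_study(cfg, seed = 5)
  expect_identical(s1$divergence$PD, s2$divergence$PD)
  expect_identical(s1$order_b$gene_id, s2$order_b$gene_id)
  expect_identical(s1$gc, s2$gc)
  s3 <- simulate_study(cfg, seed = 6)
  expect_false(identical(s1$divergence$PD, s3$divergence$PD))
})

test_that("windowed GC and GARP tracks correlate near the coupling rho", {
  cfg <- sim_config()
  orders <- simulate_genome_orders(cfg, seed = 1)
  tracks <- simulate_gc_garp(cfg, orders, seed = 2)
  for (sp in c("felis_catus", "phascolarctos_cinereus")) {
    ord <- if (sp == "felis_catus") orders$order_a else orders$order_b
    gc_ls <- sliding_window(tracks$gc[, sp], ord)
    garp_ls <- sliding_window(tracks$garp[, sp], ord)
    r <- correlate_landscapes(gc_ls, garp_ls)
    expect_gt(r, 0.90)
    expect_lt(r, 0.96)
  }
})

test_that("without regional structure the GC landscape is flat up to noise", {
  cfg <- small_config()
  cfg$gc_garp$gc_regional_sd <- 0
  cfg$gc_garp$species_regional_sd <- 0
  cfg$gc_garp$gc_subtel_boost <- 0
  orders <- simulate_genome_orders(cfg, seed = 1)
  tracks <- simulate_gc_garp(cfg, orders, seed = 2)
  ls <- sliding_window(tracks$gc[, "sus_scrofa"], orders$order_a, half_width = 50)
  # windowed gene noise: sd ~ gc_noise_sd / sqrt(101)
  expect_lt(sd(ls$values, na.rm = TRUE),
            3 * cfg$gc_garp$gc_noise_sd / sqrt(101))
})

test_that("zero-rate genes yield identical proteins through the full aligner", {
  cfg <- small_config(sigma_k = 0)
  orders <- simulate_genome_orders(cfg, seed = 1)
  truth <- simulate_rates(cfg, orders, seed = 2)
  truth$k[] <- 0
  orth <- simulate_sequences(truth, cfg, n_genes = 3, length = 120, seed = 3)
  pairs <- make_pair_table(cfg$species)
  dm <- build_divergence_matrix(orth, pairs, run_config())
  expect_true(all(dm$PD == 0))
})

test_that("aligner-measured divergence tracks k * t within 10% end to end", {
  cfg <- sim_config(sigma_k = 0.5, mean_clock = 0.06,
                    acceleration_blocks = NULL)
  orders <- simulate_genome_orders(cfg, seed = 1)
  truth <- simulate_rates(cfg, orders, seed = 2)
  orth <- simulate_sequences(truth, cfg, n_genes = 60, length = 300, seed = 3)
  pairs <- make_pair_table(cfg$species)
  # one within-clade pair: t = 70 My
  pair <- pairs[pairs$species_a == "sus_scrofa" &
                  pairs$species_b == "felis_catus", ]
  dm <- build_divergence_matrix(orth, pair, run_config())
  expected <- truth$k[rownames(dm$PD)] * pair$t
  slope <- sum(expected * dm$PD[, 1]) / sum(expected^2)
  expect_gt(slope, 0.9)
  expect_lt(slope, 1.1)
})

test_that("mean nPD over included genes is 1 on every simulated matrix", {
  sim <- simulate_study(small_config(), seed = 9)
  nd <- normalize_divergence(sim$divergence)
  expect_equal(unname(colMeans(nd$nPD, na.rm = TRUE)),
               rep(1, nrow(sim$pairs)))
})
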