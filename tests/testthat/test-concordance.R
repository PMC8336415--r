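two_orders <- function() {
  # order A: two chromosomes of 10; order B rotates the genes by two,
  # so some chromosome ends are conserved and others are not
  a <- genome_order(sprintf("g%02d", 1:20), rep(c("c1", "c2"), each = 10))
  b <- genome_order(sprintf("g%02d", c(3:12, 13:20, 1:2)),
                    rep(c("d1", "d2"), each = 10))
  list(a = a, b = b)
}

test_that("links are green only when subtelomeric in both orders", {
  o <- two_orders()
  links <- map_genes_between_orders(c("g01", "g05", "g10"), o$a, o$b, margin = 2)
  expect_equal(links$color[links$gene_id == "g01"], "green")  # subtel in both
  expect_equal(links$color[links$gene_id == "g05"], "black")  # in neither
  g10 <- links[links$gene_id == "g10", ]                      # A end only
  expect_true(g10$subtel_a && !g10$subtel_b)
  expect_equal(g10$color, "black")
  # subtelomeric only in order B -> black as well
  links2 <- map_genes_between_orders("g03", o$a, o$b, margin = 2)
  expect_true(links2$subtel_b && !links2$subtel_a)
  expect_equal(links2$color, "black")
})

test_that("link classification is symmetric and counts add up", {
  o <- two_orders()
  genes <- sprintf("g%02d", 1:20)
  ab <- map_genes_between_orders(genes, o$a, o$b, margin = 3)
  ba <- map_genes_between_orders(genes, o$b, o$a, margin = 3)
  m <- match(ab$gene_id, ba$gene_id)
  expect_equal(ab$color, ba$color[m])
  s <- concordance_summary(ab)
  expect_equal(s$n_green + s$n_black, nrow(ab))

  only_green <- ab[ab$color == "green", ]
  expect_equal(concordance_summary(only_green)$green_fraction, 1)
})

test_that("genes absent from an order are dropped, empty intersection errors", {
  o <- two_orders()
  expect_message(
    links <- map_genes_between_orders(c("g01", "nope"), o$a, o$b, margin = 2),
    "dropped 1")
  expect_equal(nrow(links), 1)
  expect_error(map_genes_between_orders("nope", o$a, o$b), "both orders")
})

test_that("link files round-trip, including the empty case", {
  o <- two_orders()
  links <- map_genes_between_orders(c("g01", "g05", "g10"), o$a, o$b, margin = 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  export_links(links, o$a, o$b, f)
  back <- read_links(f)
  expect_equal(nrow(back), 3)
  expect_setequal(back$gene_id, links$gene_id)
  expect_equal(back$color[match(links$gene_id, back$gene_id)], links$color)
  expect_equal(back$end_a, back$start_a + 1L)

  f2 <- withr::local_tempfile(fileext = ".tsv")
  export_links(links[0, ], o$a, o$b, f2)
  expect_true(grepl("^#", readLines(f2)[1]))
  expect_equal(nrow(read_links(f2)), 0)
})

test_that("arm-shuffled orders keep subtelomeric genes subtelomeric", {
  ord <- block_order(12, 200)
  margin <- 20
  sub_genes <- ord$gene_id[subtelomere_labels(ord, margin)]
  pres <- make_order_b(ord, "subtelomere-preserving", seed = 5)
  expect_setequal(pres$gene_id, ord$gene_id)
  links <- map_genes_between_orders(sub_genes, ord, pres, margin = margin)
  expect_gte(concordance_summary(links)$green_fraction, 0.8)

  ident <- make_order_b(ord, "identity")
  links_id <- map_genes_between_orders(sub_genes, ord, ident, margin = margin)
  expect_equal(concordance_summary(links_id)$green_fraction, 1)
})

test_that("reshuffled orders place subtelomeric genes uniformly", {
  ord <- block_order(12, 200)
  margin <- 20
  sub_genes <- ord$gene_id[subtelomere_labels(ord, margin)]
  expected <- length(sub_genes) / nrow(ord)   # 480/2400 = 0.2
  set.seed(55)
  fracs <- vapply(1:5, function(s) {
    resh <- make_order_b(ord, "reshuffled", seed = s)
    links <- map_genes_between_orders(sub_genes, ord, resh, margin = margin)
    concordance_summary(links)$green_fraction
  }, numeric(1))
  se <- sqrt(expected * (1 - expected) / length(sub_genes))
  expect_lt(abs(mean(fracs) - expected), 4 * se)
})
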