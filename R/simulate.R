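#' Synthetic-study configuration
#'
#' Defines the generative model for a synthetic cohort with the statistical
#' structure the pipeline assumes: 16 species (12 Eutheria in three clades of
#' four, 4 Metatheria), ~15,727 shared genes, a human-like gene order A (23
#' chromosomes, human-like relative gene counts) and an opossum-like order B
#' (8 autosomes + X, few and large), heavy-tailed lognormal per-gene clock
#' rates, lineage-specific subtelomeric acceleration blocks, binomial
#' site-sampling noise, and GC/GARP tracks with regional structure and a
#' within-species coupling of 0.93.
#'
#' Divergence is generated linearly in time with a 95% cap rather than via an
#' explicit substitution model, matching uncorrected protein divergence;
#' sequence-level simulation ([simulate_sequences()]) is the optional, slower
#' path.
#'
#' @param n_genes number of shared genes (default 15,727).
#' @param order_a_weights,order_b_weights named relative chromosome gene
#'   counts for the two reference orders.
#' @param species a [species_table()] (default the 16-mammal design).
#' @param times divergence times, see [default_divergence_times()].
#' @param mean_clock genome-mean baseline clock constant (%/My, default 0.13,
#'   i.e. 1.3% per 10 My).
#' @param sigma_k lognormal sd of per-gene rates (default 0.9, spreading the
#'   1st-to-99th rate percentiles over about two orders of magnitude).
#' @param n_sites binomial sites per gene (default 450, a typical protein
#'   length).
#' @param cap_pd cap on expected divergence (%), default 95.
#' @param identity_floor identities below this are masked, mirroring the
#'   alignment filter (PD above 100 - floor masked).
#' @param acceleration_blocks data.frame with columns `order` ("A"/"B"),
#'   `chromosome`, `side` ("start"/"end"), `n_genes`, `lineage`
#'   ("Eutheria"/"Metatheria"), `multiplier`; `NULL` for a strict-clock
#'   cohort with no regional effects.
#' @param gc_garp list of GC/GARP generator parameters (means, regional and
#'   gene-level noise SDs, subtelomeric GC boost, boost margin, coupling
#'   `rho`).
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_genes = 15727,
                       order_a_weights = NULL,
                       order_b_weights = NULL,
                       species = mammal_species_table(),
                       times = default_divergence_times(),
                       mean_clock = 0.13,
                       sigma_k = 0.9,
                       n_sites = 450,
                       cap_pd = 95,
                       identity_floor = 30,
                       acceleration_blocks = default_acceleration_blocks(),
                       gc_garp = list(gc_mean = 46, gc_regional_sd = 3,
                                      species_regional_sd = 1,
                                      gc_noise_sd = 2, gc_subtel_boost = 6,
                                      garp_mean = 12, garp_regional_sd = 1.5,
                                      garp_noise_sd = 1, rho = 0.93,
                                      boost_margin = 150,
                                      smoothing_half_width = 150)) {
  if (sigma_k < 0) abort("sigma_k must be >= 0")
  if (mean_clock <= 0) abort("mean_clock must be > 0")
  if (!is.null(gc_garp$rho) && abs(gc_garp$rho) >= 1) {
    abort("gc_garp$rho must lie in (-1, 1)")
  }
  order_a_weights <- order_a_weights %||% c(
    chr1 = 2000, chr2 = 1235, chr3 = 1060, chr4 = 750, chr5 = 880,
    chr6 = 1040, chr7 = 900, chr8 = 670, chr9 = 780, chr10 = 730,
    chr11 = 1300, chr12 = 1030, chr13 = 320, chr14 = 620, chr15 = 600,
    chr16 = 860, chr17 = 1190, chr18 = 270, chr19 = 1470, chr20 = 540,
    chr21 = 230, chr22 = 440, chrX = 840)
  order_b_weights <- order_b_weights %||% c(
    chr1 = 3000, chr2 = 2500, chr3 = 2400, chr4 = 1800, chr5 = 1500,
    chr6 = 1400, chr7 = 1000, chr8 = 700, chrX = 430)
  structure(list(n_genes = as.integer(n_genes),
                 order_a_weights = order_a_weights,
                 order_b_weights = order_b_weights,
                 species = species, times = times,
                 mean_clock = mean_clock, sigma_k = sigma_k,
                 n_sites = as.integer(n_sites), cap_pd = cap_pd,
                 identity_floor = identity_floor,
                 acceleration_blocks = acceleration_blocks,
                 gc_garp = gc_garp),
            class = "sim_config")
}

#' Default lineage-specific acceleration blocks
#'
#' Three 300-gene blocks per lineage with a 3x rate multiplier, planted at
#' subtelomeres the study design singles out: the 4p, 14q and Xq ends of the
#' human-like order A for Eutheria, and the 1q, 6q and Xq ends of the
#' opossum-like order B for Metatheria.
#'
#' @return a data.frame in the [sim_config()] `acceleration_blocks` layout.
#' @export
default_acceleration_blocks <- function() {
  data.frame(
    order = c("A", "A", "A", "B", "B", "B"),
    chromosome = c("chr4", "chr14", "chrX", "chr1", "chr6", "chrX"),
    side = c("start", "end", "end", "end", "end", "end"),
    n_genes = 300L,
    lineage = rep(c("Eutheria", "Metatheria"), each = 3),
    multiplier = 3,
    stringsAsFactors = FALSE)
}

# Largest-remainder apportionment of n genes over relative weights.
apportion <- function(n, weights) {
  raw <- n * weights / sum(weights)
  sizes <- floor(raw)
  left <- n - sum(sizes)
  if (left > 0) {
    extra <- order(raw - sizes, decreasing = TRUE)[seq_len(left)]
    sizes[extra] <- sizes[extra] + 1
  }
  stats::setNames(as.integer(sizes), names(weights))
}

#' Simulate the two reference genome orders
#'
#' Order A is human-like (23 chromosomes); order B is opossum-like (8 large
#' autosomes + X) and carries the genes in an independent random order,
#' emulating the karyotype independence of the two lineages.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @return list with `order_a`, `order_b` ([genome_order()] objects).
#' @export
simulate_genome_orders <- function(config, seed = 1L) {
  n <- config$n_genes
  genes <- sprintf("g%05d", seq_len(n))
  sizes_a <- apportion(n, config$order_a_weights)
  order_a <- genome_order(genes, rep(names(sizes_a), sizes_a))
  sizes_b <- apportion(n, config$order_b_weights)
  perm <- with_seed(seed, sample.int(n))
  order_b <- genome_order(genes[perm], rep(names(sizes_b), sizes_b))
  list(order_a = order_a, order_b = order_b)
}

block_ranks <- function(order, chromosome, side, n_genes) {
  iv <- chromosome_intervals(order)
  row <- match(chromosome, iv$chromosome)
  if (is.na(row)) abort("block chromosome '%s' not in order", chromosome)
  n_genes <- min(n_genes, iv$to[row] - iv$from[row] + 1L)
  if (side == "start") iv$from[row]:(iv$from[row] + n_genes - 1L)
  else (iv$to[row] - n_genes + 1L):iv$to[row]
}

#' Simulate heavy-tailed per-gene clock rates and the planted truth
#'
#' Per-gene baseline rates are lognormal with genome mean
#' `config$mean_clock`; acceleration blocks assign lineage-specific
#' multipliers to the genes at their rank intervals.
#'
#' @param config a [sim_config()].
#' @param orders result of [simulate_genome_orders()].
#' @param seed RNG seed.
#' @return a `synthetic_truth`: list with per-gene `k`, `mult_eutherian`,
#'   `mult_metatherian`, planted gene sets per lineage, and the orders.
#' @export
simulate_rates <- function(config, orders, seed = 1L) {
  n <- config$n_genes
  genes <- orders$order_a$gene_id[order(orders$order_a$gene_id)]
  mu <- log(config$mean_clock) - config$sigma_k^2 / 2
  k <- with_seed(seed, stats::rlnorm(n, mu, config$sigma_k))
  names(k) <- genes
  mult_e <- stats::setNames(rep(1, n), genes)
  mult_m <- stats::setNames(rep(1, n), genes)
  blocks <- config$acceleration_blocks
  if (!is.null(blocks) && nrow(blocks) > 0) {
    for (i in seq_len(nrow(blocks))) {
      ord <- if (blocks$order[i] == "A") orders$order_a else orders$order_b
      ranks <- block_ranks(ord, blocks$chromosome[i], blocks$side[i],
                           blocks$n_genes[i])
      ids <- ord$gene_id[ranks]
      if (blocks$lineage[i] == "Eutheria") {
        mult_e[ids] <- pmax(mult_e[ids], blocks$multiplier[i])
      } else {
        mult_m[ids] <- pmax(mult_m[ids], blocks$multiplier[i])
      }
    }
  }
  structure(list(k = k, mult_eutherian = mult_e, mult_metatherian = mult_m,
                 planted_eutherian = names(mult_e)[mult_e > 1],
                 planted_metatherian = names(mult_m)[mult_m > 1],
                 order_a = orders$order_a, order_b = orders$order_b),
            class = "synthetic_truth")
}

pair_multiplier <- function(truth, species, pair) {
  lin_a <- species$lineage[match(pair["species_a"], species$species_id)]
  lin_b <- species$lineage[match(pair["species_b"], species$species_id)]
  if (lin_a == "Eutheria" && lin_b == "Eutheria") return(truth$mult_eutherian)
  if (lin_a == "Metatheria" && lin_b == "Metatheria") return(truth$mult_metatherian)
  # each lineage's regional effect acts on its own branch of the path
  (truth$mult_eutherian + truth$mult_metatherian) / 2
}

expected_pd <- function(truth, species, pairs, config) {
  genes <- names(truth$k)
  vapply(seq_len(nrow(pairs)), function(p) {
    mult <- pair_multiplier(truth, species,
                            c(species_a = pairs$species_a[p],
                              species_b = pairs$species_b[p]))
    pmin(truth$k * mult * pairs$t[p], config$cap_pd)
  }, numeric(length(genes)))
}

#' Expected included PDav% per pair under the generative law
#'
#' Deterministic given the drawn rates: expected divergence per (gene, pair)
#' is min(k * mult * t, cap); genes whose expected divergence exceeds
#' 100 - identity_floor are treated as excluded, mirroring the mask.
#'
#' @param truth a [simulate_rates()] result.
#' @param pairs a pair table.
#' @param config the [sim_config()] used.
#' @return numeric vector of expected PDav% per pair.
#' @export
implied_average_divergence <- function(truth, pairs, config) {
  d <- expected_pd(truth, config$species, pairs, config)
  d[d > 100 - config$identity_floor] <- NA
  colMeans(d, na.rm = TRUE)
}

#' Implied genome-wide clock constant of a synthetic cohort
#'
#' The through-origin slope of the expected included PDav% on divergence
#' time: the quantity the clock regression estimates under the generator's
#' own law, accounting for the cap, the identity floor and the acceleration
#' multipliers.
#'
#' @inheritParams implied_average_divergence
#' @return implied kav in %/My.
#' @export
implied_k_av <- function(truth, pairs, config) {
  pd_av <- implied_average_divergence(truth, pairs, config)
  sum(pairs$t * pd_av) / sum(pairs$t^2)
}

#' Simulate the divergence matrix under the linear clock law
#'
#' Expected divergence d = min(k * mult * t, cap); realized PD% is
#' 100 * Binomial(n_sites, d/100) / n_sites, which supplies realistic
#' per-gene dispersion. Realized PD above 100 - identity_floor is masked,
#' mirroring the alignment identity filter.
#'
#' @param truth a [simulate_rates()] result.
#' @param pairs a pair table for the configured species.
#' @param config the [sim_config()].
#' @param seed RNG seed.
#' @return a [divergence_matrix()].
#' @export
simulate_divergences <- function(truth, pairs, config, seed = 1L) {
  d <- expected_pd(truth, config$species, pairs, config)
  n <- nrow(d)
  PD <- with_seed(seed, {
    vapply(seq_len(ncol(d)), function(p) {
      100 * stats::rbinom(n, config$n_sites, d[, p] / 100) / config$n_sites
    }, numeric(n))
  })
  PD[PD > 100 - config$identity_floor] <- NA_real_
  rownames(PD) <- names(truth$k)
  colnames(PD) <- pairs$pair_id
  divergence_matrix(PD, pairs)
}

smooth_track <- function(n, half_width) {
  z <- window_mean(stats::rnorm(n), half_width)
  as.numeric(scale(z))
}

#' Simulate correlated GC% and GARP% tracks per species
#'
#' Each lineage carries a smooth regional GC profile on its own reference
#' order (order A for Eutheria, order B for Metatheria) with elevated GC at
#' that order's subtelomeres; species add a small smooth deviation plus
#' gene-level noise. GARP is coupled to the species' regional GC profile with
#' coefficient `rho`, so windowed within-species GC-GARP correlations land
#' near `rho` while inter-lineage landscapes differ.
#'
#' @param config a [sim_config()].
#' @param orders result of [simulate_genome_orders()].
#' @param seed RNG seed.
#' @return list with matrices `gc` and `garp` (genes x species, rownames =
#'   gene ids sorted as in [simulate_rates()]).
#' @export
simulate_gc_garp <- function(config, orders, seed = 1L) {
  g <- config$gc_garp
  species <- config$species
  n <- config$n_genes
  genes <- sort(orders$order_a$gene_id)
  gc <- matrix(NA_real_, n, nrow(species),
               dimnames = list(genes, species$species_id))
  garp <- gc
  with_seed(seed, {
    for (lin in c("Eutheria", "Metatheria")) {
      ord <- if (lin == "Eutheria") orders$order_a else orders$order_b
      boost <- rep(0, n)
      if (g$gc_subtel_boost != 0) {
        boost[subtelomere_labels(ord, g$boost_margin)] <- g$gc_subtel_boost
      }
      lineage_profile <- g$gc_regional_sd *
        smooth_track(n, g$smoothing_half_width) + boost
      for (sp in species$species_id[species$lineage == lin]) {
        profile <- lineage_profile +
          g$species_regional_sd * smooth_track(n, g$smoothing_half_width)
        z <- if (stats::sd(profile) > 0) as.numeric(scale(profile)) else profile
        z2 <- smooth_track(n, g$smoothing_half_width)
        garp_z <- g$rho * z + sqrt(1 - g$rho^2) * z2
        gc_rank <- g$gc_mean + profile + stats::rnorm(n, 0, g$gc_noise_sd)
        garp_rank <- g$garp_mean + g$garp_regional_sd * garp_z +
          stats::rnorm(n, 0, g$garp_noise_sd)
        idx <- match(ord$gene_id, genes)
        gc[idx, sp] <- gc_rank
        garp[idx, sp] <- garp_rank
      }
    }
  })
  list(gc = gc, garp = garp)
}

#' Dated species tree of the study design
#'
#' Multifurcating ultrametric tree: each clade is a star at its within-clade
#' depth; Euarchontoglires and Laurasiatheria join, then Afrotheria, then
#' Metatheria at the root.
#'
#' @param species a [species_table()].
#' @param times see [default_divergence_times()].
#' @return an `ape::phylo` with branch lengths in My.
#' @export
species_tree <- function(species = mammal_species_table(),
                         times = default_divergence_times()) {
  star <- function(clade, depth) {
    tips <- species$species_id[species$clade == clade]
    sprintf("(%s)", paste(sprintf("%s:%g", tips, depth), collapse = ","))
  }
  wc <- times$within_clade
  newick <- sprintf("((%s:%g,(%s:%g,%s:%g):%g):%g,%s:%g);",
                    star("Afrotheria", wc), times$afrotheria_split - wc,
                    star("Euarchontoglires", wc), times$boreoeutheria - wc,
                    star("Laurasiatheria", wc), times$boreoeutheria - wc,
                    times$afrotheria_split - times$boreoeutheria,
                    times$eutheria_metatheria - times$afrotheria_split,
                    star("Metatheria", times$within_metatheria),
                    times$eutheria_metatheria - times$within_metatheria)
  ape::read.tree(text = newick)
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

mutate_seq <- function(chars, n_sub) {
  if (n_sub == 0) return(chars)
  for (i in seq_len(n_sub)) {
    site <- sample.int(length(chars), 1)
    chars[site] <- sample(setdiff(AA20, chars[site]), 1)
  }
  chars
}

#' Simulate protein sequences along the dated species tree
#'
#' Root sequences are uniform over the 20 residues; substitutions are placed
#' on each branch as a Poisson process at the gene's effective per-lineage
#' rate (k/200 per site per My, so that the expected differing fraction
#' between two species is k * t / 100) with uniform replacement. Repeat hits
#' are allowed, so realized divergence saturates slightly below k * t at
#' large separations. The slow path: intended for small gene sets
#' exercising the aligner end to end.
#'
#' @param truth a [simulate_rates()] result.
#' @param config the [sim_config()].
#' @param n_genes number of genes to simulate (first genes of the truth set;
#'   <= 200 recommended).
#' @param length protein length in residues (>= 100 recommended).
#' @param seed RNG seed.
#' @return an [ortholog_set()].
#' @export
simulate_sequences <- function(truth, config, n_genes = 100, length = 450,
                               seed = 1L) {
  species <- config$species
  tree <- species_tree(species, config$times)
  tree <- ape::reorder.phylo(tree, "cladewise")
  n_tip <- length(tree$tip.label)
  # lineage of each node = lineage of its descendant tips
  tip_lineage <- species$lineage[match(tree$tip.label, species$species_id)]
  node_lineage <- character(n_tip + tree$Nnode)
  node_lineage[seq_len(n_tip)] <- tip_lineage
  for (e in rev(seq_len(nrow(tree$edge)))) {
    node_lineage[tree$edge[e, 1]] <- node_lineage[tree$edge[e, 2]]
  }
  genes <- names(truth$k)[seq_len(n_genes)]
  with_seed(seed, {
    per_species <- lapply(species$species_id, function(sp) character(0))
    names(per_species) <- species$species_id
    for (gene in genes) {
      k <- truth$k[[gene]]
      seqs <- vector("list", n_tip + tree$Nnode)
      root <- n_tip + 1L
      seqs[[root]] <- sample(AA20, length, replace = TRUE)
      for (e in seq_len(nrow(tree$edge))) {
        parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
        lin <- node_lineage[child]
        mult <- if (lin == "Metatheria") truth$mult_metatherian[[gene]]
                else truth$mult_eutherian[[gene]]
        # k is % per My of separation; separation accrues on two branches,
        # so the per-branch rate is (k/100)/2 substitutions per site per My
        rate <- k * mult / 100 / 2
        n_sub <- stats::rpois(1, rate * tree$edge.length[e] * length)
        seqs[[child]] <- mutate_seq(seqs[[parent]], n_sub)
      }
      for (i in seq_len(n_tip)) {
        per_species[[tree$tip.label[i]]][gene] <- paste(seqs[[i]], collapse = "")
      }
    }
    ortholog_set(per_species, species)
  })
}

#' Derive a rearranged genome order
#'
#' `"subtelomere-preserving"`: every chromosome is split at its midpoint into
#' two arms and the arms are randomly re-paired into new chromosomes with
#' their telomeric ends kept outward — gene neighborhoods at chromosome ends
#' stay at chromosome ends, emulating karyotype change that conserves
#' subtelomeres. `"reshuffled"`: genes are placed uniformly at random over
#' the same chromosome partition. `"identity"`: a copy of the input order.
#'
#' @param order_a a [genome_order()].
#' @param mode rearrangement mode.
#' @param seed RNG seed.
#' @return a [genome_order()] over the same genes.
#' @export
make_order_b <- function(order_a,
                         mode = c("subtelomere-preserving", "reshuffled",
                                  "identity"),
                         seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "identity") return(order_a)
  if (mode == "reshuffled") {
    perm <- with_seed(seed, sample.int(nrow(order_a)))
    return(genome_order(order_a$gene_id[perm], order_a$chromosome))
  }
  iv <- chromosome_intervals(order_a)
  arms <- list()
  for (i in seq_len(nrow(iv))) {
    mid <- iv$from[i] + (iv$to[i] - iv$from[i]) %/% 2L
    arms[[length(arms) + 1]] <- list(genes = order_a$gene_id[iv$from[i]:mid],
                                     telomere = "first")
    arms[[length(arms) + 1]] <- list(genes = order_a$gene_id[(mid + 1L):iv$to[i]],
                                     telomere = "last")
  }
  arms <- with_seed(seed, sample(arms))
  gene_id <- character(0); chromosome <- character(0)
  for (i in seq_len(length(arms) %/% 2)) {
    left <- arms[[2 * i - 1]]; right <- arms[[2 * i]]
    lg <- if (left$telomere == "first") left$genes else rev(left$genes)
    rg <- if (right$telomere == "last") right$genes else rev(right$genes)
    gene_id <- c(gene_id, lg, rg)
    chromosome <- c(chromosome, rep(sprintf("chrB%d", i), length(lg) + length(rg)))
  }
  genome_order(gene_id, chromosome)
}

#' Simulate a complete synthetic study
#'
#' One call producing everything the pipeline reads: species and pair tables,
#' the two genome orders, the planted truth, the divergence matrix and the
#' GC/GARP tracks. Fully reproducible from (config, seed).
#'
#' @param config a [sim_config()].
#' @param seed master RNG seed; stage seeds are derived from it.
#' @return list with `config`, `species`, `pairs`, `order_a`, `order_b`,
#'   `truth`, `divergence`, `gc`, `garp`.
#' @export
simulate_study <- function(config = sim_config(), seed = 1L) {
  seed <- as.integer(seed)
  orders <- simulate_genome_orders(config, seed = seed + tag_offset("orders"))
  truth <- simulate_rates(config, orders, seed = seed + tag_offset("rates"))
  pairs <- make_pair_table(config$species, config$times)
  dm <- simulate_divergences(truth, pairs, config,
                             seed = seed + tag_offset("divergence"))
  tracks <- simulate_gc_garp(config, orders, seed = seed + tag_offset("gc"))
  list(config = config, species = config$species, pairs = pairs,
       order_a = orders$order_a, order_b = orders$order_b, truth = truth,
       divergence = dm, gc = tracks$gc, garp = tracks$garp)
}
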