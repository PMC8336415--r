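#' Randomized-gene-order null distribution of window values
#'
#' Distributes the per-gene values in a random order over the same
#' chromosome partition, recomputes the sliding-window landscape, and pools
#' the window values across replicates. The acceleration threshold is
#' pooled mean + m * pooled SD. The SD is computed over the pooled window
#' values of all replicates (a per-replicate mean-of-SDs mode is available).
#'
#' @param values per-gene metric aligned to `order` (typically the per-gene
#'   clade-mean nPD, [npd_gene_means()]); missing values allowed.
#' @param order a [genome_order()] supplying the chromosome partition.
#' @param half_width,edge_policy window parameters, see [sliding_window()].
#' @param n_reps number of random genome orders (default 3).
#' @param sd_multiplier the m in threshold = mean + m * SD (default 3).
#' @param pooling `"pooled"` (default) or `"per-rep"` (mean of per-replicate
#'   SDs).
#' @param seed RNG seed; the same seed reproduces the null exactly.
#' @return a `null_distribution`: list with `n_reps`, `window_values`
#'   (list per rep), `mean`, `sd`, `sd_multiplier`, `threshold`.
#' @export
random_order_null <- function(values, order, half_width = 50,
                              edge_policy = "concatenated",
                              n_reps = 3, sd_multiplier = 3,
                              pooling = c("pooled", "per-rep"),
                              seed = NULL) {
  pooling <- match.arg(pooling)
  if (n_reps < 1) abort("n_reps must be >= 1")
  if (!is.null(names(values))) values <- values[order$gene_id]
  n <- nrow(order)
  if (length(values) != n) abort("values length != genome order size")
  if (n < 2 * half_width + 1) abort("genome order smaller than one window")
  # canonicalize so the null depends only on the value multiset, the
  # partition and the seed -- never on how genes happened to be labeled
  values <- sort(unname(values), na.last = TRUE)
  reps <- with_seed(seed, lapply(seq_len(n_reps), function(i) {
    sliding_window(values[sample.int(n)], order, half_width = half_width,
                   edge_policy = edge_policy)$values
  }))
  pooled <- unlist(reps)
  pooled <- pooled[!is.na(pooled)]
  mu <- mean(pooled)
  sdv <- if (pooling == "pooled") {
    stats::sd(pooled)
  } else {
    mean(vapply(reps, function(r) stats::sd(r[!is.na(r)]), numeric(1)))
  }
  structure(list(n_reps = as.integer(n_reps), window_values = reps,
                 mean = mu, sd = sdv, sd_multiplier = sd_multiplier,
                 threshold = mu + sd_multiplier * sdv),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("null_distribution: %d rep(s), mean %.4g, sd %.4g, threshold %.4g\n",
              x$n_reps, x$mean, x$sd, x$threshold))
  invisible(x)
}

#' Write a null-distribution summary as JSON
#'
#' @param null a [random_order_null()] result.
#' @param path output path.
#' @export
write_null_summary <- function(null, path) {
  jsonlite::write_json(list(n_reps = null$n_reps, mean = null$mean,
                            sd = null$sd, sd_multiplier = null$sd_multiplier,
                            threshold = null$threshold),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Genes whose windowed value exceeds the acceleration threshold
#'
#' A window (equivalently, the gene centering it) is accelerated when its
#' value is strictly greater than the null threshold. Missing windows never
#' exceed.
#'
#' @param landscape a windowed [landscape()].
#' @param null a [random_order_null()] on the same order/partition.
#' @return an `acceleration_result`: list with `ranks`, `genes`, `n`,
#'   `threshold`, `n_windows` (non-missing windows tested).
#' @export
exceedance_set <- function(landscape, null) {
  stopifnot(inherits(landscape, "landscape"), inherits(null, "null_distribution"))
  v <- landscape$values
  ranks <- which(!is.na(v) & v > null$threshold)
  structure(list(ranks = ranks, genes = landscape$order$gene_id[ranks],
                 n = length(ranks), threshold = null$threshold,
                 n_windows = sum(!is.na(v))),
            class = "acceleration_result")
}

#' @export
print.acceleration_result <- function(x, ...) {
  cat(sprintf("acceleration_result: %d / %d window(s) above threshold %.4g\n",
              x$n, x$n_windows, x$threshold))
  invisible(x)
}

#' Overlap of two gene sets (Venn counts)
#'
#' @param set_a,set_b character vectors of gene ids (duplicates ignored).
#' @return named integer vector `c(a_only, b_only, both)`.
#' @examples
#' venn_overlap(c("g1", "g2", "g3"), c("g2", "g3", "g4"))
#' @export
venn_overlap <- function(set_a, set_b) {
  a <- unique(set_a); b <- unique(set_b)
  both <- length(intersect(a, b))
  c(a_only = length(a) - both, b_only = length(b) - both, both = both)
}

#' Subtelomeric enrichment of an acceleration result
#'
#' observed = fraction of exceeding windows that are subtelomeric; expected =
#' fraction of all windows that are subtelomeric; fold = observed / expected.
#'
#' @param result an [exceedance_set()] result (or an integer vector of ranks).
#' @param labels subtelomeric ranks from [subtelomere_labels()].
#' @param n_total total number of windows (genome order size).
#' @return list with `observed`, `expected`, `fold` (fractions in \[0, 1\]),
#'   `n_exceeding`, `n_subtelomeric_exceeding`, `n_subtelomeric`. With an
#'   empty exceedance set the fractions are `NA` and `empty` is TRUE.
#' @export
subtelomere_enrichment <- function(result, labels, n_total) {
  ranks <- if (inherits(result, "acceleration_result")) result$ranks else result
  n_sub <- length(labels)
  expected <- n_sub / n_total
  if (length(ranks) == 0) {
    return(list(observed = NA_real_, expected = expected, fold = NA_real_,
                n_exceeding = 0L, n_subtelomeric_exceeding = 0L,
                n_subtelomeric = n_sub, empty = TRUE))
  }
  n_hit <- length(intersect(ranks, labels))
  observed <- n_hit / length(ranks)
  list(observed = observed, expected = expected, fold = observed / expected,
       n_exceeding = length(ranks), n_subtelomeric_exceeding = n_hit,
       n_subtelomeric = n_sub, empty = FALSE)
}

#' Write an exceedance gene list as a one-column TSV
#'
#' @param result an [exceedance_set()] result.
#' @param path output path.
#' @export
write_gene_list <- function(result, path) {
  write_tsv(data.frame(gene_id = result$genes, stringsAsFactors = FALSE), path)
}
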