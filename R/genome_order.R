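#' Genome order: genes ranked along a reference genome
#'
#' A `genome_order` is a ranked gene list partitioned into chromosomes. It is
#' the coordinate system of every landscape: rank `L_k` of a gene is its
#' 1-based position in the concatenated chromosome sequence. Chromosome
#' display order is the order of first appearance in the input (never
#' lexicographic), so "chr2 < chr10" issues cannot arise. Strand plays no
#' role in ranking.
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param chromosome chromosome name per gene.
#' @param start optional 1-based start coordinate per gene. When given, genes
#'   are ranked by (chromosome first-appearance order, start ascending), with
#'   ties broken by `gene_id` lexicographically; when absent the input order
#'   within each chromosome is taken as the rank order.
#' @return a `genome_order`: a data.frame with columns `gene_id`,
#'   `chromosome`, `rank` (1..N), ordered by rank.
#' @examples
#' genome_order(c("g2", "g1", "g3"), c("chr1", "chr1", "chr2"),
#'              start = c(100, 50, 10))
#' @export
genome_order <- function(gene_id, chromosome, start = NULL) {
  gene_id <- as.character(gene_id)
  chromosome <- as.character(chromosome)
  if (length(gene_id) == 0) abort("genome order must contain at least one gene")
  if (length(chromosome) != length(gene_id)) {
    abort("gene_id and chromosome lengths differ")
  }
  dup <- unique(gene_id[duplicated(gene_id)])
  if (length(dup) > 0) {
    abort("duplicate gene_id in gene order: %s",
          paste(utils::head(dup, 5), collapse = ", "))
  }
  chrom_levels <- unique(chromosome)
  chrom_idx <- match(chromosome, chrom_levels)
  if (is.null(start)) {
    ord <- order(chrom_idx)            # stable: keeps input order within chrom
  } else {
    if (length(start) != length(gene_id)) abort("start length differs from gene_id")
    ord <- order(chrom_idx, start, gene_id)
  }
  out <- data.frame(gene_id = gene_id[ord],
                    chromosome = chromosome[ord],
                    rank = seq_along(gene_id),
                    stringsAsFactors = FALSE)
  structure(out, chrom_levels = chrom_levels,
            class = c("genome_order", "data.frame"))
}

#' @export
print.genome_order <- function(x, ...) {
  iv <- chromosome_intervals(x)
  cat(sprintf("genome_order: %d genes on %d chromosome(s)\n", nrow(x), nrow(iv)))
  cat(sprintf("  %s\n", paste(sprintf("%s[%d]", iv$chromosome, iv$to - iv$from + 1L),
                              collapse = " ")))
  invisible(x)
}

#' Contiguous rank interval of each chromosome
#'
#' @param order a [genome_order()].
#' @return data.frame with columns `chromosome`, `from`, `to` (rank interval,
#'   inclusive), in display order.
#' @export
chromosome_intervals <- function(order) {
  stopifnot(inherits(order, "genome_order"))
  lv <- attr(order, "chrom_levels") %||% unique(order$chromosome)
  idx <- split(order$rank, factor(order$chromosome, levels = lv))
  data.frame(chromosome = lv,
             from = vapply(idx, min, integer(1)),
             to = vapply(idx, max, integer(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Read a gene-order table
#'
#' Expects a TSV with columns `gene_id`, `chromosome` and either `start`
#' (1-based, GenBank convention) or `rank`. Genes are ranked by (chromosome
#' order of first appearance, start ascending, gene_id).
#'
#' @param path path to a TSV file.
#' @return a [genome_order()].
#' @export
read_gene_order <- function(path) {
  df <- read_tsv_strict(path, required = c("gene_id", "chromosome"))
  if ("start" %in% names(df)) {
    genome_order(df$gene_id, df$chromosome, start = as.numeric(df$start))
  } else if ("rank" %in% names(df)) {
    df <- df[order(as.integer(df$rank)), , drop = FALSE]
    genome_order(df$gene_id, df$chromosome)
  } else {
    abort("%s: need a 'start' or 'rank' column", path)
  }
}

#' Write a gene-order table
#'
#' Writes `gene_id`, `chromosome`, `rank`; round-trips losslessly through
#' [read_gene_order()].
#'
#' @param order a [genome_order()].
#' @param path output TSV path.
#' @export
write_gene_order <- function(order, path) {
  stopifnot(inherits(order, "genome_order"))
  write_tsv(as.data.frame(order)[, c("gene_id", "chromosome", "rank")], path)
}

#' Subtelomeric ranks of a genome order
#'
#' Labels the first `margin` and last `margin` ranks of every chromosome as
#' subtelomeric; chromosomes with at most `2 * margin` genes are entirely
#' subtelomeric.
#'
#' @param order a [genome_order()].
#' @param margin number of genes labeled at each chromosome end (default 50).
#' @return sorted integer vector of subtelomeric ranks.
#' @export
subtelomere_labels <- function(order, margin = 50) {
  stopifnot(inherits(order, "genome_order"))
  if (!is.numeric(margin) || margin < 1) abort("margin must be >= 1")
  margin <- as.integer(margin)
  iv <- chromosome_intervals(order)
  ranks <- lapply(seq_len(nrow(iv)), function(i) {
    from <- iv$from[i]; to <- iv$to[i]
    n <- to - from + 1L
    if (n <= 2L * margin) return(from:to)
    c(from:(from + margin - 1L), (to - margin + 1L):to)
  })
  sort(unique(unlist(ranks)))
}
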