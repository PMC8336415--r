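#' Map a gene set between two genome orders with subtelomere flags
#'
#' For every gene present in both orders, records its chromosome and rank in
#' each order and whether it is subtelomeric there (same margin in both).
#' Links are colored green when the gene sits at a chromosome end in both
#' orders, black otherwise (subtelomeric in only one order, or in neither).
#'
#' @param genes character vector of gene ids (e.g. an exceedance set).
#' @param order_a,order_b [genome_order()] objects.
#' @param margin subtelomere margin in genes (default 50).
#' @return a `gene_links` data.frame: `gene_id`, `chrom_a`, `rank_a`,
#'   `chrom_b`, `rank_b`, `subtel_a`, `subtel_b`, `color`.
#' @export
map_genes_between_orders <- function(genes, order_a, order_b, margin = 50) {
  stopifnot(inherits(order_a, "genome_order"), inherits(order_b, "genome_order"))
  genes <- unique(genes)
  shared <- genes[genes %in% order_a$gene_id & genes %in% order_b$gene_id]
  dropped <- length(genes) - length(shared)
  if (length(shared) == 0) abort("no input gene is present in both orders")
  if (dropped > 0) {
    log_msg("map_genes_between_orders: dropped %d gene(s) absent from an order",
            dropped)
  }
  ia <- match(shared, order_a$gene_id)
  ib <- match(shared, order_b$gene_id)
  sub_a <- order_a$rank[ia] %in% subtelomere_labels(order_a, margin)
  sub_b <- order_b$rank[ib] %in% subtelomere_labels(order_b, margin)
  out <- data.frame(gene_id = shared,
                    chrom_a = order_a$chromosome[ia], rank_a = order_a$rank[ia],
                    chrom_b = order_b$chromosome[ib], rank_b = order_b$rank[ib],
                    subtel_a = sub_a, subtel_b = sub_b,
                    color = ifelse(sub_a & sub_b, "green", "black"),
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_links", "data.frame")
  out
}

#' Summarize subtelomere concordance of gene links
#'
#' @param links a [map_genes_between_orders()] result with at least one link.
#' @return list with `n_green`, `n_black`, `green_fraction`.
#' @export
concordance_summary <- function(links) {
  if (nrow(links) == 0) abort("need at least one link")
  n_green <- sum(links$color == "green")
  list(n_green = n_green, n_black = nrow(links) - n_green,
       green_fraction = n_green / nrow(links))
}

# Within-chromosome position of each link end, used as the Circos coordinate
# when no physical coordinates are available.
chrom_position <- function(order, rank) {
  iv <- chromosome_intervals(order)
  from <- iv$from[match(order$chromosome[rank], iv$chromosome)]
  rank - from + 1L
}

#' Export gene links as a Circos-style link file
#'
#' Tab-separated records `chrom_a start_a end_a chrom_b start_b end_b options`
#' with `options` of the form `color=green,gene=<id>`, consumable by standard
#' Circos link plotting. Coordinates are within-chromosome gene indices
#' (start = index, end = index + 1).
#'
#' @param links a [map_genes_between_orders()] result.
#' @param order_a,order_b the orders the links were mapped on.
#' @param path output path.
#' @return the path, invisibly.
#' @export
export_links <- function(links, order_a, order_b, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# chrom_a\tstart_a\tend_a\tchrom_b\tstart_b\tend_b\toptions", con)
  if (nrow(links) > 0) {
    pos_a <- chrom_position(order_a, links$rank_a)
    pos_b <- chrom_position(order_b, links$rank_b)
    writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%d\tcolor=%s,gene=%s",
                       links$chrom_a, pos_a, pos_a + 1L,
                       links$chrom_b, pos_b, pos_b + 1L,
                       links$color, links$gene_id), con)
  }
  invisible(path)
}

#' Read a Circos-style link file written by [export_links()]
#'
#' @param path link file path.
#' @return data.frame with `gene_id`, `chrom_a`, `start_a`, `end_a`,
#'   `chrom_b`, `start_b`, `end_b`, `color`.
#' @export
read_links <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    return(data.frame(gene_id = character(), chrom_a = character(),
                      start_a = integer(), end_a = integer(),
                      chrom_b = character(), start_b = integer(),
                      end_b = integer(), color = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- do.call(rbind, strsplit(lines, "\t"))
  opts <- strsplit(parts[, 7], ",")
  getopt <- function(o, key) sub(paste0("^", key, "="), "",
                                 o[grepl(paste0("^", key, "="), o)][1])
  data.frame(gene_id = vapply(opts, getopt, character(1), key = "gene"),
             chrom_a = parts[, 1], start_a = as.integer(parts[, 2]),
             end_a = as.integer(parts[, 3]), chrom_b = parts[, 4],
             start_b = as.integer(parts[, 5]), end_b = as.integer(parts[, 6]),
             color = vapply(opts, getopt, character(1), key = "color"),
             stringsAsFactors = FALSE)
}
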