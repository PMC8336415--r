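#' GC content of nucleotide sequences
#'
#' 100 * (G + C) / (A + C + G + T); ambiguous IUPAC bases are excluded from
#' both numerator and denominator. Case-insensitive.
#'
#' @param seq character vector of nucleotide sequences.
#' @return GC% per sequence; `NA` where a sequence has no unambiguous base.
#' @examples
#' gc_percent(c("GGCC", "ATAT", "ATGCN"))
#' @export
gc_percent <- function(seq) {
  vapply(toupper(seq), function(s) {
    n <- nchar(s)
    if (is.na(s) || n == 0) return(NA_real_)
    counts <- table(factor(strsplit(s, "")[[1]], levels = c("A", "C", "G", "T")))
    denom <- sum(counts)
    if (denom == 0) return(NA_real_)
    100 * (counts[["G"]] + counts[["C"]]) / denom
  }, numeric(1), USE.NAMES = FALSE)
}

#' GARP content of protein sequences
#'
#' Relative occurrence of glycine, alanine, arginine and proline:
#' 100 * count(G, A, R, P) / count(standard residues). X, stop and gap
#' symbols are excluded from the denominator.
#'
#' @param seq character vector of protein sequences.
#' @return GARP% per sequence; `NA` where a sequence has no standard residue.
#' @examples
#' garp_percent(c("GARP", "GGKK", "KKKK"))
#' @export
garp_percent <- function(seq) {
  standard <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  vapply(toupper(seq), function(s) {
    if (is.na(s) || nchar(s) == 0) return(NA_real_)
    chars <- strsplit(s, "")[[1]]
    denom <- sum(chars %in% standard)
    if (denom == 0) return(NA_real_)
    100 * sum(chars %in% c("G", "A", "R", "P")) / denom
  }, numeric(1), USE.NAMES = FALSE)
}

# Running mean of a window of half-width h truncated at the ends of one
# contiguous segment; NA values are dropped from each window's mean.
window_mean <- function(v, h) {
  n <- length(v)
  s <- cumsum(ifelse(is.na(v), 0, v))
  cnt <- cumsum(!is.na(v))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  sums <- s[hi] - c(0, s)[lo]
  counts <- cnt[hi] - c(0, cnt)[lo]
  out <- sums / counts
  out[counts == 0] <- NA_real_
  out
}

#' Landscape: a windowed per-gene metric aligned to a genome order
#'
#' @param values numeric vector, one value per rank of `order`.
#' @param order the [genome_order()] the values are aligned to.
#' @param metric_name short metric label (e.g. "GC%", "nPD").
#' @param window_half_width half-width used to compute the values (0 for an
#'   unwindowed per-gene track).
#' @return a `landscape`: list with `values`, `order`, `metric_name`,
#'   `window_half_width`.
#' @export
landscape <- function(values, order, metric_name = "metric",
                      window_half_width = 0L) {
  stopifnot(inherits(order, "genome_order"))
  if (length(values) != nrow(order)) {
    abort("values length (%d) != genome order size (%d)",
          length(values), nrow(order))
  }
  structure(list(values = as.numeric(values), order = order,
                 metric_name = metric_name,
                 window_half_width = as.integer(window_half_width)),
            class = "landscape")
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf("landscape '%s': %d ranks, half-width %d, %.1f%% missing\n",
              x$metric_name, length(x$values), x$window_half_width,
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' Sliding-window average along a genome order
#'
#' The windowed value at rank k is the mean of the non-missing per-gene
#' values at ranks k-h .. k+h (h = `half_width`, default 50, i.e. the
#' centered gene and its 100 neighbors). Under the default `"concatenated"`
#' edge policy windows run over the whole ranked gene list across chromosome
#' joins and are truncated only at the two genome ends; under
#' `"per-chromosome-truncated"` they are truncated at every chromosome
#' boundary. Missing values are dropped from the mean; a window is missing
#' only when all its contributors are.
#'
#' @param values per-gene metric aligned to `order` ranks (named vector keyed
#'   by gene id is re-aligned to the order).
#' @param order a [genome_order()].
#' @param half_width window half-width in genes (>= 1).
#' @param edge_policy see above.
#' @param metric_name label stored in the result.
#' @return a [landscape()].
#' @export
sliding_window <- function(values, order, half_width = 50,
                           edge_policy = c("concatenated",
                                           "per-chromosome-truncated"),
                           metric_name = "metric") {
  edge_policy <- match.arg(edge_policy)
  if (half_width < 1) abort("half_width must be >= 1")
  if (!is.null(names(values))) values <- values[order$gene_id]
  if (length(values) != nrow(order)) {
    abort("values length (%d) != genome order size (%d)",
          length(values), nrow(order))
  }
  values <- as.numeric(values)
  if (edge_policy == "concatenated") {
    w <- window_mean(values, as.integer(half_width))
  } else {
    iv <- chromosome_intervals(order)
    w <- rep(NA_real_, length(values))
    for (i in seq_len(nrow(iv))) {
      idx <- iv$from[i]:iv$to[i]
      w[idx] <- window_mean(values[idx], as.integer(half_width))
    }
  }
  landscape(w, order, metric_name = metric_name,
            window_half_width = as.integer(half_width))
}

#' Pearson correlation of two landscapes
#'
#' Computed over jointly non-missing ranks; the two landscapes must share one
#' genome order.
#'
#' @param landscape_a,landscape_b [landscape()] objects on the same order.
#' @return Pearson R; `NA` when either track is degenerate (zero variance).
#' @export
correlate_landscapes <- function(landscape_a, landscape_b) {
  stopifnot(inherits(landscape_a, "landscape"), inherits(landscape_b, "landscape"))
  if (!identical(landscape_a$order$gene_id, landscape_b$order$gene_id)) {
    abort("landscapes are not on the same genome order")
  }
  ok <- !is.na(landscape_a$values) & !is.na(landscape_b$values)
  if (sum(ok) < 3) abort("need >= 3 jointly non-missing ranks")
  a <- landscape_a$values[ok]; b <- landscape_b$values[ok]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Stack landscapes sharing one order into a heatmap matrix
#'
#' @param landscapes list of [landscape()] objects on one genome order.
#' @param track_names row labels; defaults to list names or the metric names.
#' @return a `heatmap_matrix`: tracks x ranks matrix with the genome order
#'   attached as attribute `order`.
#' @export
heatmap_matrix <- function(landscapes, track_names = NULL) {
  if (length(landscapes) == 0) abort("empty track list")
  ref <- landscapes[[1]]$order
  for (l in landscapes) {
    if (!identical(l$order$gene_id, ref$gene_id)) {
      abort("all landscapes must share one genome order")
    }
  }
  m <- do.call(rbind, lapply(landscapes, function(l) l$values))
  rownames(m) <- track_names %||% names(landscapes) %||%
    vapply(landscapes, function(l) l$metric_name, character(1))
  colnames(m) <- ref$gene_id
  structure(m, order = ref, class = c("heatmap_matrix", class(m)))
}

#' Read/write landscapes and heatmap matrices as TSV
#'
#' A landscape is written as columns `gene_id`, `chromosome`, `rank`,
#' `value`; a heatmap as `gene_id`, `chromosome`, `rank` followed by one
#' column per track. Both round-trip losslessly through the matching reader;
#' chromosome boundaries are recoverable from the `chromosome` column.
#'
#' @param x a [landscape()] or [heatmap_matrix()].
#' @param path TSV path.
#' @export
write_landscape_tsv <- function(x, path) {
  if (inherits(x, "landscape")) {
    df <- data.frame(gene_id = x$order$gene_id,
                     chromosome = x$order$chromosome,
                     rank = x$order$rank, value = x$values,
                     stringsAsFactors = FALSE)
  } else if (inherits(x, "heatmap_matrix")) {
    ord <- attr(x, "order")
    df <- data.frame(gene_id = ord$gene_id, chromosome = ord$chromosome,
                     rank = ord$rank, t(unclass(x)[, , drop = FALSE]),
                     check.names = FALSE, stringsAsFactors = FALSE)
  } else {
    abort("x must be a landscape or a heatmap_matrix")
  }
  write_tsv(df, path)
}

#' @rdname write_landscape_tsv
#' @param metric_name,window_half_width metadata for the reconstructed
#'   landscape (not stored in the file).
#' @export
read_landscape_tsv <- function(path, metric_name = "metric",
                               window_half_width = 0L) {
  df <- read_tsv_strict(path, required = c("gene_id", "chromosome", "rank",
                                           "value"))
  df <- df[order(as.integer(df$rank)), , drop = FALSE]
  ord <- genome_order(df$gene_id, df$chromosome)
  landscape(as.numeric(df$value), ord, metric_name = metric_name,
            window_half_width = window_half_width)
}

#' @rdname write_landscape_tsv
#' @export
read_heatmap_tsv <- function(path) {
  df <- read_tsv_strict(path, required = c("gene_id", "chromosome", "rank"))
  df <- df[order(as.integer(df$rank)), , drop = FALSE]
  ord <- genome_order(df$gene_id, df$chromosome)
  tracks <- setdiff(names(df), c("gene_id", "chromosome", "rank"))
  if (length(tracks) == 0) abort("%s: no track columns", path)
  lds <- lapply(tracks, function(tr) landscape(as.numeric(df[[tr]]), ord, tr))
  heatmap_matrix(lds, track_names = tracks)
}
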