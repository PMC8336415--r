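#' Gene x species-pair divergence matrix
#'
#' @param PD numeric matrix of PD% values, genes in rows (rownames = gene
#'   ids), one column per pair (colnames = pair ids). `NA` marks entries that
#'   are masked: sequence absent in one species or identity below the floor.
#' @param pairs the matching pair table ([make_pair_table()]).
#' @return a `divergence_matrix`: list with `PD`, `genes`, `pairs`.
#' @export
divergence_matrix <- function(PD, pairs) {
  stopifnot(is.matrix(PD), is.data.frame(pairs))
  if (ncol(PD) != nrow(pairs)) abort("PD columns (%d) != pairs (%d)",
                                     ncol(PD), nrow(pairs))
  if (is.null(rownames(PD))) abort("PD must carry gene ids as rownames")
  rng <- range(PD, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 100) abort("PD values must lie in [0, 100]")
  colnames(PD) <- as.character(pairs$pair_id)
  structure(list(PD = PD, genes = rownames(PD), pairs = pairs),
            class = "divergence_matrix")
}

#' @export
print.divergence_matrix <- function(x, ...) {
  cat(sprintf("divergence_matrix: %d gene(s) x %d pair(s), %.1f%% masked\n",
              nrow(x$PD), ncol(x$PD), 100 * mean(is.na(x$PD))))
  invisible(x)
}

#' Compute the divergence matrix from aligned ortholog pairs
#'
#' For every (gene, pair) where both species carry the gene, computes the
#' optimal global alignment, percent identity and PD%; identities below the
#' configured floor are masked. Deterministic given its inputs. Genes with no
#' included pair are dropped with a logged count.
#'
#' @param orthologs an [ortholog_set()].
#' @param pairs a pair table covering the species with sequences.
#' @param config a [run_config()].
#' @return a [divergence_matrix()].
#' @export
build_divergence_matrix <- function(orthologs, pairs, config = run_config()) {
  genes <- orthologs$genes
  seqs <- orthologs$sequences
  PD <- matrix(NA_real_, nrow = length(genes), ncol = nrow(pairs),
               dimnames = list(genes, pairs$pair_id))
  for (p in seq_len(nrow(pairs))) {
    sa <- seqs[[pairs$species_a[p]]]
    sb <- seqs[[pairs$species_b[p]]]
    if (is.null(sa) || is.null(sb)) next
    shared <- intersect(names(sa), names(sb))
    for (g in shared) {
      al <- global_align(sa[[g]], sb[[g]],
                         gap_open = config$gap_open,
                         gap_extend = config$gap_extend)
      PD[g, p] <- pairwise_divergence(percent_identity(al),
                                      identity_floor = config$identity_floor)
    }
  }
  empty <- rowSums(!is.na(PD)) == 0
  if (any(empty)) {
    log_msg("build_divergence_matrix: dropped %d gene(s) with no included pair",
            sum(empty))
    PD <- PD[!empty, , drop = FALSE]
  }
  divergence_matrix(PD, pairs)
}

#' Read/write a divergence matrix as TSV
#'
#' Layout: a `gene_id` column followed by one column per pair id; masked
#' entries are written as `NA`. Round-trips losslessly.
#'
#' @param dm a [divergence_matrix()].
#' @param path TSV path.
#' @export
write_divergence_tsv <- function(dm, path) {
  stopifnot(inherits(dm, "divergence_matrix"))
  df <- data.frame(gene_id = dm$genes, dm$PD, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname write_divergence_tsv
#' @param pairs the pair table the matrix columns refer to.
#' @export
read_divergence_tsv <- function(path, pairs) {
  df <- read_tsv_strict(path, required = "gene_id")
  PD <- as.matrix(df[, setdiff(names(df), "gene_id"), drop = FALSE])
  mode(PD) <- "numeric"
  rownames(PD) <- df$gene_id
  missing <- setdiff(as.character(pairs$pair_id), colnames(PD))
  if (length(missing) > 0) {
    abort("%s: missing pair column(s): %s", path,
          paste(utils::head(missing, 5), collapse = ", "))
  }
  divergence_matrix(PD[, as.character(pairs$pair_id), drop = FALSE], pairs)
}
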