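#' Ortholog sequence set
#'
#' Container for one protein sequence per (gene, species), with genes allowed
#' to be missing in some species. Construction applies the core-set rule:
#' only genes present in at least one Eutherian and at least one Metatherian
#' species are retained, which excludes lineage-specific genes.
#'
#' @param sequences named list, one element per species: a named character
#'   vector of protein sequences keyed by gene id.
#' @param species a [species_table()] covering the list names.
#' @return an `ortholog_set`: list with `sequences`, `genes`, `species`.
#' @export
ortholog_set <- function(sequences, species) {
  stopifnot(is.list(sequences))
  unknown <- setdiff(names(sequences), species$species_id)
  if (length(unknown) > 0) {
    abort("sequences for species absent from the species table: %s",
          paste(unknown, collapse = ", "))
  }
  for (sp in names(sequences)) {
    ids <- names(sequences[[sp]])
    if (is.null(ids) || anyDuplicated(ids)) {
      abort("duplicate or missing gene ids for species %s", sp)
    }
  }
  lineage <- species$lineage[match(names(sequences), species$species_id)]
  eu_genes <- unique(unlist(lapply(sequences[lineage == "Eutheria"], names)))
  met_genes <- unique(unlist(lapply(sequences[lineage == "Metatheria"], names)))
  genes <- sort(intersect(eu_genes, met_genes))
  all_genes <- unique(unlist(lapply(sequences, names)))
  dropped <- length(all_genes) - length(genes)
  if (dropped > 0) {
    log_msg("ortholog_set: dropped %d lineage-specific gene(s)", dropped)
  }
  sequences <- lapply(sequences, function(x) x[names(x) %in% genes])
  structure(list(sequences = sequences, genes = genes, species = species),
            class = "ortholog_set")
}

#' @export
print.ortholog_set <- function(x, ...) {
  cat(sprintf("ortholog_set: %d gene(s) x %d species\n",
              length(x$genes), length(x$sequences)))
  invisible(x)
}

#' Read per-species ortholog FASTA files
#'
#' Reads one protein FASTA per species from a directory; files are matched to
#' species by base name (`<species_id>.fa|.fasta|.faa`). Record ids (first
#' whitespace-separated token) are the gene identifiers. Genes present in only
#' one lineage are dropped by the `ortholog_set` core-set rule.
#'
#' @param directory directory holding the FASTA files.
#' @param species a [species_table()].
#' @return an [ortholog_set()].
#' @export
read_ortholog_fastas <- function(directory, species) {
  if (!dir.exists(directory)) abort("directory not found: %s", directory)
  files <- list.files(directory, pattern = "\\.(fa|fasta|faa)$",
                      full.names = TRUE)
  ids <- sub("\\.(fa|fasta|faa)$", "", basename(files))
  keep <- ids %in% species$species_id
  files <- files[keep]; ids <- ids[keep]
  if (length(files) == 0) abort("no species FASTAs found in %s", directory)
  sequences <- lapply(seq_along(files), function(i) {
    set <- tryCatch(Biostrings::readAAStringSet(files[i]),
                    error = function(e) abort("unparseable FASTA %s: %s",
                                              files[i], conditionMessage(e)))
    gene_ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
    if (anyDuplicated(gene_ids)) {
      abort("duplicate gene id '%s' in %s",
            gene_ids[duplicated(gene_ids)][1], files[i])
    }
    stats::setNames(as.character(set), gene_ids)
  })
  names(sequences) <- ids
  ortholog_set(sequences, species)
}

#' Write an ortholog set as per-species FASTA files
#'
#' @param orthologs an [ortholog_set()].
#' @param directory output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_ortholog_fastas <- function(orthologs, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  for (sp in names(orthologs$sequences)) {
    seqs <- orthologs$sequences[[sp]]
    Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs),
                                file.path(directory, paste0(sp, ".fa")))
  }
  invisible(directory)
}
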