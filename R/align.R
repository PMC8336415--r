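aa_env <- new.env(parent = emptyenv())

#' BLOSUM62 substitution matrix
#'
#' @return the 25x25 BLOSUM62 matrix shipped with Biostrings (standard
#'   residues plus B, Z, X and stop).
#' @export
blosum62 <- function() {
  if (is.null(aa_env$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    aa_env$BLOSUM62 <- e$BLOSUM62
  }
  aa_env$BLOSUM62
}

check_protein <- function(seq, arg) {
  if (!is.character(seq) || length(seq) != 1 || is.na(seq) || nchar(seq) == 0) {
    abort("%s must be a non-empty protein sequence", arg)
  }
  allowed <- setdiff(rownames(blosum62()), "*")
  chars <- unique(strsplit(seq, "")[[1]])
  bad <- setdiff(chars, allowed)
  if (length(bad) > 0) {
    abort("%s contains non-amino-acid symbol(s): %s", arg,
          paste(bad, collapse = ", "))
  }
  invisible(seq)
}

#' Optimal global protein alignment (affine gaps, BLOSUM62)
#'
#' Needleman-Wunsch global alignment with affine gap penalties, the scheme
#' used by EMBOSS Stretcher for proteins. End gaps are penalized as ordinary
#' gaps. A gap of length L costs `gap_open + L * gap_extend`. The score is
#' the tested contract; when several alignments are co-optimal, any one of
#' them may be returned.
#'
#' @param seq_a,seq_b protein sequences (single strings; X allowed and scored
#'   by the matrix's X row).
#' @param gap_open,gap_extend affine gap penalties (default 12 / 2, the
#'   Stretcher protein defaults).
#' @param substitution_matrix scoring matrix, default [blosum62()].
#' @return a `pairwise_alignment`: list with `aligned_a`, `aligned_b`
#'   (equal-length gapped strings) and `score`.
#' @examples
#' al <- global_align("HEAGAWGHEE", "PAWHEAE")
#' al$score
#' @export
global_align <- function(seq_a, seq_b, gap_open = 12, gap_extend = 2,
                         substitution_matrix = blosum62()) {
  check_protein(seq_a, "seq_a")
  check_protein(seq_b, "seq_b")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend, type = "global")
  out <- list(aligned_a = as.character(Biostrings::alignedPattern(pa)),
              aligned_b = as.character(Biostrings::alignedSubject(pa)),
              score = Biostrings::score(pa))
  class(out) <- "pairwise_alignment"
  out
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("pairwise_alignment (score %g)\n  %s\n  %s\n",
              x$score, x$aligned_a, x$aligned_b))
  invisible(x)
}

#' Percent identity of a global alignment
#'
#' identity% = 100 * matches / (alignment length - gap-containing columns),
#' i.e. identity over aligned residue-pair columns. This denominator excludes
#' low identities caused by incomplete sequence information. Columns pairing
#' X with X count as mismatch, not match.
#'
#' @param alignment a [global_align()] result, or a list with `aligned_a`
#'   and `aligned_b`.
#' @return identity in \[0, 100\]; `NA` if the alignment has no ungapped
#'   column (flagged missing, excluded downstream).
#' @export
percent_identity <- function(alignment) {
  a <- strsplit(alignment$aligned_a, "")[[1]]
  b <- strsplit(alignment$aligned_b, "")[[1]]
  if (length(a) != length(b)) abort("aligned strings have different lengths")
  gap <- a == "-" | b == "-"
  n_cols <- length(a) - sum(gap)
  if (n_cols == 0) return(NA_real_)
  matches <- sum(!gap & a == b & a != "X")
  100 * matches / n_cols
}

#' Protein divergence from percent identity
#'
#' PD% = 100 - identity%. Identities below the floor are discarded
#' (returned as `NA`): such alignments usually reflect incomplete or
#' non-orthologous sequence rather than true divergence.
#'
#' @param identity percent identity in \[0, 100\] (vectorized; `NA` passes
#'   through).
#' @param identity_floor exclusion floor, default 30.
#' @return PD% per input, `NA` where excluded.
#' @examples
#' pairwise_divergence(c(100, 72, 29.9))
#' @export
pairwise_divergence <- function(identity, identity_floor = 30) {
  if (any(identity < 0 | identity > 100, na.rm = TRUE)) {
    abort("identity must lie in [0, 100]")
  }
  out <- 100 - identity
  out[!is.na(identity) & identity < identity_floor] <- NA_real_
  out
}
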