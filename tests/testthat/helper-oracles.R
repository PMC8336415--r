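# Independent oracles used by the unit and acceptance tests. Written against
# the definitions only; they share no code with the package internals.

# Affine-gap global alignment score by dynamic programming (Gotoh).
# A gap of length L costs open + L * ext. Maximizing.
oracle_align_score <- function(a, b, open = 12, ext = 2,
                               mat = clockscape::blosum62()) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)  # last column is a residue pair
  X <- matrix(NEG, n + 1, m + 1)  # last column is a[i] over a gap
  Y <- matrix(NEG, n + 1, m + 1)  # last column is a gap over b[j]
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(open + i * ext)
  for (j in seq_len(m)) Y[1, j + 1] <- -(open + j * ext)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + mat[a[i], b[j]]
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext,
                             X[i, j + 1] - ext,
                             Y[i, j + 1] - open - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext,
                             X[i + 1, j] - open - ext,
                             Y[i + 1, j] - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Direct-loop sliding-window means over one contiguous segment.
oracle_window_segment <- function(v, h) {
  n <- length(v)
  vapply(seq_len(n), function(k) {
    w <- v[max(1, k - h):min(n, k + h)]
    if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }, numeric(1))
}

# Direct-loop windows honoring an edge policy over chromosome intervals.
oracle_window <- function(v, h, intervals = NULL) {
  if (is.null(intervals)) return(oracle_window_segment(v, h))
  out <- rep(NA_real_, length(v))
  for (i in seq_len(nrow(intervals))) {
    idx <- intervals$from[i]:intervals$to[i]
    out[idx] <- oracle_window_segment(v[idx], h)
  }
  out
}

random_protein <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len, replace = TRUE),
        collapse = "")
}

# Two-lineage four-species design used by small fixtures.
tiny_species <- function() {
  species_table(c("cow", "rat", "koala", "wombat"),
                c("Laurasiatheria", "Euarchontoglires", "Metatheria",
                  "Metatheria"))
}

# Genome order with n_chrom chromosomes of chrom_size genes each.
block_order <- function(n_chrom, chrom_size, prefix = "chr") {
  n <- n_chrom * chrom_size
  genome_order(sprintf("g%05d", seq_len(n)),
               rep(sprintf("%s%d", prefix, seq_len(n_chrom)),
                   each = chrom_size))
}

# Divergence matrix holding given PD columns (one per pair of tiny_species).
tiny_divergence <- function(PD) {
  pairs <- make_pair_table(tiny_species())
  stopifnot(ncol(PD) == nrow(pairs))
  if (is.null(rownames(PD))) {
    rownames(PD) <- sprintf("g%03d", seq_len(nrow(PD)))
  }
  divergence_matrix(PD, pairs)
}
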