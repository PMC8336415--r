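#' Genome-wide average divergence per species pair
#'
#' Arithmetic mean of the included (non-masked) PD% values of each pair.
#'
#' @param dm a [divergence_matrix()].
#' @param pair optional pair id (or vector of ids); default all pairs.
#' @return named numeric vector of PDav% per pair.
#' @export
average_divergence <- function(dm, pair = NULL) {
  stopifnot(inherits(dm, "divergence_matrix"))
  PD <- dm$PD
  if (!is.null(pair)) PD <- PD[, as.character(pair), drop = FALSE]
  n_inc <- colSums(!is.na(PD))
  if (any(n_inc == 0)) {
    abort("pair(s) with zero included genes: %s",
          paste(colnames(PD)[n_inc == 0], collapse = ", "))
  }
  colMeans(PD, na.rm = TRUE)
}

#' Molecular clock regression PDav% = kav * t
#'
#' Fits the genome-wide average clock. Under the neutral strict-clock model
#' without saturation the points lie on a line through the origin, so the
#' default is a through-origin fit: kav = sum(t * PDav) / sum(t^2). A
#' free-intercept ordinary least squares fit is available with
#' `through_origin = FALSE`. R^2 is reported as the squared Pearson
#' correlation between observed and fitted values.
#'
#' @param pd_av PDav% per pair.
#' @param t divergence time (My) per pair.
#' @param through_origin force the line through the origin (default TRUE).
#' @return a `clock_fit`: list with `k_av` (%/My), `intercept`, `R2`,
#'   `n_pairs`, `fitted`, `residuals`.
#' @examples
#' clock_regression(pd_av = 0.13 * c(60, 96, 158.5), t = c(60, 96, 158.5))
#' @export
clock_regression <- function(pd_av, t, through_origin = TRUE) {
  if (length(pd_av) != length(t)) abort("pd_av and t lengths differ")
  if (length(t) < 1) abort("need at least one pair")
  if (!through_origin && length(unique(t)) < 2) {
    abort("free-intercept fit needs >= 2 distinct divergence times")
  }
  if (through_origin) {
    k_av <- sum(t * pd_av) / sum(t^2)
    intercept <- 0
  } else {
    fit <- stats::lm(pd_av ~ t)
    k_av <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
  }
  fitted <- intercept + k_av * t
  R2 <- if (length(t) >= 2 && stats::sd(fitted) > 0 && stats::sd(pd_av) > 0) {
    stats::cor(pd_av, fitted)^2
  } else {
    NA_real_
  }
  structure(list(k_av = k_av, intercept = intercept, R2 = R2,
                 n_pairs = length(t), fitted = fitted,
                 residuals = pd_av - fitted, through_origin = through_origin),
            class = "clock_fit")
}

#' @export
print.clock_fit <- function(x, ...) {
  cat(sprintf("clock_fit: k_av = %.4g %%/My (%.3g %%/10 My), R2 = %.4f, n = %d\n",
              x$k_av, 10 * x$k_av, x$R2, x$n_pairs))
  invisible(x)
}

#' Write a clock fit as JSON
#'
#' @param fit a [clock_regression()] result.
#' @param path output path.
#' @export
write_clock_fit <- function(fit, path) {
  jsonlite::write_json(list(k_av = fit$k_av, intercept = fit$intercept,
                            R2 = fit$R2, n_pairs = fit$n_pairs),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Normalized protein divergence nPD% = PD% / PDav% = k / kav
#'
#' Divides each pair's column by that pair's genome-wide average, removing
#' the influence of divergence time: the result is the gene's clock rate
#' relative to the genome average. By construction the mean of nPD over
#' included genes is exactly 1 for every pair. Masked entries stay masked.
#'
#' @param dm a [divergence_matrix()].
#' @return a `normalized_divergence`: list with `nPD` (genes x pairs),
#'   `pd_av`, `genes`, `pairs`.
#' @export
normalize_divergence <- function(dm) {
  stopifnot(inherits(dm, "divergence_matrix"))
  pd_av <- average_divergence(dm)
  if (any(pd_av == 0)) {
    abort("degenerate pair(s) with PDav = 0: %s",
          paste(names(pd_av)[pd_av == 0], collapse = ", "))
  }
  nPD <- sweep(dm$PD, 2, pd_av, "/")
  structure(list(nPD = nPD, pd_av = pd_av, genes = dm$genes, pairs = dm$pairs),
            class = "normalized_divergence")
}

#' @export
print.normalized_divergence <- function(x, ...) {
  cat(sprintf("normalized_divergence: %d gene(s) x %d pair(s)\n",
              nrow(x$nPD), ncol(x$nPD)))
  invisible(x)
}

pairs_of_class <- function(pairs, pair_class) {
  classes <- unique(pairs$pair_class)
  if (!pair_class %in% classes) {
    abort("no pairs of class '%s' (available: %s)", pair_class,
          paste(classes, collapse = ", "))
  }
  pairs$pair_id[pairs$pair_class == pair_class]
}

#' Per-gene mean nPD across the pairs of one class
#'
#' Missing-aware mean over the included (gene, pair) entries of all pairs in
#' `pair_class` — the per-gene summary the acceleration analysis windows.
#'
#' @param nd a [normalize_divergence()] result.
#' @param pair_class one of `"intra-Eutherian"`, `"Eutherian-Metatherian"`,
#'   `"intra-Metatherian"`.
#' @return named numeric vector, one mean per gene (`NA` where a gene is
#'   masked in every pair of the class).
#' @export
npd_gene_means <- function(nd, pair_class) {
  stopifnot(inherits(nd, "normalized_divergence"))
  ids <- pairs_of_class(nd$pairs, pair_class)
  sub <- nd$nPD[, as.character(ids), drop = FALSE]
  out <- rowMeans(sub, na.rm = TRUE)
  out[rowSums(!is.na(sub)) == 0] <- NA_real_
  stats::setNames(out, nd$genes)
}

#' Clade-mean nPD landscape
#'
#' Windows each pair's nPD track on the given order, then averages the
#' windowed values across the pairs of the class at every rank
#' (missing-aware, equal weight per pair). On missing-free data this equals
#' windowing the per-gene clade means, by linearity of the window.
#'
#' @param nd a [normalize_divergence()] result.
#' @param order a [genome_order()]; genes of `nd` absent from the order are
#'   ignored, order genes without divergence data contribute missing values.
#' @param pair_class pair class to average over.
#' @param half_width,edge_policy window parameters, see [sliding_window()].
#' @return a [landscape()] named `nPD:<pair_class>`.
#' @export
clade_mean_landscape <- function(nd, order, pair_class, half_width = 50,
                                 edge_policy = "concatenated") {
  stopifnot(inherits(nd, "normalized_divergence"))
  ids <- pairs_of_class(nd$pairs, pair_class)
  idx <- match(order$gene_id, nd$genes)
  sums <- numeric(nrow(order)); counts <- numeric(nrow(order))
  for (p in as.character(ids)) {
    v <- rep(NA_real_, nrow(order))
    v[!is.na(idx)] <- nd$nPD[idx[!is.na(idx)], p]
    w <- sliding_window(v, order, half_width = half_width,
                        edge_policy = edge_policy)$values
    ok <- !is.na(w)
    sums[ok] <- sums[ok] + w[ok]
    counts[ok] <- counts[ok] + 1
  }
  vals <- sums / counts
  vals[counts == 0] <- NA_real_
  landscape(vals, order, metric_name = paste0("nPD:", pair_class),
            window_half_width = as.integer(half_width))
}
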