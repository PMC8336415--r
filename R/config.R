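#' Pipeline run configuration
#'
#' All defaults follow the study design: 101-gene windows (half-width 50),
#' a 30% identity floor below which alignments are discarded, three random
#' genome orders for the null, a mean + 3 SD acceleration threshold, and
#' 50-gene subtelomere margins. Alignment penalties are the protein defaults
#' of the EMBOSS Stretcher tool (gap open 12, extend 2, BLOSUM62).
#'
#' @param window_half_width genes on each side of the window center (>= 1).
#' @param identity_floor percent identity below which an alignment is
#'   discarded; must lie in (0, 100).
#' @param n_random_orders randomized gene orders for the null (>= 1).
#' @param threshold_sd_multiplier the m in threshold = mean + m * SD.
#' @param subtelomere_margin genes labeled subtelomeric at each chromosome end.
#' @param rng_seed integer seed for all randomized steps.
#' @param gap_open,gap_extend affine gap penalties (matrix units).
#' @param edge_policy `"concatenated"` (windows run over the whole ranked
#'   list, truncated only at the two genome ends) or
#'   `"per-chromosome-truncated"` (windows truncated at chromosome
#'   boundaries).
#' @return a `run_config` list.
#' @export
run_config <- function(window_half_width = 50,
                       identity_floor = 30,
                       n_random_orders = 3,
                       threshold_sd_multiplier = 3,
                       subtelomere_margin = 50,
                       rng_seed = 1L,
                       gap_open = 12,
                       gap_extend = 2,
                       edge_policy = c("concatenated", "per-chromosome-truncated")) {
  edge_policy <- match.arg(edge_policy)
  if (window_half_width < 1) abort("window_half_width must be >= 1")
  if (identity_floor <= 0 || identity_floor >= 100) {
    abort("identity_floor must be in (0, 100)")
  }
  if (n_random_orders < 1) abort("n_random_orders must be >= 1")
  structure(list(window_half_width = as.integer(window_half_width),
                 identity_floor = identity_floor,
                 n_random_orders = as.integer(n_random_orders),
                 threshold_sd_multiplier = threshold_sd_multiplier,
                 subtelomere_margin = as.integer(subtelomere_margin),
                 rng_seed = as.integer(rng_seed),
                 gap_open = gap_open, gap_extend = gap_extend,
                 edge_policy = edge_policy),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' The file holds a flat key set mirroring [run_config()]; keys not present
#' keep their defaults.
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort("config file not found: %s", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    abort("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  do.call(run_config, vals)
}

#' @rdname read_run_config
#' @param config a `run_config` to write.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
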