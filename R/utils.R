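`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate code with a temporary RNG seed
#'
#' Sets the seed for the duration of `code` and restores the caller's RNG
#' state afterwards, so seeded package functions do not disturb the session
#' stream. A `NULL` seed runs the code on the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

abort <- function(...) stop(sprintf(...), call. = FALSE)

#' @keywords internal
log_msg <- function(...) message(sprintf(...))

# Stable small-integer hash of a string, used to derive per-analysis seeds
# (kept < 2^31 so seed arithmetic stays in integer range).
tag_offset <- function(tag) {
  sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag))) %% 10000L
}

read_tsv_strict <- function(path, required = character()) {
  if (!file.exists(path)) abort("file not found: %s", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "#")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort("%s: missing required column(s): %s", path,
          paste(missing, collapse = ", "))
  }
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
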