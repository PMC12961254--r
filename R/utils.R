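#' @importFrom rlang %||% abort warn inform .data
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join inner_join bind_rows bind_cols distinct across n pull rename
#'   if_else count
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom purrr map map2 pmap map_dbl map_int map_chr map_lgl
#' @importFrom stats rnbinom rpois rnorm runif rgeom setNames quantile
#'   optimize pchisq phyper p.adjust cmdscale dist pt dnbinom weighted.mean
#' @importFrom utils head tail
NULL

# deterministic per-stage seed derived from a user seed; stays within 32-bit range
stage_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483587) + 1L
}

assert_cols <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("`%s` is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

#' Convert a wide count table to a numeric matrix
#'
#' Count tables in this package are tibbles with a `region_id` column and one
#' numeric column per sample. This helper extracts the numeric matrix with
#' region ids as row names, the form the statistical routines work on.
#'
#' @param counts A wide count tibble (`region_id` plus one column per sample),
#'   or a numeric matrix (returned unchanged).
#' @return A numeric matrix, regions in rows, samples in columns.
#' @export
as_count_matrix <- function(counts) {
  if (is.matrix(counts)) return(counts)
  assert_cols(counts, "region_id", "counts")
  sample_cols <- setdiff(names(counts), c("region_id", "chrom", "start", "end"))
  m <- as.matrix(counts[, sample_cols, drop = FALSE])
  rownames(m) <- counts$region_id
  storage.mode(m) <- "double"
  m
}

sample_cols_of <- function(counts) {
  setdiff(names(counts), c("region_id", "chrom", "start", "end"))
}

# library sizes: explicit vector wins, else column sums of the count table
resolve_lib_sizes <- function(counts, lib_sizes = NULL) {
  m <- as_count_matrix(counts)
  if (is.null(lib_sizes)) {
    lib_sizes <- colSums(m)
  }
  if (is.null(names(lib_sizes))) names(lib_sizes) <- colnames(m)
  ls <- lib_sizes[colnames(m)]
  if (anyNA(ls)) abort("`lib_sizes` does not cover every sample in `counts`.")
  if (any(ls <= 0)) abort("library sizes must be positive.")
  ls
}
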