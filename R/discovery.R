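#' Per-sample read counts in non-overlapping genomic windows
#'
#' Tiles each chromosome with non-overlapping windows (the last window may be
#' short) and counts, per sample, how many alignment records of the selected
#' read lengths overlap each window. A record straddling a window boundary
#' increments every window it overlaps (coverage semantics); these raw read
#' counts drive region retention only, not quantification.
#'
#' @param alignments Alignment-record tibble (`sample_id`, `chrom`, `start`,
#'   `end`, `length`, `n_hits`).
#' @param chrom_sizes Tibble with `chrom`, `length`.
#' @param window_size Window width in bp (default 100).
#' @param lengths Read lengths to include (default 20:24).
#' @return Long tibble: `chrom`, `start`, `end`, `sample_id`, `reads`
#'   (zero rows are omitted; windows absent for a sample have zero reads).
#' @export
window_read_counts <- function(alignments, chrom_sizes, window_size = 100,
                               lengths = 20:24) {
  assert_cols(alignments, c("sample_id", "chrom", "start", "end", "length"),
              "alignments")
  if (length(lengths) == 0) abort("`lengths` must be non-empty")
  sizes <- setNames(chrom_sizes$length, chrom_sizes$chrom)
  aln <- filter(alignments, .data$length %in% lengths)
  if (nrow(aln) > 0) {
    if (!all(aln$chrom %in% names(sizes))) abort("alignment on unknown chromosome")
    if (any(aln$end > sizes[aln$chrom]) || any(aln$start < 0)) {
      abort("alignment record beyond chromosome end")
    }
  }
  windows <- GenomicRanges::tileGenome(sizes, tilewidth = window_size,
                                       cut.last.tile.in.chrom = TRUE)
  win_tbl <- tibble(chrom = as.character(GenomicRanges::seqnames(windows)),
                    start = GenomicRanges::start(windows) - 1L,
                    end = GenomicRanges::end(windows))
  if (nrow(aln) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  sample_id = character(), reads = integer()))
  }
  aln |>
    group_by(.data$sample_id) |>
    dplyr::group_modify(function(d, key) {
      hits <- GenomicRanges::countOverlaps(windows, iv_granges(d))
      win_tbl |> mutate(reads = hits) |> filter(.data$reads > 0)
    }) |>
    ungroup() |>
    select("chrom", "start", "end", "sample_id", "reads")
}

#' Retain covered windows and merge adjacent ones into target regions
#'
#' A window is retained when its read count reaches `min_reads` in at least
#' one sample; maximal runs of immediately adjacent retained windows are
#' merged into single intervals.
#'
#' @param window_counts Output of [window_read_counts()].
#' @param min_reads Retention threshold on raw read counts (default 10).
#' @return Tibble of merged regions (`chrom`, `start`, `end`), sorted.
#' @export
retain_and_merge <- function(window_counts, min_reads = 10) {
  assert_cols(window_counts, c("chrom", "start", "end", "reads"),
              "window_counts")
  kept <- window_counts |>
    group_by(.data$chrom, .data$start, .data$end) |>
    summarise(max_reads = max(.data$reads), .groups = "drop") |>
    filter(.data$max_reads >= min_reads)
  if (nrow(kept) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  # min.gapwidth = 1: merge abutting windows, never across a >= 1 bp gap
  merged <- GenomicRanges::reduce(iv_granges(kept), min.gapwidth = 1L)
  tibble(chrom = as.character(GenomicRanges::seqnames(merged)),
         start = GenomicRanges::start(merged) - 1L,
         end = GenomicRanges::end(merged)) |>
    arrange(.data$chrom, .data$start)
}

#' Discover small-RNA target regions from alignments
#'
#' Convenience wrapper: window counting, retention and merging in one call.
#'
#' @inheritParams window_read_counts
#' @inheritParams retain_and_merge
#' @return Sorted region tibble with stable `region_id`s (`reg1..regN`).
#' @export
discover_regions <- function(alignments, chrom_sizes, window_size = 100,
                             min_reads = 10, lengths = 20:24) {
  wc <- window_read_counts(alignments, chrom_sizes, window_size, lengths)
  retain_and_merge(wc, min_reads) |>
    mutate(region_id = sprintf("reg%d", dplyr::row_number()), .before = 1)
}

#' Fractional counts of alignment records per target region
#'
#' Each record of a selected read length overlapping a region contributes
#' `1/n_hits` to that region's count for its sample (fractional multi-mapper
#' assignment); records overlapping no region contribute nothing. Regions
#' must be non-overlapping; in the degenerate case of a record touching two
#' adjacent regions it is assigned once, to the region with the larger
#' overlap.
#'
#' @param alignments Alignment-record tibble.
#' @param regions Region tibble (`chrom`, `start`, `end`), sorted and
#'   non-overlapping; a `region_id` column is added if absent.
#' @param samples Optional sample sheet; ensures a (zero) count column for
#'   every sample even if it has no reads.
#' @param lengths Read lengths to include.
#' @return Wide count tibble: `region_id`, `chrom`, `start`, `end`, one real
#'   column per sample.
#' @export
count_regions <- function(alignments, regions, samples = NULL, lengths = 20:24) {
  assert_cols(alignments, c("sample_id", "chrom", "start", "end", "length",
                            "n_hits"), "alignments")
  regions <- as_tibble(regions)
  assert_cols(regions, c("chrom", "start", "end"), "regions")
  regions <- arrange(regions, .data$chrom, .data$start)
  if (!"region_id" %in% names(regions)) {
    regions <- mutate(regions, region_id = sprintf("reg%d", dplyr::row_number()),
                      .before = 1)
  }
  rg <- iv_granges(regions)
  if (nrow(regions) > 1 &&
      any(GenomicRanges::countOverlaps(rg, rg) > 1)) {
    abort("`regions` must be non-overlapping: assignment would be ambiguous")
  }
  aln <- filter(alignments, .data$length %in% lengths)
  sample_ids <- if (!is.null(samples)) samples$sample_id else
    sort(unique(alignments$sample_id))
  zero <- matrix(0, nrow(regions), length(sample_ids),
                 dimnames = list(regions$region_id, sample_ids))
  if (nrow(aln) > 0) {
    ag <- iv_granges(aln)
    ov <- GenomicRanges::findOverlaps(ag, rg)
    if (length(ov) > 0) {
      q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
      w <- IRanges::width(IRanges::pintersect(IRanges::ranges(ag)[q],
                                              IRanges::ranges(rg)[s]))
      # one assignment per record: keep the larger overlap, first on ties
      o <- order(q, -w, s)
      keep <- o[!duplicated(q[o])]
      q <- q[keep]; s <- s[keep]
      add <- tibble(region = regions$region_id[s],
                    sample = aln$sample_id[q],
                    weight = 1 / aln$n_hits[q]) |>
        group_by(.data$region, .data$sample) |>
        summarise(w = sum(.data$weight), .groups = "drop")
      zero[cbind(add$region, add$sample)] <- add$w
    }
  }
  bind_cols(regions[c("region_id", "chrom", "start", "end")], as_tibble(zero))
}
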