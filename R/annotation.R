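#' Build a genome annotation object
#'
#' Bundles gene models, transposable-element (TE) intervals and chromosome
#' sizes into a single validated object. All coordinates are internal 0-based
#' half-open (BED convention); the GFF3 readers/writers convert at the
#' boundary.
#'
#' @param genes Tibble with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (gene spans).
#' @param exons Tibble with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`; exons must be sorted, non-overlapping and contained in their
#'   gene span. Introns are the within-span complement of the exons.
#' @param tes Tibble with columns `chrom`, `start`, `end`, `strand`,
#'   `te_class` (non-empty class label, e.g. `"LTR/Gypsy"`).
#' @param chrom_sizes Tibble with columns `chrom`, `length` (bp).
#' @return An object of class `smrna_annotation`.
#' @export
annotation <- function(genes, exons, tes, chrom_sizes) {
  genes <- as_tibble(genes); exons <- as_tibble(exons)
  tes <- as_tibble(tes); chrom_sizes <- as_tibble(chrom_sizes)
  assert_cols(chrom_sizes, c("chrom", "length"), "chrom_sizes")
  assert_cols(genes, c("gene_id", "chrom", "start", "end", "strand"), "genes")
  assert_cols(exons, c("gene_id", "chrom", "start", "end", "strand"), "exons")
  assert_cols(tes, c("chrom", "start", "end", "te_class"), "tes")
  if (!"strand" %in% names(tes)) tes$strand <- "."

  sizes <- setNames(chrom_sizes$length, chrom_sizes$chrom)
  check_iv <- function(df, what) {
    if (nrow(df) == 0) return(invisible())
    if (any(df$start < 0) || any(df$start >= df$end)) {
      abort(sprintf("%s: intervals must satisfy 0 <= start < end", what))
    }
    bad <- is.na(sizes[df$chrom]) | df$end > sizes[df$chrom]
    if (any(bad)) {
      abort(sprintf("%s: %d feature(s) outside chromosome bounds", what, sum(bad)))
    }
  }
  check_iv(genes, "genes"); check_iv(exons, "exons"); check_iv(tes, "tes")
  if (nrow(tes) > 0 && any(is.na(tes$te_class) | tes$te_class == "")) {
    abort("tes: TE class labels must be non-empty")
  }
  # exons contained in span, sorted, non-overlapping within each gene
  if (nrow(exons) > 0) {
    spans <- genes[match(exons$gene_id, genes$gene_id), ]
    if (anyNA(spans$gene_id)) abort("exons reference unknown gene_id")
    if (any(exons$start < spans$start | exons$end > spans$end)) {
      abort("exons: every exon must lie within its gene span")
    }
    exons <- arrange(exons, .data$gene_id, .data$start)
    ovl <- exons |>
      group_by(.data$gene_id) |>
      summarise(bad = any(.data$start[-1] < head(.data$end, -1)), .groups = "drop")
    if (any(ovl$bad)) abort("exons: overlapping exons within a gene model")
  }
  structure(
    list(genes = genes, exons = exons, tes = tes, chrom_sizes = chrom_sizes),
    class = "smrna_annotation"
  )
}

#' @export
print.smrna_annotation <- function(x, ...) {
  cat(sprintf(
    "<smrna_annotation> %d chromosome(s) (%.1f kb), %d gene(s), %d TE(s)\n",
    nrow(x$chrom_sizes), sum(x$chrom_sizes$length) / 1e3,
    nrow(x$genes), nrow(x$tes)))
  invisible(x)
}

# introns = within-span complement of the exons, one tibble for all genes
intron_table <- function(ann) {
  if (nrow(ann$exons) == 0) {
    return(tibble(gene_id = character(), chrom = character(),
                  start = integer(), end = integer(), strand = character()))
  }
  ann$exons |>
    arrange(.data$gene_id, .data$start) |>
    group_by(.data$gene_id, .data$chrom, .data$strand) |>
    summarise(istart = list(head(.data$end, -1)),
              iend = list(.data$start[-1]), .groups = "drop") |>
    tidyr::unnest(c("istart", "iend")) |>
    filter(.data$istart < .data$iend) |>
    select("gene_id", "chrom", start = "istart", end = "iend", "strand")
}

# strand-aware promoter windows, clipped at chromosome bounds
promoter_table <- function(ann, promoter_len = 1000) {
  if (promoter_len <= 0) abort("`promoter_len` must be > 0")
  g <- ann$genes
  if (nrow(g) == 0) return(tibble(chrom = character(), start = integer(), end = integer()))
  if (any(g$strand == ".")) {
    warn("gene(s) with strand '.' treated as '+' for promoter windows")
  }
  sizes <- setNames(ann$chrom_sizes$length, ann$chrom_sizes$chrom)
  minus <- g$strand == "-"
  start <- ifelse(minus, g$end, g$start - promoter_len)
  end <- ifelse(minus, g$end + promoter_len, g$start)
  tibble(gene_id = g$gene_id, chrom = g$chrom,
         start = pmax(0L, as.integer(start)),
         end = pmin(as.integer(sizes[g$chrom]), as.integer(end))) |>
    filter(.data$start < .data$end)
}

iv_granges <- function(df) {
  if (nrow(df) == 0) {
    return(GenomicRanges::GRanges())
  }
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start + 1L, df$end))
}

#' Classify genomic intervals by context
#'
#' Labels each interval with every context it overlaps (>= 1 bp): the
#' strand-aware promoter window upstream of a gene model, exon, intron, TE;
#' `intergenic` if and only if none of the others apply. Multiple labels are
#' allowed (a region can sit in an intron and a TE at once).
#'
#' @param regions Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @param ann An [annotation()] object.
#' @param promoter_len Promoter window length in bp upstream of the gene start
#'   (strand-aware, clipped at chromosome bounds). Default 1000.
#' @return The input tibble with logical columns `promoter`, `exon`, `intron`,
#'   `te`, `intergenic` and a collapsed `context` string.
#' @export
classify_context <- function(regions, ann, promoter_len = 1000) {
  regions <- as_tibble(regions)
  assert_cols(regions, c("chrom", "start", "end"), "regions")
  known <- ann$chrom_sizes$chrom
  if (!all(regions$chrom %in% known)) {
    abort(sprintf("region chromosome(s) absent from chrom_sizes: %s",
                  paste(setdiff(regions$chrom, known), collapse = ", ")))
  }
  q <- iv_granges(regions)
  hit <- function(subj) {
    if (length(subj) == 0) rep(FALSE, length(q))
    else IRanges::overlapsAny(q, subj)
  }
  prom <- hit(iv_granges(promoter_table(ann, promoter_len)))
  exon <- hit(iv_granges(ann$exons))
  intr <- hit(iv_granges(intron_table(ann)))
  te <- hit(iv_granges(ann$tes))
  out <- regions
  out$promoter <- prom; out$exon <- exon; out$intron <- intr; out$te <- te
  out$intergenic <- !(prom | exon | intr | te)
  labs <- cbind(promoter = prom, exon = exon, intron = intr, te = te,
                intergenic = out$intergenic)
  out$context <- apply(labs, 1, function(r) paste(colnames(labs)[r], collapse = ","))
  out
}
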