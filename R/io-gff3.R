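#' Read a genome annotation from GFF3
#'
#' Parses gene, exon and TE features from a GFF3 file (1-based closed
#' coordinates) into the package's 0-based half-open representation. Exons are
#' grouped under their parent gene (one level of indirection, e.g. an mRNA
#' between exon and gene, is resolved). Unknown feature types are ignored with
#' a logged count.
#'
#' @param path Path to a GFF3 file.
#' @param te_types Feature types treated as TEs. The TE class label is taken
#'   from the `class` attribute, falling back to `Name`, then the type.
#' @param chrom_sizes Optional tibble (`chrom`, `length`) or path to a
#'   two-column TSV. If absent, `##sequence-region` pragmas are used, else
#'   sizes are inferred from the maximum feature end (with a note).
#' @return An [annotation()] object.
#' @export
read_gff3 <- function(path,
                      te_types = c("transposable_element", "TE",
                                   "repeat_region", "transposon"),
                      chrom_sizes = NULL) {
  lines <- readLines(path)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf != 9)) {
    bad <- body[which(nf != 9)[1]]
    abort(sprintf("malformed GFF3: line %d has %d column(s), expected 9",
                  bad, nf[which(nf != 9)[1]]))
  }

  if (length(body) == 0) {
    gr <- GenomicRanges::GRanges()
  } else {
    gr <- rtracklayer::import(path, format = "gff3")
  }
  empty_iv <- function() tibble(chrom = character(), start = integer(),
                                end = integer(), strand = character())

  # chromosome sizes: explicit > pragma > inferred
  if (!is.null(chrom_sizes)) {
    if (is.character(chrom_sizes)) {
      chrom_sizes <- readr::read_tsv(chrom_sizes,
                                     col_names = c("chrom", "length"),
                                     col_types = "ci", progress = FALSE)
    }
    cs <- as_tibble(chrom_sizes)
  } else {
    prag <- grep("^##sequence-region", lines, value = TRUE)
    if (length(prag) > 0) {
      parts <- strsplit(trimws(prag), "\\s+")
      cs <- tibble(chrom = map_chr(parts, 2),
                   length = as.integer(map_chr(parts, 4)))
    } else if (length(gr) > 0) {
      inform("no ##sequence-region pragma; chromosome sizes inferred from feature ends")
      cs <- tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
                   end = GenomicRanges::end(gr)) |>
        group_by(.data$chrom) |>
        summarise(length = max(.data$end), .groups = "drop")
    } else {
      cs <- tibble(chrom = character(), length = integer())
    }
  }

  if (length(gr) == 0) {
    return(annotation(
      genes = tibble(gene_id = character(), chrom = character(),
                     start = integer(), end = integer(), strand = character()),
      exons = tibble(gene_id = character(), chrom = character(),
                     start = integer(), end = integer(), strand = character()),
      tes = tibble(chrom = character(), start = integer(), end = integer(),
                   strand = character(), te_class = character()),
      chrom_sizes = cs))
  }

  ft <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # 1-based closed -> 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    id = if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_,
    parent = if (!is.null(gr$Parent)) {
      map_chr(as.list(gr$Parent), ~ if (length(.x)) .x[[1]] else NA_character_)
    } else NA_character_,
    te_class = if (!is.null(gr$class)) as.character(gr$class) else NA_character_,
    name = if (!is.null(gr$Name)) as.character(gr$Name) else NA_character_
  )
  ft$strand[ft$strand == "*"] <- "."

  genes <- ft |> filter(.data$type == "gene") |>
    mutate(gene_id = .data$id) |>
    select("gene_id", "chrom", "start", "end", "strand")
  if (anyNA(genes$gene_id)) abort("gene feature without an ID attribute")

  exons <- ft |> filter(.data$type == "exon")
  if (nrow(exons) > 0) {
    # resolve Parent: direct gene, or one intermediate feature (e.g. mRNA)
    id2parent <- setNames(ft$parent, ft$id)
    resolve <- exons$parent
    miss <- !(resolve %in% genes$gene_id)
    resolve[miss] <- id2parent[resolve[miss]]
    if (any(is.na(resolve)) || !all(resolve %in% genes$gene_id)) {
      abort("exon with unknown Parent gene")
    }
    exons <- exons |> mutate(gene_id = resolve) |>
      select("gene_id", "chrom", "start", "end", "strand")
  } else {
    exons <- tibble(gene_id = character(), chrom = character(),
                    start = integer(), end = integer(), strand = character())
  }

  tes <- ft |> filter(.data$type %in% te_types) |>
    mutate(te_class = dplyr::coalesce(.data$te_class, .data$name, .data$type)) |>
    select("chrom", "start", "end", "strand", "te_class")

  known <- c("gene", "exon", "mRNA", te_types)
  n_ignored <- sum(!ft$type %in% known)
  if (n_ignored > 0) {
    inform(sprintf("read_gff3: ignored %d feature(s) of unknown type", n_ignored))
  }

  annotation(genes = genes, exons = exons, tes = tes, chrom_sizes = cs)
}

#' Write an annotation to GFF3
#'
#' Emits `##sequence-region` pragmas, gene/exon features (exons carry a
#' `Parent` attribute) and TE features (`transposable_element` with a `class`
#' attribute), converting to 1-based closed coordinates.
#'
#' @param ann An [annotation()] object.
#' @param path Output path.
#' @export
write_annotation_gff3 <- function(ann, path) {
  fmt_attr <- function(...) paste(c(...), collapse = ";")
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d",
                     ann$chrom_sizes$chrom, ann$chrom_sizes$length))
  g <- ann$genes
  if (nrow(g) > 0) {
    lines <- c(lines, sprintf("%s\tsmrnaploid\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                              g$chrom, g$start + 1L, g$end, g$strand, g$gene_id))
  }
  e <- ann$exons
  if (nrow(e) > 0) {
    e <- e |> group_by(.data$gene_id) |> mutate(.i = dplyr::row_number()) |> ungroup()
    lines <- c(lines, sprintf(
      "%s\tsmrnaploid\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
      e$chrom, e$start + 1L, e$end, e$strand, e$gene_id, e$.i, e$gene_id))
  }
  t <- ann$tes
  if (nrow(t) > 0) {
    lines <- c(lines, sprintf(
      "%s\tsmrnaploid\ttransposable_element\t%d\t%d\t.\t%s\t.\tID=te%d;class=%s",
      t$chrom, t$start + 1L, t$end, t$strand, seq_len(nrow(t)), t$te_class))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write discovered target regions to GFF3
#'
#' One line per region, feature type `smRNA_target_region`, 1-based closed
#' coordinates. Stable IDs `reg1..regN` are assigned in sorted order, so the
#' input must already be sorted by (chrom, start).
#'
#' @param regions Tibble with `chrom`, `start`, `end` sorted by (chrom, start).
#' @param path Output path.
#' @export
write_regions_gff3 <- function(regions, path) {
  regions <- as_tibble(regions)
  assert_cols(regions, c("chrom", "start", "end"), "regions")
  srt <- arrange(regions, .data$chrom, .data$start)
  if (!identical(srt[c("chrom", "start")], regions[c("chrom", "start")])) {
    abort("`regions` must be sorted by (chrom, start): region IDs would not be stable")
  }
  lines <- c("##gff-version 3",
             sprintf("%s\tsmrnaploid\tsmRNA_target_region\t%d\t%d\t.\t.\t.\tID=reg%d",
                     regions$chrom, regions$start + 1L, regions$end,
                     seq_len(nrow(regions))))
  writeLines(lines, path)
  invisible(path)
}

#' Read target regions written by [write_regions_gff3()]
#'
#' @param path Path to a GFF3 file of `smRNA_target_region` features.
#' @return Tibble with `region_id`, `chrom`, `start`, `end` (0-based half-open).
#' @export
read_regions_gff3 <- function(path) {
  lines <- readLines(path)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(body) == 0) {
    return(tibble(region_id = character(), chrom = character(),
                  start = integer(), end = integer()))
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(f) != 9)) abort("malformed GFF3 region file")
  tibble(
    region_id = sub("^ID=([^;]+).*$", "\\1", map_chr(f, 9)),
    chrom = map_chr(f, 1),
    start = as.integer(map_chr(f, 4)) - 1L,
    end = as.integer(map_chr(f, 5))
  ) |> filter(map_chr(f, 3) == "smRNA_target_region")
}

#' Read TE intervals from a BED6 file
#'
#' @param path Path to a BED file; the name column is used as the TE class.
#' @return Tibble with `chrom`, `start`, `end`, `strand`, `te_class`.
#' @export
read_bed_tes <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  s <- as.character(GenomicRanges::strand(gr))
  s[s == "*"] <- "."
  tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
         start = GenomicRanges::start(gr) - 1L,
         end = GenomicRanges::end(gr),
         strand = s,
         te_class = if (!is.null(gr$name)) as.character(gr$name) else "TE")
}
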