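# Independent brute-force oracles used to validate the package's fast paths.

# literal step-up BH: fdr_i = min over ranks j >= rank(i) of p_(j) * m / j
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  fdr_sorted <- numeric(m)
  for (j in seq_len(m)) {
    fdr_sorted[j] <- min(c((m / (j:m)) * ps[j:m], 1))
  }
  fdr <- numeric(m)
  fdr[o] <- fdr_sorted
  fdr
}

# upper-tail hypergeometric P(X >= k) by direct summation of the pmf
oracle_hyper <- function(N, m, n, k) {
  js <- k:min(m, n)
  sum(choose(m, js) * choose(N - m, n - js)) / choose(N, n)
}

# per-base brute-force region discovery: label every base of every retained
# window, then collect maximal runs of labelled bases
oracle_retain_merge <- function(alignments, chrom_len, window_size, min_reads,
                                lengths = 20:24) {
  aln <- alignments[alignments$length %in% lengths, ]
  samples <- unique(aln$sample_id)
  n_win <- ceiling(chrom_len / window_size)
  win_counts <- matrix(0L, n_win, max(length(samples), 1))
  for (si in seq_along(samples)) {
    a <- aln[aln$sample_id == samples[si], ]
    for (i in seq_len(nrow(a))) {
      w1 <- floor(a$start[i] / window_size) + 1
      w2 <- floor((a$end[i] - 1) / window_size) + 1
      win_counts[w1:w2, si] <- win_counts[w1:w2, si] + 1L
    }
  }
  retained <- which(apply(win_counts, 1, max) >= min_reads)
  base <- logical(chrom_len)
  for (w in retained) {
    base[(w - 1) * window_size + seq_len(min(window_size, chrom_len - (w - 1) * window_size))] <- TRUE
  }
  r <- rle(base)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  tibble::tibble(chrom = rep("chr1", sum(keep)),
                 start = as.integer(starts[keep]),
                 end = as.integer(ends[keep]))
}

# random micro-genome of reads on one chromosome
random_micro_alignments <- function(chrom_len = 5000, n_reads = 300,
                                    n_samples = 2) {
  n <- sample.int(n_reads, 1)
  lens <- sample(20:24, n, replace = TRUE)
  starts <- floor(runif(n) * (chrom_len - lens))
  tibble::tibble(
    sample_id = paste0("s", sample.int(n_samples, n, replace = TRUE)),
    read_id = sprintf("r%04d", seq_len(n)),
    chrom = "chr1",
    start = as.integer(starts),
    end = as.integer(starts + lens),
    length = as.integer(lens),
    n_hits = 1L)
}

# per-base context labeller: a region carries a label iff any of its bases
# falls inside a feature of that kind
oracle_context <- function(region, ann, promoter_len = 1000) {
  bases <- seq(region$start, region$end - 1)
  in_any <- function(df) {
    if (nrow(df) == 0) return(FALSE)
    any(vapply(seq_len(nrow(df)), function(i) {
      df$chrom[i] == region$chrom &&
        any(bases >= df$start[i] & bases < df$end[i])
    }, logical(1)))
  }
  len <- ann$chrom_sizes$length[match(region$chrom, ann$chrom_sizes$chrom)]
  proms <- ann$genes
  if (nrow(proms) > 0) {
    minus <- proms$strand == "-"
    p_start <- ifelse(minus, proms$end, proms$start - promoter_len)
    p_end <- ifelse(minus, proms$end + promoter_len, proms$start)
    proms <- tibble::tibble(chrom = proms$chrom,
                            start = pmax(0, p_start),
                            end = pmin(len, p_end))
    proms <- proms[proms$start < proms$end, ]
  }
  introns <- NULL
  if (nrow(ann$exons) > 0) {
    introns <- do.call(rbind, lapply(split(ann$exons, ann$exons$gene_id), function(e) {
      e <- e[order(e$start), ]
      if (nrow(e) < 2) return(NULL)
      data.frame(chrom = e$chrom[1],
                 start = head(e$end, -1), end = e$start[-1])
    }))
    if (!is.null(introns)) {
      introns <- introns[introns$start < introns$end, , drop = FALSE]
      if (nrow(introns) == 0) introns <- NULL
    }
  }
  labs <- c(promoter = in_any(proms),
            exon = in_any(ann$exons),
            intron = if (is.null(introns)) FALSE else in_any(introns),
            te = in_any(ann$tes))
  c(labs, intergenic = !any(labs))
}

# small random annotation on one chromosome (<= 5 kb)
random_tiny_annotation <- function(chrom_len = 5000) {
  n_genes <- sample(0:2, 1)
  genes <- exons <- NULL
  if (n_genes > 0) {
    for (i in seq_len(n_genes)) {
      gl <- sample(300:800, 1)
      g0 <- sample.int(chrom_len - gl, 1) - 1
      strand <- sample(c("+", "-"), 1)
      gid <- paste0("g", i)
      genes <- rbind(genes, data.frame(gene_id = gid, chrom = "chr1",
                                       start = g0, end = g0 + gl,
                                       strand = strand))
      e1 <- sample(50:150, 1)
      gap <- sample(20:80, 1)
      exons <- rbind(exons,
                     data.frame(gene_id = gid, chrom = "chr1",
                                start = c(g0, g0 + e1 + gap),
                                end = c(g0 + e1, g0 + gl),
                                strand = strand))
    }
  } else {
    genes <- data.frame(gene_id = character(), chrom = character(),
                        start = integer(), end = integer(),
                        strand = character())
    exons <- genes
  }
  n_tes <- sample(0:3, 1)
  if (n_tes > 0) {
    tl <- sample(100:600, n_tes, replace = TRUE)
    t0 <- vapply(tl, function(l) sample.int(chrom_len - l, 1) - 1, numeric(1))
    tes <- data.frame(chrom = "chr1", start = t0, end = t0 + tl,
                      strand = ".", te_class = "LTR/Gypsy")
  } else {
    tes <- data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), te_class = character())
  }
  suppressWarnings(annotation(genes, exons, tes,
                              data.frame(chrom = "chr1", length = chrom_len)))
}

# wide count tibble from a plain matrix
as_counts_tbl <- function(y, region_ids = sprintf("r%d", seq_len(nrow(y)))) {
  if (is.null(colnames(y))) colnames(y) <- paste0("s", seq_len(ncol(y)))
  dplyr::bind_cols(tibble::tibble(region_id = region_ids),
                   tibble::as_tibble(y))
}

two_group_sheet <- function(n_a, n_b, roles = c("A", "B")) {
  tibble::tibble(
    sample_id = paste0("s", seq_len(n_a + n_b)),
    role = rep(roles, c(n_a, n_b)))
}

# scaled-down simulation used where full study-size runs are not needed
small_sim_config <- function(seed = 1, ...) {
  sim_config(seed = seed, n_chroms = 1L, chrom_len = 60000L,
             n_genes = 10L, n_tes = 12L, n_intergenic = 8L,
             group_sizes = c(maternal = 2L, paternal = 2L,
                             polyA = 3L, polyB = 3L),
             lib_size_mean = 1e4, ...)
}
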