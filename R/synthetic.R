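#' Configuration for the synthetic small-RNA dataset generator
#'
#' The generator emulates the study design the package targets: four species
#' groups with unequal replicate numbers (two diploid parents and two sibling
#' allopolyploids), log-normal library-size variation, negative-binomial
#' per-region counts with planted interaction classes, a 20-24 nt read-length
#' mixture with modes at 21-22 nt and 24 nt, and preferential placement of
#' 24 nt reads in TE regions.
#'
#' @param seed Integer seed; fixes every output byte.
#' @param n_chroms,chrom_len Genome shape (chromosome count and length, bp).
#' @param n_genes,n_tes,n_intergenic Feature counts; one ground-truth target
#'   region is planted per feature (inside an exon for genes, inside the TE
#'   for TEs) and per intergenic slot.
#' @param region_len Planted target-region length (bp).
#' @param group_sizes Named replicate counts for roles
#'   `maternal`, `paternal`, `polyA`, `polyB`.
#' @param lib_size_mean,lib_size_cv Mean reads per sample and log-normal
#'   coefficient of variation.
#' @param dispersion Negative-binomial dispersion phi (variance
#'   `m + phi m^2`); 0 degenerates to Poisson.
#' @param base_mean_log2 log2 of the baseline expected count per region.
#' @param effect_log2fc Planted absolute log2 fold change between differing
#'   groups.
#' @param class_probs Probabilities over the six truth classes `null`,
#'   `additive`, `dominant_maternal`, `dominant_paternal`,
#'   `transgressive_up`, `transgressive_down`.
#' @param len_probs Read-length distribution over 20-24 nt.
#' @param te_frac_24nt Probability that a 24 nt read is placed in a TE region
#'   (draws landing in non-TE regions are resampled to 20-23 nt with this
#'   probability).
#' @param multimap_prob Fraction of reads with more than one reported hit.
#' @param max_hits Cap on reported hits per read (<= 100).
#' @return A validated list of class `smrna_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L, chrom_len = 200000L,
                       n_genes = 60L, n_tes = 80L, n_intergenic = 60L,
                       region_len = 200L,
                       group_sizes = c(maternal = 4L, paternal = 4L,
                                       polyA = 9L, polyB = 12L),
                       lib_size_mean = 4e4, lib_size_cv = 0.4,
                       dispersion = 0.05,
                       base_mean_log2 = 6,
                       effect_log2fc = 1.5,
                       class_probs = c(null = 0.40, additive = 0.12,
                                       dominant_maternal = 0.12,
                                       dominant_paternal = 0.12,
                                       transgressive_up = 0.12,
                                       transgressive_down = 0.12),
                       len_probs = c(`20` = 0.08, `21` = 0.22, `22` = 0.22,
                                     `23` = 0.08, `24` = 0.40),
                       te_frac_24nt = 0.7,
                       multimap_prob = 0.05,
                       max_hits = 100L) {
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_len = as.integer(chrom_len), n_genes = as.integer(n_genes),
              n_tes = as.integer(n_tes), n_intergenic = as.integer(n_intergenic),
              region_len = as.integer(region_len), group_sizes = group_sizes,
              lib_size_mean = lib_size_mean, lib_size_cv = lib_size_cv,
              dispersion = dispersion, base_mean_log2 = base_mean_log2,
              effect_log2fc = effect_log2fc, class_probs = class_probs,
              len_probs = len_probs, te_frac_24nt = te_frac_24nt,
              multimap_prob = multimap_prob, max_hits = as.integer(max_hits))
  roles <- c("maternal", "paternal", "polyA", "polyB")
  if (!all(roles %in% names(cfg$group_sizes))) {
    abort("`group_sizes` must name maternal, paternal, polyA, polyB")
  }
  if (abs(sum(cfg$class_probs) - 1) > 1e-9) abort("`class_probs` must sum to 1")
  if (abs(sum(cfg$len_probs) - 1) > 1e-9) abort("`len_probs` must sum to 1")
  if (!identical(names(cfg$len_probs), as.character(20:24))) {
    abort("`len_probs` must be named '20'..'24'")
  }
  if (cfg$max_hits > 100L || cfg$max_hits < 1L) abort("`max_hits` must be in [1, 100]")
  if (any(unlist(cfg[c("n_chroms", "chrom_len", "n_genes", "n_tes",
                       "region_len", "lib_size_mean")]) <= 0) ||
      any(cfg$group_sizes <= 0)) {
    abort("genome/feature/library sizes must all be positive")
  }
  if (cfg$dispersion < 0) abort("`dispersion` must be >= 0")
  if (cfg$region_len < 24L) abort("`region_len` must be >= 24 (longest read)")
  structure(cfg, class = "smrna_sim_config")
}

truth_classes <- c("null", "additive", "dominant_maternal", "dominant_paternal",
                   "transgressive_up", "transgressive_down")

#' Simulate a genome annotation, sample sheet and ground-truth regions
#'
#' Lays out genes, TEs and intergenic slots on the genome without overlap and
#' plants one target region per slot with a known interaction class. Group
#' means follow the class semantics: `null` leaves all four groups equal;
#' `additive` separates the parents by `effect_log2fc` and puts both
#' polyploids at the parents' arithmetic (mid-parent) mean; dominance pins
#' both polyploids to one parent and offsets the other parent; transgressive
#' classes offset both polyploids above/below the (equal) parents.
#'
#' @param cfg A [sim_config()] object.
#' @return A list with `annotation` ([annotation()]), `truth` (tibble of
#'   planted regions with per-role expected counts) and `samples` (sample
#'   sheet tibble).
#' @export
simulate_truth <- function(cfg) {
  stopifnot(inherits(cfg, "smrna_sim_config"))
  set.seed(stage_seed(cfg$seed, 1L))

  n_slots <- cfg$n_genes + cfg$n_tes + cfg$n_intergenic
  total_len <- cfg$n_chroms * cfg$chrom_len
  slot_len <- floor(total_len / n_slots)
  required <- 1000L + 2L * 100L   # widest feature (gene 700-1000 bp) + margins
  if (slot_len < required) {
    abort(sprintf(
      "genome too small to place %d features: need at least %d bp total (%d bp/slot)",
      n_slots, n_slots * required, required))
  }

  chroms <- sprintf("chr%d", seq_len(cfg$n_chroms))
  chrom_sizes <- tibble(chrom = chroms, length = cfg$chrom_len)
  slots_per_chrom <- diff(round(seq(0, n_slots, length.out = cfg$n_chroms + 1)))
  slot_tbl <- tibble(
    chrom = rep(chroms, slots_per_chrom),
    idx = unlist(lapply(slots_per_chrom, seq_len)),
    slot_len = unlist(lapply(slots_per_chrom, function(k) rep(floor(cfg$chrom_len / k), k)))
  ) |> mutate(slot_start = (.data$idx - 1L) * .data$slot_len)
  kind <- sample(rep(c("gene", "te", "intergenic"),
                     c(cfg$n_genes, cfg$n_tes, cfg$n_intergenic)))
  slot_tbl$kind <- kind

  rl <- cfg$region_len
  genes <- exons <- tes <- NULL
  regions <- vector("list", n_slots)
  gi <- ti <- 0L
  for (i in seq_len(n_slots)) {
    s <- slot_tbl[i, ]
    room <- s$slot_len - required
    off <- s$slot_start + 100L + sample.int(max(room, 1L), 1L) - 1L
    if (s$kind == "gene") {
      gi <- gi + 1L
      gl <- 700L + sample.int(301L, 1L) - 1L
      strand <- sample(c("+", "-"), 1L)
      gid <- sprintf("g%03d", gi)
      g0 <- off
      e1 <- c(g0, g0 + 300L); e2 <- c(g0 + 450L, g0 + gl)
      genes <- bind_rows(genes, tibble(gene_id = gid, chrom = s$chrom,
                                       start = g0, end = g0 + gl, strand = strand))
      exons <- bind_rows(exons,
        tibble(gene_id = gid, chrom = s$chrom,
               start = c(e1[1], e2[1]), end = c(e1[2], e2[2]), strand = strand))
      r0 <- e2[1] + sample.int(e2[2] - e2[1] - rl + 1L, 1L) - 1L
      regions[[i]] <- tibble(chrom = s$chrom, start = r0, end = r0 + rl,
                             feature = "gene")
    } else if (s$kind == "te") {
      ti <- ti + 1L
      tl <- 400L + sample.int(401L, 1L) - 1L
      cls <- sample(c("LTR/Gypsy", "LTR/Copia", "DNA/MuDR"), 1L,
                    prob = c(0.5, 0.3, 0.2))
      tes <- bind_rows(tes, tibble(chrom = s$chrom, start = off, end = off + tl,
                                   strand = ".", te_class = cls))
      r0 <- off + sample.int(tl - rl + 1L, 1L) - 1L
      regions[[i]] <- tibble(chrom = s$chrom, start = r0, end = r0 + rl,
                             feature = "te")
    } else {
      regions[[i]] <- tibble(chrom = s$chrom, start = off, end = off + rl,
                             feature = "intergenic")
    }
  }
  truth <- bind_rows(regions) |>
    arrange(.data$chrom, .data$start) |>
    mutate(region_id = sprintf("t%04d", dplyr::row_number()), .before = 1)

  # planted classes and per-role expected counts
  n <- nrow(truth)
  cls <- sample(truth_classes, n, replace = TRUE, prob = cfg$class_probs[truth_classes])
  side <- sample(c(1, -1), n, replace = TRUE)   # which group sits on the high side
  b <- 2^cfg$base_mean_log2
  d <- 2^(cfg$effect_log2fc / 2)
  mm <- mp <- pa <- pb <- rep(b, n)
  i <- cls == "additive"
  mm[i] <- b * d^side[i]; mp[i] <- b * d^(-side[i])
  pa[i] <- pb[i] <- (mm[i] + mp[i]) / 2
  i <- cls == "dominant_maternal"
  mm[i] <- pa[i] <- pb[i] <- b * d^side[i]; mp[i] <- b * d^(-side[i])
  i <- cls == "dominant_paternal"
  mp[i] <- pa[i] <- pb[i] <- b * d^side[i]; mm[i] <- b * d^(-side[i])
  i <- cls == "transgressive_up"
  mm[i] <- mp[i] <- b / d; pa[i] <- pb[i] <- b * d
  i <- cls == "transgressive_down"
  mm[i] <- mp[i] <- b * d; pa[i] <- pb[i] <- b / d
  truth <- truth |> mutate(
    truth_class = cls,
    dominant_parent = dplyr::case_when(
      cls == "dominant_maternal" ~ "maternal",
      cls == "dominant_paternal" ~ "paternal",
      TRUE ~ NA_character_),
    mean_maternal = mm, mean_paternal = mp,
    mean_polyA = pa, mean_polyB = pb)

  ann <- annotation(genes = genes, exons = exons, tes = tes,
                    chrom_sizes = chrom_sizes)

  roles <- c("maternal", "paternal", "polyA", "polyB")
  labels <- c(maternal = "diploid_maternal", paternal = "diploid_paternal",
              polyA = "polyploid_A", polyB = "polyploid_B")
  prefix <- c(maternal = "mat", paternal = "pat", polyA = "pA", polyB = "pB")
  sdlog <- sqrt(log(1 + cfg$lib_size_cv^2))
  meanlog <- log(cfg$lib_size_mean) - sdlog^2 / 2
  samples <- purrr::map_dfr(roles, function(r) {
    k <- cfg$group_sizes[[r]]
    tibble(sample_id = sprintf("%s_%02d", prefix[[r]], seq_len(k)),
           species_label = labels[[r]], role = r,
           lib_size = round(stats::rlnorm(k, meanlog, sdlog)))
  })

  list(annotation = ann, truth = truth, samples = samples)
}

#' Simulate the region-by-sample count matrix
#'
#' Draws `count ~ NB(mean = group_mean * lib_size / lib_size_mean,
#' dispersion = phi)`; `phi = 0` degenerates to Poisson. Seed-determined by the
#' configuration.
#'
#' @param truth Truth tibble from [simulate_truth()].
#' @param samples Sample sheet from [simulate_truth()].
#' @param cfg A [sim_config()] object.
#' @return Wide count tibble: `region_id` plus one integer column per sample.
#' @export
simulate_counts <- function(truth, samples, cfg) {
  stopifnot(inherits(cfg, "smrna_sim_config"))
  set.seed(stage_seed(cfg$seed, 2L))
  mean_cols <- c(maternal = "mean_maternal", paternal = "mean_paternal",
                 polyA = "mean_polyA", polyB = "mean_polyB")
  mu <- sapply(seq_len(nrow(samples)), function(j) {
    truth[[mean_cols[[samples$role[j]]]]] * samples$lib_size[j] / cfg$lib_size_mean
  })
  if (any(mu < 0)) abort("negative expected count")
  phi <- cfg$dispersion
  counts <- if (phi == 0) {
    matrix(rpois(length(mu), mu), nrow = nrow(mu))
  } else {
    matrix(rnbinom(length(mu), mu = mu, size = 1 / phi), nrow = nrow(mu))
  }
  colnames(counts) <- samples$sample_id
  bind_cols(tibble(region_id = truth$region_id), as_tibble(counts))
}

#' Emit per-sample alignment records from a count matrix
#'
#' Each region's count for a sample becomes that many reads placed uniformly
#' (fully inside) the region's planted interval. Read lengths are drawn from
#' the configured 20-24 nt mixture; a 24 nt draw landing in a non-TE region is
#' resampled to 20-23 nt with probability `te_frac_24nt`, so 24 nt reads are
#' preferentially emitted from TE-overlapping regions. A `multimap_prob`
#' fraction of reads is duplicated to `k <= max_hits` locations (`n_hits = k`
#' on every record, so each record carries fractional weight `1/k`), with the
#' extra hits placed in random TE intervals.
#'
#' @param counts Wide count tibble from [simulate_counts()].
#' @param truth Truth tibble from [simulate_truth()].
#' @param ann The matching [annotation()].
#' @param cfg A [sim_config()] object.
#' @return Tibble of alignment records: `sample_id`, `read_id`, `chrom`,
#'   `start`, `end`, `length`, `n_hits`.
#' @export
emit_alignments <- function(counts, truth, ann, cfg) {
  stopifnot(inherits(cfg, "smrna_sim_config"))
  set.seed(stage_seed(cfg$seed, 3L))
  m <- as_count_matrix(counts)
  tr <- truth[match(rownames(m), truth$region_id), ]
  if (any(tr$end - tr$start < 24L)) abort("region shorter than the longest read length")
  is_te_region <- if (nrow(ann$tes) > 0) {
    IRanges::overlapsAny(iv_granges(tr), iv_granges(ann$tes))
  } else rep(FALSE, nrow(tr))

  long <- tidyr::expand_grid(r = seq_len(nrow(m)), s = seq_len(ncol(m))) |>
    mutate(n = m[cbind(.data$r, .data$s)]) |>
    filter(.data$n > 0)
  ridx <- rep(long$r, long$n)
  sidx <- rep(long$s, long$n)
  nread <- length(ridx)
  if (nread == 0) {
    return(tibble(sample_id = character(), read_id = character(),
                  chrom = character(), start = integer(), end = integer(),
                  length = integer(), n_hits = integer()))
  }

  lens <- as.integer(sample(20:24, nread, replace = TRUE, prob = cfg$len_probs))
  resample <- lens == 24L & !is_te_region[ridx] &
    runif(nread) < cfg$te_frac_24nt
  if (any(resample)) {
    p_short <- cfg$len_probs[1:4] / sum(cfg$len_probs[1:4])
    lens[resample] <- as.integer(sample(20:23, sum(resample), replace = TRUE,
                                        prob = p_short))
  }
  room <- (tr$end[ridx] - tr$start[ridx]) - lens
  starts <- tr$start[ridx] + floor(runif(nread) * (room + 1))
  sample_ids <- colnames(m)[sidx]
  read_ids <- sprintf("%s_r%06d", sample_ids, stats::ave(ridx, sidx, FUN = seq_along))

  has_tes <- nrow(ann$tes) > 0 && all(ann$tes$end - ann$tes$start >= 24L)
  n_hits <- rep(1L, nread)
  if (cfg$multimap_prob > 0 && has_tes) {
    mm <- runif(nread) < cfg$multimap_prob
    k <- pmin(2L + rgeom(nread, 0.5), cfg$max_hits)
    n_hits[mm] <- k[mm]
  }
  primary <- tibble(sample_id = sample_ids, read_id = read_ids,
                    chrom = tr$chrom[ridx],
                    start = as.integer(starts),
                    end = as.integer(starts + lens),
                    length = lens, n_hits = n_hits)
  extra_n <- n_hits - 1L
  if (any(extra_n > 0)) {
    ei <- rep(seq_len(nread), extra_n)
    ne <- length(ei)
    te_i <- sample.int(nrow(ann$tes), ne, replace = TRUE)
    te <- ann$tes[te_i, ]
    el <- lens[ei]
    es <- te$start + floor(runif(ne) * (te$end - te$start - el + 1))
    extras <- tibble(sample_id = sample_ids[ei], read_id = read_ids[ei],
                     chrom = te$chrom, start = as.integer(es),
                     end = as.integer(es + el), length = el,
                     n_hits = n_hits[ei])
    primary <- bind_rows(primary, extras)
  }
  arrange(primary, .data$sample_id, .data$chrom, .data$start, .data$read_id)
}

#' Simulate a complete dataset (annotation, truth, counts, alignments)
#'
#' Convenience wrapper running [simulate_truth()], [simulate_counts()] and
#' [emit_alignments()] under one seed; optionally writes all outputs as plain
#' text (GFF3 + TSV).
#'
#' @param cfg A [sim_config()] object.
#' @param dir Optional output directory; if given, writes `annotation.gff3`,
#'   `samples.tsv`, `truth.tsv`, `counts.tsv` and `alignments.tsv`.
#' @return List with `annotation`, `truth`, `samples`, `counts`, `alignments`.
#' @export
simulate_dataset <- function(cfg, dir = NULL) {
  sim <- simulate_truth(cfg)
  counts <- simulate_counts(sim$truth, sim$samples, cfg)
  aln <- emit_alignments(counts, sim$truth, sim$annotation, cfg)
  out <- list(annotation = sim$annotation, truth = sim$truth,
              samples = sim$samples, counts = counts, alignments = aln)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_annotation_gff3(sim$annotation, file.path(dir, "annotation.gff3"))
    readr::write_tsv(sim$samples, file.path(dir, "samples.tsv"), progress = FALSE)
    readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"), progress = FALSE)
    readr::write_tsv(counts, file.path(dir, "counts.tsv"), progress = FALSE)
    readr::write_tsv(aln, file.path(dir, "alignments.tsv"), progress = FALSE)
  }
  out
}

#' Read an alignment table written by [simulate_dataset()]
#'
#' @param path Path to an `alignments.tsv` file.
#' @return Tibble of alignment records.
#' @export
read_alignments <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    sample_id = "c", read_id = "c", chrom = "c",
    start = "i", end = "i", length = "i", n_hits = "i"), progress = FALSE)
}
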