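#' Classify polyploid-parent genomic interactions
#'
#' Joins the two polyploid-versus-parent test results by region and applies
#' the decision table: both contrasts significant with opposite log fold
#' changes -> `additive` (the polyploid sits between the parents); both
#' significant and both positive/negative -> `transgressive_up` /
#' `transgressive_down`; exactly one significant -> dominance toward the
#' parent the polyploid does NOT differ from; neither -> `no_change`.
#'
#' @param results_vs_maternal,results_vs_paternal [nb_test()] results with
#'   log fold changes oriented polyploid/diploid.
#' @param alpha FDR significance threshold (default 0.05, strict `<`).
#' @param polyploid Optional label recorded in the output.
#' @return Tibble: `region_id`, `polyploid`, `category`, the four inputs
#'   (`fdr_vs_maternal`, `log_fc_vs_maternal`, `fdr_vs_paternal`,
#'   `log_fc_vs_paternal`) and an `ambiguous` flag (significant contrast with
#'   a zero log fold change cannot be oriented; its category is `NA`).
#' @export
classify_interactions <- function(results_vs_maternal, results_vs_paternal,
                                  alpha = 0.05, polyploid = "polyploid") {
  assert_cols(results_vs_maternal, c("region_id", "log_fc", "fdr"),
              "results_vs_maternal")
  assert_cols(results_vs_paternal, c("region_id", "log_fc", "fdr"),
              "results_vs_paternal")
  d <- inner_join(
    tibble(region_id = results_vs_maternal$region_id,
           fdr_vs_maternal = results_vs_maternal$fdr,
           log_fc_vs_maternal = results_vs_maternal$log_fc),
    tibble(region_id = results_vs_paternal$region_id,
           fdr_vs_paternal = results_vs_paternal$fdr,
           log_fc_vs_paternal = results_vs_paternal$log_fc),
    by = "region_id")
  sM <- d$fdr_vs_maternal < alpha
  sP <- d$fdr_vs_paternal < alpha
  ambiguous <- (sM & d$log_fc_vs_maternal == 0) | (sP & d$log_fc_vs_paternal == 0)
  up_m <- d$log_fc_vs_maternal > 0
  up_p <- d$log_fc_vs_paternal > 0
  category <- dplyr::case_when(
    ambiguous ~ NA_character_,
    sM & sP & up_m & up_p ~ "transgressive_up",
    sM & sP & !up_m & !up_p ~ "transgressive_down",
    sM & sP ~ "additive",
    sM & !sP ~ "dominant_paternal",   # indistinguishable from the paternal parent
    !sM & sP ~ "dominant_maternal",
    TRUE ~ "no_change")
  tibble(region_id = d$region_id, polyploid = polyploid, category = category,
         ambiguous = ambiguous) |>
    bind_cols(d[c("fdr_vs_maternal", "log_fc_vs_maternal",
                  "fdr_vs_paternal", "log_fc_vs_paternal")])
}

#' Hypergeometric test for shared DT regions between two polyploids
#'
#' Upper-tail exact test of whether the observed intersection of two DT
#' region sets is larger than expected for independent draws from the tested
#' universe: `p = P(X >= k)` for `X ~ Hypergeometric(N, m, n)`.
#'
#' @param ids_a,ids_b Character vectors of DT region ids for the two
#'   polyploids; must be subsets of `universe`.
#' @param universe All regions tested in both analyses.
#' @return One-row tibble: `N`, `m`, `n`, `k`, `expected`, `p_value`.
#' @export
shared_dt_test <- function(ids_a, ids_b, universe) {
  universe <- unique(universe)
  ids_a <- unique(ids_a); ids_b <- unique(ids_b)
  if (!all(ids_a %in% universe) || !all(ids_b %in% universe)) {
    abort("`ids_a` and `ids_b` must be subsets of `universe`")
  }
  N <- length(universe); m <- length(ids_a); n <- length(ids_b)
  k <- length(intersect(ids_a, ids_b))
  if (k > min(m, n)) abort("intersection larger than the smaller set")
  p <- if (k == 0) 1 else phyper(k - 1, m, N - m, n, lower.tail = FALSE)
  tibble(N = N, m = m, n = n, k = k,
         expected = m * n / max(N, 1), p_value = p)
}

#' Per-length CPM comparison between species groups
#'
#' For each sample, the CPM of reads at each length (reads of that length per
#' million 20-24 nt reads); for each pair of species groups and each length,
#' a two-sided Welch t-test (unequal variances, Satterthwaite df).
#'
#' @param alignments Alignment-record tibble (each read counted once via its
#'   `read_id`).
#' @param samples Sample sheet (`sample_id`, `role`).
#' @return Tibble: `length`, `group_a`, `group_b`, `mean_a`, `mean_b`,
#'   `t_stat`, `df`, `p_value`, `degenerate` (zero variance in both groups).
#' @export
per_length_cpm_compare <- function(alignments, samples) {
  assert_cols(alignments, c("sample_id", "read_id", "length"), "alignments")
  assert_cols(samples, c("sample_id", "role"), "samples")
  reads <- distinct(alignments, .data$sample_id, .data$read_id, .data$length)
  percpm <- reads |>
    count(.data$sample_id, .data$length) |>
    group_by(.data$sample_id) |>
    mutate(cpm = .data$n / sum(.data$n) * 1e6) |>
    ungroup() |>
    tidyr::complete(sample_id = samples$sample_id, length = 20:24,
                    fill = list(n = 0, cpm = 0)) |>
    left_join(samples[c("sample_id", "role")], by = "sample_id")
  roles <- unique(samples$role)
  n_per <- table(samples$role)
  if (any(n_per < 2)) abort("every species group needs at least two samples")
  pairs <- utils::combn(roles, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    purrr::map_dfr(20:24, function(L) {
      xa <- percpm$cpm[percpm$role == pr[1] & percpm$length == L]
      xb <- percpm$cpm[percpm$role == pr[2] & percpm$length == L]
      welch_row(xa, xb) |>
        mutate(length = L, group_a = pr[1], group_b = pr[2], .before = 1)
    })
  })
}

welch_row <- function(xa, xb) {
  va <- stats::var(xa); vb <- stats::var(xb)
  if (va == 0 && vb == 0) {
    if (mean(xa) == mean(xb)) {
      return(tibble(mean_a = mean(xa), mean_b = mean(xb), t_stat = 0,
                    df = NA_real_, p_value = 1, degenerate = TRUE))
    }
    return(tibble(mean_a = mean(xa), mean_b = mean(xb),
                  t_stat = sign(mean(xa) - mean(xb)) * Inf,
                  df = NA_real_, p_value = 0, degenerate = TRUE))
  }
  tt <- stats::t.test(xa, xb, var.equal = FALSE)
  tibble(mean_a = mean(xa), mean_b = mean(xb),
         t_stat = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, degenerate = FALSE)
}

#' Proportions of alignment weight by genomic feature context
#'
#' Classifies every alignment interval by context and aggregates fractional
#' alignment weight (`1/n_hits`) per sample and read length into three bins:
#' `exon`, `te`, `other` (promoter, intron, intergenic). A multi-label
#' alignment splits its weight equally among its labels before binning;
#' fractions sum to 1 per (sample, length).
#'
#' @param alignments Alignment-record tibble.
#' @param ann An [annotation()] object.
#' @param promoter_len Promoter window for context classification.
#' @return Long tibble: `sample_id`, `length`, `context`, `weight`,
#'   `fraction`.
#' @export
feature_mapping_proportions <- function(alignments, ann, promoter_len = 1000) {
  assert_cols(alignments, c("sample_id", "chrom", "start", "end", "length",
                            "n_hits"), "alignments")
  if (nrow(alignments) == 0) {
    return(tibble(sample_id = character(), length = integer(),
                  context = character(), weight = numeric(),
                  fraction = numeric()))
  }
  ctx <- classify_context(alignments[c("chrom", "start", "end")], ann,
                          promoter_len)
  labs <- as.matrix(ctx[c("promoter", "exon", "intron", "te", "intergenic")])
  n_labs <- rowSums(labs)
  bin_of <- c(promoter = "other", exon = "exon", intron = "other",
              te = "te", intergenic = "other")
  w <- 1 / alignments$n_hits
  per_bin <- vapply(c("exon", "te", "other"), function(b) {
    cols <- names(bin_of)[bin_of == b]
    rowSums(labs[, cols, drop = FALSE]) / n_labs * w
  }, numeric(nrow(alignments)))
  if (!is.matrix(per_bin)) {
    per_bin <- matrix(per_bin, nrow = 1,
                      dimnames = list(NULL, c("exon", "te", "other")))
  }
  long <- bind_cols(alignments[c("sample_id", "length")], as_tibble(per_bin)) |>
    tidyr::pivot_longer(c("exon", "te", "other"), names_to = "context",
                        values_to = "w") |>
    group_by(.data$sample_id, .data$length, .data$context) |>
    summarise(weight = sum(.data$w), .groups = "drop_last") |>
    mutate(fraction = .data$weight / sum(.data$weight)) |>
    ungroup()
  long
}

#' Classical MDS of samples from a count table
#'
#' Pairwise sample distance is the root-mean-square of the `top_k` largest
#' absolute log2 CPM differences between the two samples (leading fold
#' change, prior count added before the log); the distance matrix is embedded
#' by classical MDS. Axis signs are fixed by making each axis's
#' largest-magnitude coordinate positive.
#'
#' @param counts Wide count tibble or matrix.
#' @param top_k Number of leading regions per pair (default 500; if fewer
#'   regions are available, all are used with a note).
#' @param dims Number of dimensions (default 2).
#' @param lib_sizes Optional library sizes.
#' @param prior_count Prior count on the CPM scale offset (default 0.5,
#'   scaled by mean library size).
#' @return Tibble of class `smrna_mds`: `sample_id`, `dim1`, `dim2`, ...;
#'   eigenvalues in the `eig` attribute.
#' @export
mds_coordinates <- function(counts, top_k = 500, dims = 2, lib_sizes = NULL,
                            prior_count = 0.5) {
  m <- as_count_matrix(counts)
  if (ncol(m) < 3) abort("MDS needs at least three samples")
  ls <- resolve_lib_sizes(counts, lib_sizes)
  pc <- prior_count * 1e6 / mean(ls)
  lcpm <- log2(sweep(m, 2, ls, "/") * 1e6 + pc)
  k <- min(top_k, nrow(m))
  if (k < top_k) inform(sprintf("only %d regions available; using all of them", k))
  S <- ncol(m)
  d <- matrix(0, S, S, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(S - 1)) {
    for (j in (i + 1):S) {
      dif <- sort(abs(lcpm[, i] - lcpm[, j]), decreasing = TRUE)[seq_len(k)]
      d[i, j] <- d[j, i] <- sqrt(mean(dif^2))
    }
  }
  mds_embed(d, dims)
}

#' Embed a distance matrix by classical MDS
#'
#' Double-centred squared-distance decomposition with coordinates scaled by
#' the root eigenvalues; axis signs fixed by making each axis's
#' largest-magnitude coordinate positive.
#'
#' @param d Symmetric distance matrix (or `dist`).
#' @param dims Number of dimensions.
#' @return Tibble of class `smrna_mds` with `sample_id` and `dim1..dimK`;
#'   eigenvalues in the `eig` attribute.
#' @export
mds_embed <- function(d, dims = 2) {
  d <- as.matrix(d)
  fit <- cmdscale(d, k = dims, eig = TRUE)
  coords <- fit$points
  for (a in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, a]))
    if (coords[i, a] < 0) coords[, a] <- -coords[, a]
  }
  out <- bind_cols(
    tibble(sample_id = rownames(d) %||% as.character(seq_len(nrow(d)))),
    as_tibble(setNames(as.data.frame(coords),
                       paste0("dim", seq_len(ncol(coords))))))
  structure(out, class = c("smrna_mds", class(out)), eig = fit$eig)
}
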