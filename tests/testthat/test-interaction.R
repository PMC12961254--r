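mk_res <- function(fdr, lfc) {
  tibble::tibble(region_id = sprintf("r%d", seq_along(fdr)),
                 log_fc = lfc, fdr = fdr)
}

test_that("the interaction decision table matches its definition", {
  m <- mk_res(c(0.01, 0.01, 0.60, 0.01, 0.90),
              c(+1.2, +2.0, +0.1, -1.0, 0.0))
  p <- mk_res(c(0.01, 0.01, 0.01, 0.60, 0.80),
              c(-1.0, +1.5, +1.8, -0.2, 0.0))
  calls <- classify_interactions(m, p)
  expect_equal(calls$category,
               c("additive",            # significant both ways, opposite signs
                 "transgressive_up",    # above both parents
                 "dominant_maternal",   # only differs from the paternal parent
                 "dominant_paternal",   # only differs from the maternal parent
                 "no_change"))
})

test_that("every significance/sign combination maps to exactly one category", {
  grid <- expand.grid(sM = c(TRUE, FALSE), sP = c(TRUE, FALSE),
                      signM = c(1, -1), signP = c(1, -1))
  m <- mk_res(ifelse(grid$sM, 0.01, 0.5), grid$signM * 1.5)
  p <- mk_res(ifelse(grid$sP, 0.01, 0.5), grid$signP * 1.5)
  calls <- classify_interactions(m, p)
  expect_false(any(is.na(calls$category)))
  expect_setequal(unique(calls$category),
                  c("additive", "transgressive_up", "transgressive_down",
                    "dominant_maternal", "dominant_paternal", "no_change"))
  # deterministic single category per cell
  expect_equal(length(calls$category), nrow(grid))
  # both-significant cells split by sign pattern
  both <- grid$sM & grid$sP
  expect_true(all(calls$category[both & grid$signM == 1 & grid$signP == 1] ==
                    "transgressive_up"))
  expect_true(all(calls$category[both & grid$signM == -1 & grid$signP == -1] ==
                    "transgressive_down"))
  expect_true(all(calls$category[both & grid$signM != grid$signP] == "additive"))
})

test_that("a significant contrast with zero logFC is flagged ambiguous", {
  calls <- classify_interactions(mk_res(0.01, 0), mk_res(0.01, 1))
  expect_true(calls$ambiguous)
  expect_true(is.na(calls$category))
})

test_that("shared_dt_test reproduces exact enumeration values", {
  u10 <- sprintf("u%02d", 1:10)
  r <- shared_dt_test(u10[1:5], u10[1:5], u10)
  expect_equal(r$p_value, 1 / 252, tolerance = 1e-12)

  u4 <- sprintf("u%d", 1:4)
  r2 <- shared_dt_test(u4[1:2], u4[1:2], u4)
  expect_equal(r2$p_value, 1 / 6, tolerance = 1e-12)

  r0 <- shared_dt_test(u10[1:5], u10[6:10], u10)
  expect_equal(r0$k, 0L)
  expect_equal(r0$p_value, 1)

  expect_error(shared_dt_test(c("x", "z"), "x", c("x", "y")), "subset")
})

test_that("shared_dt_test equals brute-force summation for all small cases", {
  for (N in c(4, 7, 10)) {
    u <- sprintf("u%02d", seq_len(N))
    for (m in 0:N) for (n in 0:N) for (k in max(0, m + n - N):min(m, n)) {
      ids_a <- u[seq_len(m)]
      ids_b <- c(u[seq_len(k)], rev(u)[seq_len(n - k)])
      if (length(intersect(ids_a, ids_b)) != k) next
      got <- shared_dt_test(ids_a, ids_b, u)$p_value
      want <- if (k == 0) 1 else oracle_hyper(N, m, n, k)
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("shared_dt_test p-values are roughly uniform under independent draws", {
  set.seed(77)
  u <- sprintf("u%03d", 1:60)
  p <- replicate(400, {
    shared_dt_test(sample(u, 20), sample(u, 25), u)$p_value
  })
  # discrete statistic: super-uniformity of the upper-tail p-value
  expect_lte(mean(p < 0.05), 0.08)
  expect_gte(mean(p), 0.45)
})

test_that("Welch comparison reproduces hand-computed statistics", {
  sheet <- tibble::tibble(sample_id = paste0("s", 1:6),
                          role = rep(c("A", "B"), each = 3))
  # craft alignments whose per-sample 21 nt CPM are {1,2,3} vs {4,5,6} * 1e5
  reads <- dplyr::bind_rows(purrr::map2(
    paste0("s", 1:6), c(1, 2, 3, 4, 5, 6),
    function(s, k) {
      n21 <- k; n22 <- 10 - k
      tibble::tibble(sample_id = s,
                     read_id = sprintf("%s_%02d", s, 1:10),
                     chrom = "chr1",
                     start = 0L, end = 21L,
                     length = c(rep(21L, n21), rep(22L, n22)),
                     n_hits = 1L)
    }))
  tab <- per_length_cpm_compare(reads, sheet)
  row <- tab[tab$length == 21 & tab$group_a == "A", ]
  expect_equal(row$t_stat, -3.674, tolerance = 1e-3)
  expect_equal(row$df, 4, tolerance = 1e-6)
  expect_equal(row$p_value, 0.0214, tolerance = 1e-2)

  ident <- per_length_cpm_compare(
    dplyr::mutate(reads, length = 21L), sheet)
  r21 <- ident[ident$length == 21, ]
  expect_equal(r21$t_stat, 0)
  expect_equal(r21$p_value, 1)

  expect_error(per_length_cpm_compare(reads[reads$sample_id %in%
                                              c("s1", "s4"), ],
                                      sheet[c(1, 4), ]),
               "two samples")
})

test_that("feature-mapping proportions split multi-label weight equally", {
  ann <- annotation(
    genes = data.frame(gene_id = "g1", chrom = "chr1", start = 100L,
                       end = 400L, strand = "+"),
    exons = data.frame(gene_id = "g1", chrom = "chr1", start = 100L,
                       end = 400L, strand = "+"),
    tes = data.frame(chrom = "chr1", start = 380L, end = 600L,
                     strand = ".", te_class = "LTR/Gypsy"),
    chrom_sizes = data.frame(chrom = "chr1", length = 2000L))
  aln <- tibble::tibble(
    sample_id = "s1", read_id = c("r1", "r2"), chrom = "chr1",
    start = c(150L, 390L), end = c(171L, 411L),
    length = 21L, n_hits = 1L)
  props <- feature_mapping_proportions(aln, ann)
  get <- function(ctx) props$weight[props$context == ctx]
  expect_equal(get("exon"), 1 + 0.5)   # r1 fully exonic, r2 split exon/te
  expect_equal(get("te"), 0.5)
  expect_equal(sum(props$fraction), 1)

  all_exon <- feature_mapping_proportions(aln[1, ], ann)
  expect_equal(all_exon$fraction[all_exon$context == "exon"], 1)

  empty <- feature_mapping_proportions(aln[0, ], ann)
  expect_equal(nrow(empty), 0L)
})

test_that("classical MDS embeds a 3-4-5 triangle exactly and is equivariant", {
  d <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  d["a", "b"] <- d["b", "a"] <- 3
  d["a", "c"] <- d["c", "a"] <- 4
  d["b", "c"] <- d["c", "b"] <- 5
  emb <- mds_embed(d, dims = 2)
  coords <- as.matrix(emb[c("dim1", "dim2")])
  rec <- as.matrix(dist(coords))
  expect_lt(max(abs(rec - d)), 1e-6)

  set.seed(3)
  y <- matrix(rpois(200 * 4, 60), 200, 4,
              dimnames = list(NULL, paste0("s", 1:4)))
  y <- cbind(y, s5 = y[, "s1"])   # duplicated sample
  mc <- mds_coordinates(as_counts_tbl(y), top_k = 100)
  expect_equal(unlist(mc[mc$sample_id == "s1", -1]),
               unlist(mc[mc$sample_id == "s5", -1]), tolerance = 1e-8)

  perm <- c(3, 1, 2, 5, 4)
  mp <- mds_coordinates(as_counts_tbl(y[, perm]), top_k = 100)
  expect_equal(as.matrix(mp[match(mc$sample_id, mp$sample_id), -1]),
               as.matrix(mc[, -1]), tolerance = 1e-8, ignore_attr = TRUE)
})
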