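test_that("planted group means follow the interaction-class semantics", {
  cfg <- small_sim_config(seed = 3)
  sim <- simulate_truth(cfg)
  tr <- sim$truth
  e <- cfg$effect_log2fc

  nul <- tr[tr$truth_class == "null", ]
  expect_true(all(nul$mean_maternal == nul$mean_paternal &
                    nul$mean_maternal == nul$mean_polyA &
                    nul$mean_maternal == nul$mean_polyB))

  add <- tr[tr$truth_class == "additive", ]
  expect_equal(abs(log2(add$mean_maternal / add$mean_paternal)),
               rep(e, nrow(add)))
  expect_equal(add$mean_polyA, (add$mean_maternal + add$mean_paternal) / 2)
  expect_equal(add$mean_polyA, add$mean_polyB)

  dm <- tr[tr$truth_class == "dominant_maternal", ]
  expect_equal(dm$mean_polyA, dm$mean_maternal)
  expect_equal(dm$mean_polyB, dm$mean_maternal)
  expect_equal(abs(log2(dm$mean_paternal / dm$mean_maternal)),
               rep(e, nrow(dm)))
  expect_true(all(dm$dominant_parent == "maternal"))

  up <- tr[tr$truth_class == "transgressive_up", ]
  expect_true(all(up$mean_maternal == up$mean_paternal))
  expect_equal(log2(up$mean_polyA / up$mean_maternal), rep(e, nrow(up)))
  dn <- tr[tr$truth_class == "transgressive_down", ]
  expect_equal(log2(dn$mean_polyA / dn$mean_maternal), rep(-e, nrow(dn)))
})

test_that("planted intervals do not overlap and sit in their feature type", {
  sim <- simulate_truth(small_sim_config(seed = 11))
  tr <- dplyr::arrange(sim$truth, chrom, start)
  by_chrom <- split(tr, tr$chrom)
  for (d in by_chrom) {
    if (nrow(d) > 1) expect_true(all(d$start[-1] >= head(d$end, -1)))
  }
  ctx <- classify_context(tr, sim$annotation)
  expect_true(all(ctx$exon[tr$feature == "gene"]))
  expect_true(all(ctx$te[tr$feature == "te"]))
  expect_true(all(ctx$intergenic[tr$feature == "intergenic"]))
})

test_that("a too-small genome is rejected with the required minimum", {
  expect_error(simulate_truth(sim_config(seed = 1, n_chroms = 1L,
                                         chrom_len = 5000L)),
               "too small")
})

test_that("the generator is byte-deterministic under a fixed seed", {
  cfg <- small_sim_config(seed = 5)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$truth, b$truth)
  expect_identical(a$samples, b$samples)
  expect_identical(a$counts, b$counts)
  expect_identical(a$alignments, b$alignments)
  c <- simulate_truth(small_sim_config(seed = 6))
  expect_false(identical(a$truth$truth_class, c$truth$truth_class))
})

test_that("simulated counts have Poisson/NB moments", {
  n <- 10000
  truth <- tibble::tibble(region_id = sprintf("t%05d", seq_len(n)),
                          mean_maternal = 10, mean_paternal = 10,
                          mean_polyA = 10, mean_polyB = 10)
  sheet <- tibble::tibble(sample_id = "m1", role = "maternal",
                          lib_size = 1e4)
  cfg <- small_sim_config(seed = 2, dispersion = 0)
  cfg$lib_size_mean <- 1e4
  y <- as_count_matrix(simulate_counts(truth, sheet, cfg))
  expect_lt(abs(mean(y) - 10), 0.3)   # ~3 sigma of the mean at n = 1e4

  truth$mean_maternal <- 100
  cfg2 <- small_sim_config(seed = 2, dispersion = 0.1)
  cfg2$lib_size_mean <- 1e4
  y2 <- as_count_matrix(simulate_counts(truth, sheet, cfg2))
  expect_lt(abs(stats::var(as.numeric(y2)) - 1100), 110)  # m + phi m^2

  truth$mean_maternal <- 0
  y0 <- as_count_matrix(simulate_counts(truth, sheet, cfg2))
  expect_true(all(y0 == 0))
})

test_that("emitted alignments conserve fractional weight per region and sample", {
  cfg <- small_sim_config(seed = 4, multimap_prob = 0)
  sim <- simulate_dataset(cfg)
  expect_true(all(sim$alignments$n_hits == 1))
  got <- sim$alignments |>
    dplyr::inner_join(sim$truth[c("region_id", "chrom", "start", "end")] |>
                        dplyr::rename(r_start = start, r_end = end),
                      by = "chrom", relationship = "many-to-many") |>
    dplyr::filter(start >= r_start, end <= r_end) |>
    dplyr::count(region_id, sample_id)
  m <- as_count_matrix(sim$counts)
  for (i in seq_len(nrow(got))) {
    expect_equal(got$n[i], m[got$region_id[i], got$sample_id[i]])
  }
  expect_equal(sum(got$n), sum(m))   # every read placed inside its region

  # multi-mapped reads: k records share a read_id and weight sums to 1
  cfg2 <- small_sim_config(seed = 4, multimap_prob = 0.3)
  sim2 <- simulate_dataset(cfg2)
  per_read <- sim2$alignments |>
    dplyr::group_by(sample_id, read_id) |>
    dplyr::summarise(n_rec = dplyr::n(), w = sum(1 / n_hits),
                     k = dplyr::first(n_hits), .groups = "drop")
  expect_true(all(per_read$n_rec == per_read$k))
  expect_equal(per_read$w, rep(1, nrow(per_read)))
  expect_true(all(sim2$alignments$n_hits <= cfg2$max_hits))
})

test_that("24 nt reads avoid non-TE regions at te_frac_24nt = 1", {
  cfg <- small_sim_config(seed = 8, te_frac_24nt = 1, multimap_prob = 0)
  sim <- simulate_dataset(cfg)
  non_te <- sim$truth$region_id[sim$truth$feature != "te"]
  in_non_te <- sim$alignments |>
    dplyr::inner_join(sim$truth[sim$truth$region_id %in% non_te,
                                c("chrom", "start", "end")] |>
                        dplyr::rename(r_start = start, r_end = end),
                      by = "chrom", relationship = "many-to-many") |>
    dplyr::filter(start >= r_start, end <= r_end)
  expect_true(nrow(in_non_te) > 0)
  expect_true(all(in_non_te$length < 24))
})

test_that("read-length fractions match the configured mixture", {
  cfg <- sim_config(seed = 12, n_chroms = 1L, chrom_len = 120000L,
                    n_genes = 25L, n_tes = 25L, n_intergenic = 14L,
                    group_sizes = c(maternal = 2L, paternal = 2L,
                                    polyA = 2L, polyB = 2L),
                    lib_size_mean = 2e4, base_mean_log2 = 8,
                    te_frac_24nt = 0, multimap_prob = 0)
  sim <- simulate_dataset(cfg)
  n <- nrow(sim$alignments)
  expect_gt(n, 1e5)
  frac <- table(factor(sim$alignments$length, 20:24)) / n
  p <- cfg$len_probs
  expect_true(all(abs(frac - p) <= 3 * sqrt(p * (1 - p) / n)))
})
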