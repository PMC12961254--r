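test_that("CPM scales by library size and sums to one million", {
  y <- matrix(c(1, 0, 10, 90), ncol = 2,
              dimnames = list(NULL, c("s1", "s2")))
  counts <- as_counts_tbl(y)
  cp <- as_count_matrix(cpm(counts, lib_sizes = c(s1 = 1e6, s2 = 100)))
  expect_equal(cp[1, "s1"], 1)
  expect_equal(cp[2, "s1"], 0)
  expect_equal(unname(cp[, "s2"]), c(1e5, 9e5))
  expect_equal(sum(cp[, "s2"]), 1e6)
  expect_error(cpm(counts, lib_sizes = c(s1 = 0, s2 = 100)), "positive")
})

test_that("the CPM filter applies max(min_samples, ceil(frac * n)) within a group", {
  sheet <- two_group_sheet(4, 12, roles = c("g4", "g12"))
  lib <- rep(1e6, 16); names(lib) <- sheet$sample_id
  mk <- function(pass4, pass12) {
    y <- matrix(0, 1, 16, dimnames = list(NULL, sheet$sample_id))
    y[1, seq_len(pass4)] <- 1            # CPM 1 at lib 1e6
    y[1, 4 + seq_len(pass12)] <- 1
    as_counts_tbl(y, "r1")
  }
  keep <- function(cnt, groups) {
    nrow(filter_regions(cnt, sheet, groups = groups, lib_sizes = lib))
  }
  # 1/4 passing: max(2, ceil(1)) = 2 not met
  expect_equal(keep(mk(1, 0), "g4"), 0L)
  # 2/4 passing: both floors met
  expect_equal(keep(mk(2, 0), "g4"), 1L)
  # 3/12 passing: max(2, ceil(3)) = 3 met
  expect_equal(keep(mk(0, 3), "g12"), 1L)
  expect_equal(keep(mk(0, 2), "g12"), 0L)
  # retained if ANY group in play passes
  expect_equal(keep(mk(2, 0), c("g4", "g12")), 1L)
  expect_error(keep(mk(1, 1), "missing"), "empty group")
})

test_that("TMM factors are 1 for identical or purely rescaled libraries", {
  set.seed(2)
  base <- rpois(200, 50) + 1
  y <- cbind(s1 = base, s2 = base)
  f <- tmm_factors(as_counts_tbl(y))
  expect_equal(f$norm_factor, c(1, 1), tolerance = 1e-9)

  y2 <- cbind(s1 = base, s2 = 2 * base)   # scaling absorbed by library size
  f2 <- tmm_factors(as_counts_tbl(y2))
  expect_equal(f2$norm_factor, c(1, 1), tolerance = 1e-6)
  expect_equal(exp(mean(log(f2$norm_factor))), 1, tolerance = 1e-9)
})

test_that("TMM matches a hand-computed trimmed weighted mean on a toy matrix", {
  # 6 regions, one inflated in sample B; spreadsheet-style scalar oracle
  y <- cbind(A = c(100, 200, 300, 400, 500, 1000),
             B = c(110, 190, 310, 390, 520, 5000))
  ls <- colSums(y)
  uq <- c(quantile(y[, 1], .75) / ls[1], quantile(y[, 2], .75) / ls[2])
  ref <- which.min(abs(uq - mean(uq)))   # reference column
  s <- setdiff(1:2, ref)
  M <- A <- w <- numeric(6)
  for (r in 1:6) {
    ps <- y[r, s] / ls[s]; pr <- y[r, ref] / ls[ref]
    M[r] <- log2(ps / pr)
    A[r] <- 0.5 * log2(ps * pr)
    w[r] <- (ls[s] - y[r, s]) / (ls[s] * y[r, s]) +
      (ls[ref] - y[r, ref]) / (ls[ref] * y[r, ref])
  }
  loM <- floor(6 * 0.3) + 1; hiM <- 6 + 1 - loM
  loA <- floor(6 * 0.05) + 1; hiA <- 6 + 1 - loA
  keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
  f_s <- 2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
  expected <- c(1, 1); expected[s] <- f_s
  expected <- expected / exp(mean(log(expected)))

  got <- tmm_factors(as_counts_tbl(y))$norm_factor
  expect_equal(got, expected, tolerance = 1e-9)
})

test_that("TMM agrees with edgeR's calcNormFactors and is permutation-equivariant", {
  skip_if_not_installed("edgeR")
  set.seed(31)
  y <- matrix(rpois(300 * 4, exp(rnorm(300 * 4, log(60), 1))), 300, 4,
              dimnames = list(NULL, paste0("s", 1:4)))
  ours <- tmm_factors(as_counts_tbl(y))$norm_factor
  theirs <- edgeR::calcNormFactors(y, method = "TMM")
  expect_equal(ours, unname(theirs), tolerance = 1e-8)

  perm <- c(3, 1, 4, 2)
  ours_perm <- tmm_factors(as_counts_tbl(y[, perm]))$norm_factor
  expect_equal(ours_perm, ours[perm], tolerance = 1e-12)
})

test_that("dispersion estimation recovers Poisson and NB truth at small scale", {
  set.seed(7)
  sheet <- two_group_sheet(4, 4)
  mu <- exp(rnorm(800, log(80), 0.6))
  yp <- matrix(rpois(800 * 8, rep(mu, 8)), 800, 8,
               dimnames = list(NULL, sheet$sample_id))
  dp <- estimate_dispersion(as_counts_tbl(yp), sheet, groups = c("A", "B"))
  expect_lte(dp$common_phi, 0.01)

  ynb <- matrix(rnbinom(800 * 8, mu = rep(mu, 8), size = 10), 800, 8,
                dimnames = list(NULL, sheet$sample_id))
  dnb <- estimate_dispersion(as_counts_tbl(ynb), sheet, groups = c("A", "B"))
  expect_gt(dnb$common_phi, 0.07)
  expect_lt(dnb$common_phi, 0.13)

  one <- as_counts_tbl(matrix(5, 1, 8, dimnames = list(NULL, sheet$sample_id)))
  expect_lte(estimate_dispersion(one, sheet)$common_phi, 1e-4)

  zero <- as_counts_tbl(matrix(0, 3, 8, dimnames = list(NULL, sheet$sample_id)))
  expect_warning(dz <- estimate_dispersion(zero, sheet), "zero")
  expect_equal(dz$common_phi, 0)
})

test_that("nb_test handles identical groups, recovers logFC, and respects orientation", {
  sheet <- two_group_sheet(3, 3)
  y <- matrix(rep(c(10, 20, 40), each = 6), 3, 6, byrow = TRUE,
              dimnames = list(NULL, sheet$sample_id))
  res <- nb_test(as_counts_tbl(y), sheet, c("A", "B"), dispersion = 0.05,
                 lib_sizes = setNames(rep(1e4, 6), sheet$sample_id))
  expect_equal(res$log_fc, rep(0, 3))
  expect_equal(res$p_value, rep(1, 3))

  # group A CPM exactly 4x group B (after priors): logFC = 2
  y2 <- matrix(c(rep(4000, 3), rep(1000, 3)), 1, 6,
               dimnames = list(NULL, sheet$sample_id))
  lib <- setNames(rep(1e6, 6), sheet$sample_id)
  res2 <- nb_test(as_counts_tbl(y2, "r1"), sheet, c("A", "B"),
                  dispersion = 0.05, lib_sizes = lib, prior_count = 0)
  expect_equal(res2$log_fc, 2)

  # raising group A counts raises the log fold change
  y3 <- y2; y3[1, 1:3] <- y3[1, 1:3] * 2
  res3 <- nb_test(as_counts_tbl(y3, "r1"), sheet, c("A", "B"),
                  dispersion = 0.05, lib_sizes = lib, prior_count = 0)
  expect_gt(res3$log_fc, res2$log_fc)
})

test_that("bh_adjust matches the brute-force step-up exactly", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.123), 0.123)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(17)
  for (rep in 1:200) {
    p <- runif(sample(1:60, 1))^sample(1:3, 1)
    expect_identical(bh_adjust(p), oracle_bh(p))
  }
})

test_that("DT calls use a strict FDR threshold", {
  res <- tibble::tibble(region_id = c("a", "b", "c"),
                        fdr = c(0.049, 0.05, 0.051))
  expect_equal(call_dt(res, 0.05)$dt, c(TRUE, FALSE, FALSE))
  empty <- call_dt(res[0, ], 0.05)
  expect_equal(nrow(empty), 0L)
})

test_that("tagwise moderation stays near the common dispersion under a common truth", {
  set.seed(5)
  sheet <- two_group_sheet(4, 4)
  y <- matrix(rnbinom(400 * 8, mu = 60, size = 1 / 0.1), 400, 8,
              dimnames = list(NULL, sheet$sample_id))
  d <- estimate_dispersion(as_counts_tbl(y), sheet, tagwise = TRUE)
  expect_length(d$tagwise_phi, 400)
  expect_lt(abs(log(median(d$tagwise_phi) / d$common_phi)), log(2.5))
})
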