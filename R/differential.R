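#' Counts per million
#'
#' `cpm[r, s] = counts[r, s] / lib_size[s] * 1e6`. With library sizes equal to
#' column sums, every column of the result sums to one million.
#'
#' @param counts Wide count tibble or matrix (regions x samples).
#' @param lib_sizes Optional named library sizes; defaults to column sums.
#' @return Same shape as the input, CPM-scaled.
#' @export
cpm <- function(counts, lib_sizes = NULL) {
  m <- as_count_matrix(counts)
  ls <- resolve_lib_sizes(counts, lib_sizes)
  out <- sweep(m, 2, ls, "/") * 1e6
  if (is.matrix(counts)) return(out)
  bind_cols(counts[intersect(names(counts), c("region_id", "chrom", "start", "end"))],
            as_tibble(out))
}

#' Filter regions on CPM support within groups
#'
#' A region is retained when, in at least one group under analysis, the number
#' of samples with `CPM >= cpm_min` reaches
#' `max(min_samples, ceiling(group_frac * n_group))`.
#'
#' @param counts Wide count tibble.
#' @param samples Sample sheet (`sample_id`, `role`).
#' @param groups Roles participating in the analysis (default: all roles in
#'   `samples` that have count columns).
#' @param cpm_min CPM threshold (default 1).
#' @param group_frac Fraction of a group's samples that must pass (default
#'   0.25).
#' @param min_samples Absolute floor on passing samples (default 2).
#' @param lib_sizes Optional library sizes for the CPM computation.
#' @return The filtered count tibble (rows = retained regions).
#' @export
filter_regions <- function(counts, samples, groups = NULL, cpm_min = 1,
                           group_frac = 0.25, min_samples = 2,
                           lib_sizes = NULL) {
  assert_cols(samples, c("sample_id", "role"), "samples")
  sc <- sample_cols_of(counts)
  samples <- filter(samples, .data$sample_id %in% sc)
  groups <- groups %||% unique(samples$role)
  if (!all(groups %in% samples$role)) {
    abort(sprintf("empty group(s): %s",
                  paste(setdiff(groups, samples$role), collapse = ", ")))
  }
  cp <- as_count_matrix(cpm(counts, lib_sizes))
  keep <- rep(FALSE, nrow(cp))
  for (g in groups) {
    ids <- samples$sample_id[samples$role == g]
    need <- max(min_samples, ceiling(group_frac * length(ids)))
    keep <- keep | rowSums(cp[, ids, drop = FALSE] >= cpm_min) >= need
  }
  counts[keep, , drop = FALSE]
}

#' TMM normalization factors
#'
#' Weighted trimmed mean of M-values. The reference sample is the one whose
#' upper-quartile CPM is closest to the mean upper-quartile. For each sample,
#' over regions positive in both sample and reference, the log2 ratio (M) and
#' mean log2 abundance (A) of library-size-scaled counts are computed; the
#' top/bottom `trim_m` fraction by M and `trim_a` by A are dropped, and the
#' factor is two to the precision-weighted mean of the remaining M values
#' (weights from the inverse binomial variance approximation). Factors are
#' rescaled to geometric mean 1.
#'
#' @param counts Wide count tibble or matrix.
#' @param lib_sizes Optional library sizes (default: column sums).
#' @param trim_m Two-sided trim fraction on M (default 0.30).
#' @param trim_a Two-sided trim fraction on A (default 0.05).
#' @return Tibble: `sample_id`, `lib_size`, `norm_factor`, `eff_lib_size`.
#' @export
tmm_factors <- function(counts, lib_sizes = NULL, trim_m = 0.30, trim_a = 0.05) {
  m <- as_count_matrix(counts)
  if (ncol(m) < 2) abort("TMM needs at least two samples")
  if (all(m == 0)) abort("TMM needs some positive counts")
  ls <- resolve_lib_sizes(counts, lib_sizes)

  uq <- apply(m, 2, function(y) quantile(y, 0.75)) / ls
  ref <- which.min(abs(uq - mean(uq)))

  one_factor <- function(s) {
    if (s == ref) return(1)
    ys <- m[, s]; yr <- m[, ref]
    ok <- ys > 0 & yr > 0
    if (!any(ok)) {
      warn(sprintf("no regions positive in both '%s' and the reference; factor set to 1",
                   colnames(m)[s]))
      return(1)
    }
    ys <- ys[ok]; yr <- yr[ok]
    ns <- ls[s]; nr <- ls[ref]
    M <- log2((ys / ns) / (yr / nr))
    A <- 0.5 * log2((ys / ns) * (yr / nr))
    w <- (ns - ys) / (ns * ys) + (nr - yr) / (nr * yr)
    n <- length(M)
    loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
    rM <- rank(M, ties.method = "first"); rA <- rank(A, ties.method = "first")
    keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    if (!any(keep)) return(1)
    f <- 2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
    if (!is.finite(f) || f <= 0) 1 else f
  }
  f <- vapply(seq_len(ncol(m)), one_factor, numeric(1))
  f <- f / exp(mean(log(f)))   # geometric mean 1
  tibble(sample_id = colnames(m), lib_size = unname(ls),
         norm_factor = f, eff_lib_size = unname(ls) * f)
}

# ---- NB likelihood machinery ------------------------------------------------

# Fit a common rate per region for one group of samples, vectorized over
# regions. y: R x S rounded counts; e: effective library sizes; phi: scalar or
# per-region vector. Returns fitted mu, per-region log-likelihood and the
# observed information of the log-rate (for the Cox-Reid adjustment).
nb_fit_group <- function(y, e, phi) {
  R <- nrow(y)
  sy <- rowSums(y)
  m <- sy / sum(e)
  pos <- sy > 0
  if (length(phi) == 1) phi <- rep(phi, R)
  mu <- outer(m, e)
  if (any(pos) && any(phi > 0)) {
    t <- log(pmax(m, 1e-12))
    for (it in 1:80) {
      mu <- outer(exp(t), e)
      grad <- rowSums((y - mu) / (1 + phi * mu))
      info <- rowSums(mu / (1 + phi * mu))
      step <- ifelse(pos & info > 0, grad / pmax(info, 1e-12), 0)
      step <- pmin(pmax(step, -4), 4)
      t <- t + step
      if (max(abs(step)) < 1e-10) break
    }
    mu <- outer(exp(t), e)
    mu[!pos, ] <- 0
  }
  ll <- numeric(R)
  info <- rowSums(mu / (1 + phi * mu))
  if (any(pos)) {
    mup <- pmax(mu, 1e-300)
    llm <- matrix(0, R, ncol(y))
    nbr <- pos & phi > 0
    por <- pos & phi == 0
    if (any(nbr)) {
      llm[nbr, ] <- dnbinom(y[nbr, , drop = FALSE],
                            size = 1 / phi[nbr],
                            mu = mup[nbr, , drop = FALSE], log = TRUE)
    }
    if (any(por)) {
      llm[por, ] <- stats::dpois(y[por, , drop = FALSE],
                                 mup[por, , drop = FALSE], log = TRUE)
    }
    ll[pos] <- rowSums(llm[pos, , drop = FALSE])
  }
  list(mu = mu, loglik = ll, info = info, rate = rowSums(y) / sum(e))
}

# Cox-Reid adjusted profile log-likelihood summed over regions, given a
# grouping (list of column-index vectors).
apl_total <- function(y, e, group_idx, phi) {
  tot <- 0
  per <- numeric(nrow(y))
  for (idx in group_idx) {
    f <- nb_fit_group(y[, idx, drop = FALSE], e[idx], phi)
    adj <- ifelse(f$info > 0, 0.5 * log(f$info), 0)
    per <- per + f$loglik - adj
  }
  per
}

#' Estimate the negative-binomial dispersion
#'
#' Estimates a common dispersion phi shared by all regions by maximizing the
#' Cox-Reid adjusted profile likelihood (per-region group means profiled out,
#' with offsets for effective library sizes) via 1-D search on
#' `[1e-6, 10]`. Optionally computes per-region (tagwise) dispersions by
#' weighted-likelihood moderation toward the common value.
#'
#' @param counts Wide count tibble (fractional counts are rounded for the
#'   likelihood).
#' @param samples Sample sheet (`sample_id`, `role`).
#' @param groups Roles defining the mean model (default: all roles present).
#' @param norm_factors Optional [tmm_factors()] tibble; effective library
#'   sizes are used as offsets.
#' @param lib_sizes Optional raw library sizes (default: column sums).
#' @param tagwise Also compute moderated per-region dispersions.
#' @param prior_df Prior weight (in units of per-region information) pulling
#'   tagwise estimates toward the common value (default 10).
#' @return Object of class `smrna_dispersion` with elements `common_phi`,
#'   `tagwise_phi` (or `NULL`), `n_regions`, `n_samples`.
#' @export
estimate_dispersion <- function(counts, samples, groups = NULL,
                                norm_factors = NULL, lib_sizes = NULL,
                                tagwise = FALSE, prior_df = 10) {
  assert_cols(samples, c("sample_id", "role"), "samples")
  sc <- sample_cols_of(counts)
  samples <- filter(samples, .data$sample_id %in% sc)
  groups <- groups %||% unique(samples$role)
  samples <- filter(samples, .data$role %in% groups)
  if (any(table(factor(samples$role, levels = groups)) == 0)) {
    abort("every group must contain at least one sample")
  }
  y <- round(as_count_matrix(counts)[, samples$sample_id, drop = FALSE])
  if (all(y == 0)) {
    warn("all counts are zero; dispersion set to 0")
    return(new_dispersion(0, NULL, nrow(y), ncol(y)))
  }
  e <- effective_lib_sizes(counts, samples$sample_id, norm_factors, lib_sizes)
  group_idx <- lapply(groups, function(g) which(samples$role == g))

  obj <- function(lp) -sum(apl_total(y, e, group_idx, exp(lp)))
  opt <- optimize(obj, interval = log(c(1e-6, 10)), tol = 1e-4)
  common <- exp(opt$minimum)
  # a boundary solution at the lower end means "no overdispersion"
  if (common < 2e-6 && obj(log(1e-6)) <= opt$objective + 1e-8) common <- 0

  tag <- NULL
  if (tagwise) {
    grid <- pmax(common, 1e-4) * 4^seq(-3, 3, length.out = 25)
    grid <- pmin(pmax(grid, 1e-6), 10)
    apl_mat <- sapply(grid, function(p) apl_total(y, e, group_idx, p))
    shared <- colMeans(apl_mat)
    df_res <- max(ncol(y) - length(group_idx), 1)
    w <- prior_df / df_res
    score <- apl_mat + matrix(w * shared, nrow(y), length(grid), byrow = TRUE)
    tag <- grid[max.col(score, ties.method = "first")]
  }
  new_dispersion(common, tag, nrow(y), ncol(y))
}

new_dispersion <- function(common, tagwise, n_regions, n_samples) {
  structure(list(common_phi = common, tagwise_phi = tagwise,
                 n_regions = n_regions, n_samples = n_samples),
            class = "smrna_dispersion")
}

#' @export
print.smrna_dispersion <- function(x, ...) {
  cat(sprintf("<smrna_dispersion> common phi = %.4g (%d regions, %d samples)%s\n",
              x$common_phi, x$n_regions, x$n_samples,
              if (!is.null(x$tagwise_phi)) "; tagwise estimates present" else ""))
  invisible(x)
}

effective_lib_sizes <- function(counts, sample_ids, norm_factors = NULL,
                                lib_sizes = NULL) {
  ls <- resolve_lib_sizes(counts, lib_sizes)[sample_ids]
  if (!is.null(norm_factors)) {
    nf <- setNames(norm_factors$norm_factor, norm_factors$sample_id)[sample_ids]
    if (anyNA(nf)) abort("`norm_factors` does not cover every sample")
    ls <- ls * nf
  }
  ls
}

#' Per-region negative-binomial differential test
#'
#' For each region, a likelihood-ratio test of the two-group NB GLM (separate
#' means for the two roles, offsets = log effective library sizes, dispersion
#' fixed from `dispersion`) against the pooled-mean model; p-values from the
#' chi-square distribution with 1 df, corrected with [bh_adjust()]. The log
#' fold change is `log2` of prior-count-augmented group mean CPMs, oriented
#' `log2(A/B)` for `contrast = c(A, B)`.
#'
#' @param counts Wide count tibble (typically [filter_regions()] output).
#' @param samples Sample sheet (`sample_id`, `role`).
#' @param contrast Character vector `c(roleA, roleB)`.
#' @param dispersion An [estimate_dispersion()] object (tagwise values are
#'   used when present), or a single numeric phi.
#' @param norm_factors Optional [tmm_factors()] tibble.
#' @param lib_sizes Optional raw library sizes.
#' @param prior_count Prior count added to each group-mean CPM before the log
#'   (default 0.5), keeping the log fold change finite.
#' @param alpha FDR threshold for the `dt` flag (default 0.05; strict `<`).
#' @return Tibble of class `smrna_dt`: `region_id`, `log_fc`,
#'   `mean_log2_cpm`, `p_value`, `fdr`, `dt`.
#' @export
nb_test <- function(counts, samples, contrast, dispersion,
                    norm_factors = NULL, lib_sizes = NULL,
                    prior_count = 0.5, alpha = 0.05) {
  if (length(contrast) != 2) abort("`contrast` must name exactly two roles")
  assert_cols(samples, c("sample_id", "role"), "samples")
  sc <- sample_cols_of(counts)
  samples <- filter(samples, .data$sample_id %in% sc,
                    .data$role %in% contrast)
  if (!all(contrast %in% samples$role)) abort("both contrast roles must have samples")
  ids_a <- samples$sample_id[samples$role == contrast[1]]
  ids_b <- samples$sample_id[samples$role == contrast[2]]

  mraw <- as_count_matrix(counts)
  y <- round(mraw[, c(ids_a, ids_b), drop = FALSE])
  e <- effective_lib_sizes(counts, c(ids_a, ids_b), norm_factors, lib_sizes)
  if (sum(e[ids_a]) <= 0 || sum(e[ids_b]) <= 0) {
    abort("a contrast group has zero effective library size")
  }
  phi <- if (inherits(dispersion, "smrna_dispersion")) {
    dispersion$tagwise_phi %||% dispersion$common_phi
  } else as.numeric(dispersion)

  fa <- nb_fit_group(y[, ids_a, drop = FALSE], e[ids_a], phi)
  fb <- nb_fit_group(y[, ids_b, drop = FALSE], e[ids_b], phi)
  fp <- nb_fit_group(y, e, phi)
  lrt <- pmax(2 * (fa$loglik + fb$loglik - fp$loglik), 0)
  p <- pchisq(lrt, df = 1, lower.tail = FALSE)

  pc <- prior_count * 1e6 / mean(e)
  cpm_a <- fa$rate * 1e6
  cpm_b <- fb$rate * 1e6
  res <- tibble(
    region_id = rownames(y) %||% as.character(seq_len(nrow(y))),
    log_fc = unname(log2((cpm_a + pc) / (cpm_b + pc))),
    mean_log2_cpm = unname(log2(fp$rate * 1e6 + pc)),
    p_value = unname(p),
    fdr = unname(bh_adjust(p))
  )
  res$dt <- res$fdr < alpha
  structure(res, class = c("smrna_dt", class(res)),
            contrast = contrast, alpha = alpha,
            phi = if (length(phi) == 1) phi else NULL)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: `fdr_i = min over j >= rank(i) of
#' (p_(j) * m / j)`, capped at 1.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Vector of FDR-adjusted values.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Flag differentially targeted (DT) regions
#'
#' A region is DT when `fdr < alpha` (strict inequality).
#'
#' @param results A [nb_test()] result tibble (needs an `fdr` column).
#' @param alpha FDR threshold (default 0.05).
#' @return The input with an updated logical `dt` column.
#' @export
call_dt <- function(results, alpha = 0.05) {
  assert_cols(results, "fdr", "results")
  results$dt <- results$fdr < alpha
  attr(results, "alpha") <- alpha
  results
}
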