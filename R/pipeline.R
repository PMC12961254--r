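#' Pipeline configuration
#'
#' Collects every tunable constant of the end-to-end analysis: 100 bp
#' windows, a 10-read retention threshold, 1000 bp promoters, the CPM filter
#' (CPM >= 1 in at least 25% of a group's samples and two samples), FDR 0.05,
#' the three read-length sets (genic 20-24 nt; TE analyses separately on
#' 20-23 nt and 24 nt) and the five two-group contrasts.
#'
#' @param seed Integer seed driving the simulation stage.
#' @param window_size,min_reads Region-discovery parameters (bp, reads).
#' @param promoter_len Promoter window (bp upstream of a gene model).
#' @param cpm_min,group_frac,min_samples CPM filter rule.
#' @param alpha FDR threshold for DT calls.
#' @param length_sets Named list of read-length vectors analysed separately.
#' @param contrasts List of two-role character vectors.
#' @param sim A [sim_config()] for the simulation stage (its seed is forced
#'   to `seed`).
#' @param paths Optional named list of input paths (`alignments`,
#'   `annotation`, `samples`) to run on pre-existing data instead of
#'   simulating.
#' @return List of class `smrna_pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            window_size = 100, min_reads = 10,
                            promoter_len = 1000,
                            cpm_min = 1, group_frac = 0.25, min_samples = 2,
                            alpha = 0.05,
                            length_sets = list(genic = 20:24,
                                               te_short = 20:23,
                                               te_24 = 24L),
                            contrasts = list(c("polyA", "polyB"),
                                             c("polyA", "maternal"),
                                             c("polyA", "paternal"),
                                             c("polyB", "maternal"),
                                             c("polyB", "paternal")),
                            sim = NULL,
                            paths = NULL) {
  sim <- sim %||% sim_config(seed = seed)
  sim$seed <- as.integer(seed)
  cfg <- list(seed = as.integer(seed), window_size = window_size,
              min_reads = min_reads, promoter_len = promoter_len,
              cpm_min = cpm_min, group_frac = group_frac,
              min_samples = min_samples, alpha = alpha,
              length_sets = length_sets, contrasts = contrasts,
              sim = sim, paths = paths)
  if (any(c(window_size, min_reads, promoter_len, cpm_min, group_frac,
            min_samples, alpha) <= 0)) {
    abort("all pipeline thresholds must be positive")
  }
  roles <- c("maternal", "paternal", "polyA", "polyB")
  for (ct in contrasts) {
    if (length(ct) != 2 || !all(ct %in% roles)) {
      abort(sprintf("contrast '%s' does not reference two known roles",
                    paste(ct, collapse = ":")))
    }
  }
  structure(cfg, class = "smrna_pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; keys under
#' `sim:` are passed to [sim_config()].
#'
#' @param path Path to a YAML file.
#' @return A [pipeline_config()] object.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  if (!is.null(sim_args$group_sizes)) sim_args$group_sizes <- unlist(sim_args$group_sizes)
  if (!is.null(sim_args$class_probs)) sim_args$class_probs <- unlist(sim_args$class_probs)
  if (!is.null(sim_args$len_probs)) sim_args$len_probs <- unlist(sim_args$len_probs)
  sim <- do.call(sim_config, sim_args)
  args <- y[setdiff(names(y), "sim")]
  if (!is.null(args$contrasts)) args$contrasts <- lapply(args$contrasts, unlist)
  if (!is.null(args$length_sets)) {
    args$length_sets <- lapply(args$length_sets, function(v) {
      v <- unlist(v); if (length(v) == 2 && v[2] > v[1] + 1) seq(v[1], v[2]) else v
    })
  }
  do.call(pipeline_config, c(args, list(sim = sim)))
}

polyploids_in <- function(contrasts) {
  ct <- vapply(contrasts, paste, character(1), collapse = ":")
  pp <- unique(unlist(lapply(contrasts, function(x) intersect(x, c("polyA", "polyB")))))
  keep <- vapply(pp, function(p) {
    all(c(paste(p, "maternal", sep = ":"), paste(p, "paternal", sep = ":")) %in% ct)
  }, logical(1))
  pp[keep]
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> discover -> count -> filter/normalize/test
#' per length set and contrast -> classify interactions -> overlap tests ->
#' summaries, writing every table as TSV, the region set as GFF3, a markdown
#' report and a run manifest under `out_dir`.
#'
#' @param config A [pipeline_config()] object.
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress per-stage log lines.
#' @return (Invisibly) a list with all in-memory results plus the manifest.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "smrna_pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  stages <- list()
  say <- function(fmt, ...) if (!quiet) inform(sprintf(fmt, ...))
  note_stage <- function(name, files, rows) {
    stages[[length(stages) + 1]] <<- tibble(
      stage = name, output = paste(basename(files), collapse = ","),
      n_rows = rows, seconds = round(proc.time()[["elapsed"]] - t0, 2))
  }

  # stage 1: inputs -----------------------------------------------------------
  if (is.null(config$paths)) {
    sim <- simulate_dataset(config$sim, dir = out_dir)
    ann <- sim$annotation; samples <- sim$samples
    alignments <- sim$alignments; truth <- sim$truth
    say("simulate: %d alignment records, %d samples, %d truth regions",
        nrow(alignments), nrow(samples), nrow(truth))
  } else {
    ann <- read_gff3(config$paths$annotation)
    samples <- readr::read_tsv(config$paths$samples, col_types = readr::cols(),
                               progress = FALSE)
    alignments <- read_alignments(config$paths$alignments)
    truth <- NULL
    say("load: %d alignment records, %d samples", nrow(alignments), nrow(samples))
  }
  note_stage("inputs", "alignments.tsv", nrow(alignments))

  # stage 2: region discovery (all 20-24 nt reads) ----------------------------
  regions <- discover_regions(alignments, ann$chrom_sizes,
                              window_size = config$window_size,
                              min_reads = config$min_reads, lengths = 20:24)
  write_regions_gff3(regions[c("chrom", "start", "end")],
                     file.path(out_dir, "target_regions.gff3"))
  say("discover: %d target regions", nrow(regions))
  note_stage("discover", "target_regions.gff3", nrow(regions))

  # stage 3: per-length-set counting and testing ------------------------------
  tests <- list(); counts_by_set <- list()
  for (set_name in names(config$length_sets)) {
    lens <- config$length_sets[[set_name]]
    counts <- count_regions(alignments, regions, samples, lengths = lens)
    counts_by_set[[set_name]] <- counts
    readr::write_tsv(counts, file.path(out_dir, sprintf("counts_%s.tsv", set_name)),
                     progress = FALSE)
    for (ct in config$contrasts) {
      key <- sprintf("%s.%s_vs_%s", set_name, ct[1], ct[2])
      filt <- filter_regions(counts, samples, groups = ct,
                             cpm_min = config$cpm_min,
                             group_frac = config$group_frac,
                             min_samples = config$min_samples)
      if (nrow(filt) < 2) {
        say("test %s: <2 regions pass the CPM filter; skipped", key)
        next
      }
      nf <- tmm_factors(filt)
      disp <- estimate_dispersion(filt, samples, groups = ct, norm_factors = nf)
      res <- nb_test(filt, samples, contrast = ct, dispersion = disp,
                     norm_factors = nf, alpha = config$alpha)
      tests[[key]] <- res
      readr::write_tsv(res, file.path(out_dir, sprintf("dt_%s.tsv", key)),
                       progress = FALSE)
      say("test %s: %d/%d regions pass filter, %d DT (phi=%.3g)",
          key, nrow(filt), nrow(counts), sum(res$dt), disp$common_phi)
    }
  }
  note_stage("test", sprintf("dt_%s.tsv", names(tests)), length(tests))

  # stage 4: interaction classification ---------------------------------------
  interactions <- list()
  for (set_name in names(config$length_sets)) {
    for (p in polyploids_in(config$contrasts)) {
      km <- sprintf("%s.%s_vs_maternal", set_name, p)
      kp <- sprintf("%s.%s_vs_paternal", set_name, p)
      if (is.null(tests[[km]]) || is.null(tests[[kp]])) next
      cls <- classify_interactions(tests[[km]], tests[[kp]],
                                   alpha = config$alpha, polyploid = p)
      interactions[[sprintf("%s.%s", set_name, p)]] <-
        mutate(cls, length_set = set_name, .before = 1)
    }
  }
  interactions_tbl <- bind_rows(interactions)
  readr::write_tsv(interactions_tbl, file.path(out_dir, "interactions.tsv"),
                   progress = FALSE)
  note_stage("classify", "interactions.tsv", nrow(interactions_tbl))

  # stage 5: shared-DT overlap tests ------------------------------------------
  overlaps <- list()
  for (set_name in names(config$length_sets)) {
    ka <- sprintf("%s.polyA", set_name); kb <- sprintf("%s.polyB", set_name)
    if (is.null(interactions[[ka]]) || is.null(interactions[[kb]])) next
    ia <- interactions[[ka]]; ib <- interactions[[kb]]
    universe <- intersect(ia$region_id, ib$region_id)
    ia <- filter(ia, .data$region_id %in% universe, !.data$ambiguous)
    ib <- filter(ib, .data$region_id %in% universe, !.data$ambiguous)
    cats <- c("all_dt", setdiff(truth_classes, "null"))
    for (cat in cats) {
      ids_a <- if (cat == "all_dt") ia$region_id[ia$category != "no_change"]
               else ia$region_id[ia$category == cat]
      ids_b <- if (cat == "all_dt") ib$region_id[ib$category != "no_change"]
               else ib$region_id[ib$category == cat]
      st <- shared_dt_test(ids_a, ids_b, universe)
      overlaps[[sprintf("%s.%s", set_name, cat)]] <-
        mutate(st, length_set = set_name, category = cat, .before = 1)
    }
  }
  overlaps_tbl <- bind_rows(overlaps)
  readr::write_tsv(overlaps_tbl, file.path(out_dir, "overlap_stats.tsv"),
                   progress = FALSE)
  note_stage("overlap", "overlap_stats.tsv", nrow(overlaps_tbl))

  # stage 6: descriptive summaries --------------------------------------------
  lengths_ttest <- per_length_cpm_compare(alignments, samples)
  readr::write_tsv(lengths_ttest, file.path(out_dir, "lengths_ttest.tsv"),
                   progress = FALSE)
  feat_props <- feature_mapping_proportions(alignments, ann,
                                            config$promoter_len)
  readr::write_tsv(feat_props, file.path(out_dir, "feature_proportions.tsv"),
                   progress = FALSE)
  mds <- mds_coordinates(counts_by_set[[1]])
  readr::write_tsv(as_tibble(mds), file.path(out_dir, "mds.tsv"),
                   progress = FALSE)
  contexts <- classify_context(regions, ann, config$promoter_len)
  readr::write_tsv(contexts, file.path(out_dir, "region_contexts.tsv"),
                   progress = FALSE)
  note_stage("summarize",
             c("lengths_ttest.tsv", "feature_proportions.tsv", "mds.tsv",
               "region_contexts.tsv"),
             nrow(lengths_ttest))

  # stage 7: truth recovery + report ------------------------------------------
  recovery <- NULL
  if (!is.null(truth)) {
    recovery <- truth_recovery(interactions_tbl, regions, truth)
    readr::write_tsv(recovery$confusion, file.path(out_dir, "confusion.tsv"),
                     progress = FALSE)
  }
  write_report(file.path(out_dir, "report.md"), config, regions, tests,
               interactions_tbl, overlaps_tbl, recovery)
  note_stage("report", c("report.md", "confusion.tsv"),
             nrow(interactions_tbl))

  manifest <- bind_rows(stages)
  files <- setdiff(list.files(out_dir, full.names = TRUE),
                   file.path(out_dir, "manifest.tsv"))
  manifest <- dplyr::bind_rows(manifest)
  checks <- tibble(stage = "checksum", output = basename(files),
                   n_rows = NA_integer_, seconds = NA_real_,
                   md5 = unname(tools::md5sum(files)))
  manifest <- bind_rows(manifest, checks)
  readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"), progress = FALSE)

  invisible(list(annotation = ann, samples = samples, alignments = alignments,
                 truth = truth, regions = regions, counts = counts_by_set,
                 tests = tests, interactions = interactions_tbl,
                 overlaps = overlaps_tbl, lengths_ttest = lengths_ttest,
                 feature_proportions = feat_props, mds = mds,
                 recovery = recovery, manifest = manifest))
}

# map discovered regions back to planted truth intervals (by overlap; planted
# regions are spaced far apart, so the mapping is 1:1 where it exists) and
# tabulate planted class vs called category per polyploid
truth_recovery <- function(interactions_tbl, regions, truth) {
  ov <- GenomicRanges::findOverlaps(iv_granges(regions), iv_granges(truth))
  map <- tibble(region_id = regions$region_id[S4Vectors::queryHits(ov)],
                truth_id = truth$region_id[S4Vectors::subjectHits(ov)]) |>
    distinct(.data$region_id, .keep_all = TRUE)
  joined <- interactions_tbl |>
    inner_join(map, by = "region_id") |>
    inner_join(truth[c("region_id", "truth_class")],
               by = c("truth_id" = "region_id"))
  # confusion over the all-lengths (genic) set when present, both polyploids pooled
  first_set <- if ("genic" %in% joined$length_set) "genic" else
    sort(unique(joined$length_set))[1]
  use <- filter(joined, .data$length_set == first_set, !.data$ambiguous)
  called_levels <- c("no_change", "additive", "dominant_maternal",
                     "dominant_paternal", "transgressive_up", "transgressive_down")
  truth_levels <- c("null", setdiff(called_levels, "no_change"))
  conf <- use |>
    count(.data$polyploid,
          truth_class = factor(.data$truth_class, truth_levels),
          category = factor(.data$category, called_levels),
          .drop = FALSE) |>
    rename(n_regions = "n")
  dt_use <- filter(use, .data$category != "no_change")
  truth_equiv <- c(null = "no_change", additive = "additive",
                   dominant_maternal = "dominant_maternal",
                   dominant_paternal = "dominant_paternal",
                   transgressive_up = "transgressive_up",
                   transgressive_down = "transgressive_down")
  acc_tbl <- filter(dt_use, .data$truth_class != "null")
  accuracy <- mean(acc_tbl$category == truth_equiv[acc_tbl$truth_class])
  empirical_fdr <- mean(dt_use$truth_class == "null")
  list(confusion = conf, accuracy = accuracy, empirical_fdr = empirical_fdr,
       length_set = first_set, n_dt_called = nrow(dt_use))
}

write_report <- function(path, config, regions, tests, interactions_tbl,
                         overlaps_tbl, recovery) {
  ln <- c("# smrnaploid pipeline report", "",
          sprintf("- seed: %d", config$seed),
          sprintf("- target regions discovered: %d", nrow(regions)), "",
          "## DT tests", "")
  for (k in names(tests)) {
    ln <- c(ln, sprintf("- %s: %d regions tested, %d DT at FDR < %.2f",
                        k, nrow(tests[[k]]), sum(tests[[k]]$dt), config$alpha))
  }
  if (nrow(interactions_tbl) > 0) {
    tab <- interactions_tbl |> count(.data$length_set, .data$polyploid, .data$category)
    ln <- c(ln, "", "## Interaction categories", "")
    ln <- c(ln, sprintf("- %s / %s / %s: %d", tab$length_set, tab$polyploid,
                        tab$category, tab$n))
  }
  if (nrow(overlaps_tbl) > 0) {
    ln <- c(ln, "", "## Shared DT regions between polyploids", "")
    ln <- c(ln, sprintf("- %s %s: k=%d of m=%d,n=%d (N=%d), p=%.3g",
                        overlaps_tbl$length_set, overlaps_tbl$category,
                        overlaps_tbl$k, overlaps_tbl$m, overlaps_tbl$n,
                        overlaps_tbl$N, overlaps_tbl$p_value))
  }
  if (!is.null(recovery)) {
    ln <- c(ln, "", "## Truth recovery", "",
            sprintf("- length set: %s", recovery$length_set),
            sprintf("- DT-called regions mapped to truth: %d", recovery$n_dt_called),
            sprintf("- category accuracy on DT-called non-null regions: %.3f",
                    recovery$accuracy),
            sprintf("- empirical FDR of DT calls: %.3f", recovery$empirical_fdr))
  }
  writeLines(ln, path)
}
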