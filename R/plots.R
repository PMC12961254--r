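#' @importFrom ggplot2 ggplot aes geom_point geom_hline geom_col geom_line
#'   labs theme_minimal scale_colour_manual facet_wrap
NULL

#' MA plot of a differential-targeting result
#'
#' Mean log2 CPM against log2 fold change; DT regions highlighted, with the
#' conventional guide lines at logFC 0 and +/- 1.5.
#'
#' @param object A [nb_test()] result.
#' @param guide_fc Positions of the dotted guide lines (default 1.5).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot smrna_dt
#' @export
autoplot.smrna_dt <- function(object, guide_fc = 1.5, ...) {
  ct <- attr(object, "contrast") %||% c("A", "B")
  ggplot(tidy(object), aes(x = .data$mean_log2_cpm, y = .data$log_fc,
                           colour = .data$dt)) +
    geom_point(size = 0.6, alpha = 0.7) +
    geom_hline(yintercept = 0, linetype = "dashed") +
    geom_hline(yintercept = c(-guide_fc, guide_fc), linetype = "dotted") +
    scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
                        name = "DT") +
    labs(x = "mean log2 CPM", y = sprintf("log2 FC (%s / %s)", ct[1], ct[2])) +
    theme_minimal()
}

#' Plot an MDS embedding of samples
#'
#' @param object A [mds_coordinates()] result.
#' @param samples Optional sample sheet; points are coloured by `role`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot smrna_mds
#' @export
autoplot.smrna_mds <- function(object, samples = NULL, ...) {
  d <- tidy(object)
  if (!is.null(samples)) {
    d <- left_join(d, samples[c("sample_id", "role")], by = "sample_id")
    p <- ggplot(d, aes(.data$dim1, .data$dim2, colour = .data$role))
  } else {
    p <- ggplot(d, aes(.data$dim1, .data$dim2))
  }
  p + geom_point(size = 2) +
    labs(x = "dimension 1", y = "dimension 2") + theme_minimal()
}

#' Bar plot of interaction-category counts
#'
#' @param interactions Output of [classify_interactions()] (or the pipeline's
#'   pooled interactions table).
#' @param drop_no_change Drop the `no_change` category (default TRUE).
#' @return A ggplot object.
#' @export
plot_interaction_counts <- function(interactions, drop_no_change = TRUE) {
  d <- interactions |> filter(!is.na(.data$category))
  if (drop_no_change) d <- filter(d, .data$category != "no_change")
  d <- count(d, .data$polyploid, .data$category)
  ggplot(d, aes(.data$category, .data$n, fill = .data$polyploid)) +
    geom_col(position = "dodge") +
    labs(x = NULL, y = "DT regions") + theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Per-sample read-length profile
#'
#' Fraction of (unique) reads per length and sample, grouped by role; shows
#' the characteristic bimodal 21-22 / 24 nt small-RNA profile.
#'
#' @param alignments Alignment-record tibble.
#' @param samples Sample sheet.
#' @return A ggplot object.
#' @export
plot_length_profile <- function(alignments, samples) {
  d <- alignments |>
    distinct(.data$sample_id, .data$read_id, .data$length) |>
    count(.data$sample_id, .data$length) |>
    group_by(.data$sample_id) |>
    mutate(fraction = .data$n / sum(.data$n)) |>
    ungroup() |>
    left_join(samples[c("sample_id", "role")], by = "sample_id")
  ggplot(d, aes(.data$length, .data$fraction, group = .data$sample_id,
                colour = .data$role)) +
    geom_line(alpha = 0.6) +
    labs(x = "read length (nt)", y = "fraction of reads") +
    theme_minimal()
}
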