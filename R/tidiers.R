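#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a differential-targeting result
#'
#' @param x A [nb_test()] result.
#' @param ... Unused.
#' @return A plain tibble (one row per region).
#' @method tidy smrna_dt
#' @export
tidy.smrna_dt <- function(x, ...) {
  as_tibble(unclass(x)[c("region_id", "log_fc", "mean_log2_cpm",
                         "p_value", "fdr", "dt")])
}

#' One-row summary of a differential-targeting result
#'
#' @param x A [nb_test()] result.
#' @param ... Unused.
#' @return Tibble: contrast, regions tested, DT count, alpha, dispersion.
#' @method glance smrna_dt
#' @export
glance.smrna_dt <- function(x, ...) {
  ct <- attr(x, "contrast") %||% c(NA, NA)
  tibble(contrast = paste(ct, collapse = ":"),
         n_regions = nrow(x), n_dt = sum(x$dt),
         alpha = attr(x, "alpha") %||% NA_real_,
         phi = attr(x, "phi") %||% NA_real_)
}

#' Tidy a dispersion fit
#'
#' @param x An [estimate_dispersion()] object.
#' @param ... Unused.
#' @return One row per region when tagwise estimates exist, else one row.
#' @method tidy smrna_dispersion
#' @export
tidy.smrna_dispersion <- function(x, ...) {
  if (is.null(x$tagwise_phi)) {
    tibble(term = "common_phi", estimate = x$common_phi)
  } else {
    tibble(region = seq_along(x$tagwise_phi),
           phi = x$tagwise_phi, common_phi = x$common_phi)
  }
}

#' One-row summary of a dispersion fit
#'
#' @param x An [estimate_dispersion()] object.
#' @param ... Unused.
#' @method glance smrna_dispersion
#' @export
glance.smrna_dispersion <- function(x, ...) {
  tibble(common_phi = x$common_phi,
         tagwise = !is.null(x$tagwise_phi),
         n_regions = x$n_regions, n_samples = x$n_samples)
}

#' Tidy an MDS embedding
#'
#' @param x A [mds_coordinates()] / [mds_embed()] result.
#' @param ... Unused.
#' @method tidy smrna_mds
#' @export
tidy.smrna_mds <- function(x, ...) as_tibble(unclass(x))
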