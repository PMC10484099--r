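#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a panel design into its probe table
#'
#' @param x A [panel_design()].
#' @param ... Unused.
#' @return The probe tibble.
#' @export
tidy.panel_design <- function(x, ...) {
  x$probes
}

#' One-row summary of a panel design
#'
#' @param x A [panel_design()].
#' @param ... Unused.
#' @return Tibble with probe counts, synthesized copies, unique footprint
#'   and overall in-silico coverage.
#' @export
glance.panel_design <- function(x, ...) {
  s <- panel_summary(x)
  tot <- s[s$group == "total", ]
  cov <- in_silico_coverage(x)
  tibble::tibble(
    n_probes = tot$n_probes,
    n_synthesized = tot$n_synthesized,
    footprint_kb = tot$footprint_kb,
    n_regions = tot$n_regions,
    n_groups = length(unique(x$targets$group)),
    coverage = cov$coverage[cov$group == "overall"]
  )
}

#' One-row summary of a methylation table
#'
#' @param x A `methyl_tbl`.
#' @param ... Unused.
#' @return Tibble with site count, coverage summaries and the applied
#'   coverage filter.
#' @export
glance.methyl_tbl <- function(x, ...) {
  tibble::tibble(
    sample_id = attr(x, "sample_id") %||% NA_character_,
    library = attr(x, "library") %||% NA_character_,
    n_sites = nrow(x),
    median_coverage = stats::median(x$coverage),
    mean_beta = mean(x$beta, na.rm = TRUE),
    coverage_filter = attr(x, "coverage_filter") %||% 0L
  )
}

#' One-row summary of a DMP table
#'
#' @param x A `dmp_tbl` from [methylation_diff()].
#' @param ... Unused.
#' @return Tibble with shared-CpG and DMP counts by direction.
#' @export
glance.dmp_tbl <- function(x, ...) {
  tibble::tibble(
    n_shared = nrow(x),
    n_dmp = sum(x$is_dmp),
    n_hyper = sum(x$is_dmp & x$direction > 0),
    n_hypo = sum(x$is_dmp & x$direction < 0),
    dmp_threshold = attr(x, "dmp_threshold") %||% NA_real_
  )
}

#' Totals of a region-coverage summary
#'
#' @param x A `region_cov_tbl` from [region_coverage()].
#' @param ... Unused.
#' @return The pooled totals row (captured counts, pooled median/range,
#'   threshold fractions).
#' @export
glance.region_cov_tbl <- function(x, ...) {
  attr(x, "totals")
}

#' Methylation-difference plot along the genome
#'
#' @param object A `dmp_tbl`.
#' @param ... Unused.
#' @return A ggplot: per-CpG delta by position, DMPs highlighted, one
#'   facet per chromosome.
#' @export
autoplot.dmp_tbl <- function(object, ...) {
  thr <- attr(object, "dmp_threshold") %||% 0.1
  ggplot2::ggplot(
    tibble::as_tibble(object),
    ggplot2::aes(x = .data$pos, y = .data$delta, colour = .data$is_dmp)
  ) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = c(-thr, thr), linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), scales = "free_x") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(
      x = "position (bp)", y = expression(Delta * beta),
      colour = "DMP"
    ) +
    ggplot2::theme_minimal()
}

#' Beta-value distribution of a methylation table
#'
#' @param object A `methyl_tbl`.
#' @param ... Unused.
#' @return A ggplot histogram of per-CpG beta values.
#' @export
autoplot.methyl_tbl <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object), ggplot2::aes(x = .data$beta)) +
    ggplot2::geom_histogram(bins = 50, fill = "steelblue", colour = "white") +
    ggplot2::labs(x = expression(beta), y = "CpG units") +
    ggplot2::theme_minimal()
}

#' Coverage-threshold profile of a region summary
#'
#' @param object A `region_cov_tbl`.
#' @param ... Unused.
#' @return A ggplot of the pooled fraction of bases at or above each
#'   coverage threshold (monotone non-increasing).
#' @export
autoplot.region_cov_tbl <- function(object, ...) {
  totals <- attr(object, "totals")
  thresholds <- attr(object, "thresholds")
  df <- tibble::tibble(
    threshold = thresholds,
    fraction = unlist(totals[sprintf("frac_ge_%d", thresholds)])
  )
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$threshold), y = .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "coverage threshold (X)", y = "fraction of bases") +
    ggplot2::theme_minimal()
}
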