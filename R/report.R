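#' Per-base depth track from read observations
#'
#' @param observations Observation tibble.
#' @param reference Reference sequences (defines track lengths; uncovered
#'   bases have depth 0).
#' @return A `depth_track`: named list of integer vectors, one per
#'   chromosome.
#' @export
depth_track <- function(observations, reference) {
  lens <- chrom_lengths(reference)
  out <- purrr::map(names(lens), function(ch) {
    o <- observations[observations$chrom == ch, ]
    if (nrow(o) == 0) {
      return(integer(lens[[ch]]))
    }
    as.integer(IRanges::coverage(
      IRanges::IRanges(o$start + 1L, o$end),
      width = lens[[ch]]
    ))
  })
  structure(stats::setNames(out, names(lens)), class = "depth_track")
}

#' Per-region coverage summaries
#'
#' Medians, ranges and the fraction of bases at or above each coverage
#' threshold, per region and pooled. A region counts as captured when at
#' least one base (or, when a site table is supplied, at least one
#' strand-merged site) inside it meets `capture_min` coverage.
#'
#' @param depth A `depth_track`.
#' @param regions Interval tibble (a `name` column is carried through).
#' @param thresholds Coverage thresholds for the fraction columns.
#' @param capture_min Coverage a base/site needs for the region to count
#'   as captured (default 10).
#' @param sites Optional `methyl_tbl`; when given, the captured flag uses
#'   site coverage instead of base depth.
#' @return A `region_cov_tbl` with per-region rows and a `totals`
#'   attribute (pooled medians and threshold fractions; see
#'   [glance.region_cov_tbl()]).
#' @export
region_coverage <- function(depth, regions, thresholds = c(10L, 20L, 30L, 50L, 100L),
                            capture_min = 10L, sites = NULL) {
  regions <- as_intervals(regions)
  if (nrow(regions) == 0) stop("`regions` is empty", call. = FALSE)
  frac_cols <- sprintf("frac_ge_%d", thresholds)
  rows <- vector("list", nrow(regions))
  all_bases <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    v <- depth[[regions$chrom[i]]][(regions$start[i] + 1L):regions$end[i]]
    all_bases[[i]] <- v
    captured <- if (is.null(sites)) {
      any(v >= capture_min)
    } else {
      any(sites$chrom == regions$chrom[i] &
        sites$pos >= regions$start[i] & sites$pos < regions$end[i] &
        sites$coverage >= capture_min)
    }
    row <- tibble::tibble(
      chrom = regions$chrom[i], start = regions$start[i], end = regions$end[i],
      name = if ("name" %in% names(regions)) regions$name[i] else sprintf("region_%d", i),
      n_bases = length(v),
      median_depth = stats::median(v),
      min_depth = min(v),
      max_depth = max(v),
      captured = captured
    )
    for (k in seq_along(thresholds)) row[[frac_cols[k]]] <- mean(v >= thresholds[k])
    rows[[i]] <- row
  }
  out <- dplyr::bind_rows(rows)
  pooled <- unlist(all_bases)
  totals <- tibble::tibble(
    n_regions = nrow(out),
    n_captured = sum(out$captured),
    frac_captured = mean(out$captured),
    median_depth = stats::median(pooled),
    min_depth = min(pooled),
    max_depth = max(pooled)
  )
  for (k in seq_along(thresholds)) totals[[frac_cols[k]]] <- mean(pooled >= thresholds[k])
  class(out) <- c("region_cov_tbl", class(tibble::tibble()))
  attr(out, "totals") <- totals
  attr(out, "thresholds") <- thresholds
  out
}

#' Flank coverage around target regions
#'
#' For each window size w, the fraction of bases in `(regions +/- w)`
#' excluding the regions themselves whose depth strictly exceeds
#' `threshold` — the proximal off-target capture a hybridization panel
#' produces. A zero window has an empty flank and is reported as NA.
#'
#' @param depth A `depth_track`.
#' @param regions Interval tibble.
#' @param windows Flank widths in bases.
#' @param threshold Depth a flank base must exceed (default 30).
#' @return Tibble: `window`, `n_bases`, `fraction`.
#' @export
flank_coverage <- function(depth, regions, windows = c(100L, 200L), threshold = 30L) {
  regions <- interval_normalize(regions)
  lens <- stats::setNames(
    vapply(depth, length, integer(1)),
    names(depth)
  )
  purrr::map(windows, function(w) {
    if (w <= 0) {
      return(tibble::tibble(window = w, n_bases = 0L, fraction = NA_real_))
    }
    expanded <- regions
    expanded$start <- pmax(0L, expanded$start - as.integer(w))
    expanded$end <- pmin(lens[expanded$chrom], expanded$end + as.integer(w))
    expanded <- interval_normalize(expanded)
    flank <- purrr::map(split(expanded, expanded$chrom), function(d) {
      ch <- d$chrom[1]
      rc <- regions[regions$chrom == ch, ]
      r <- IRanges::setdiff(.ir(d), .ir(rc))
      .from_ir(ch, r)
    }) |> dplyr::bind_rows()
    vals <- unlist(purrr::map(seq_len(nrow(flank)), function(i) {
      depth[[flank$chrom[i]]][(flank$start[i] + 1L):flank$end[i]]
    }))
    tibble::tibble(
      window = w,
      n_bases = length(vals),
      fraction = if (length(vals) > 0) mean(vals > threshold) else NA_real_
    )
  }) |> dplyr::bind_rows()
}

#' Spearman correlation of beta values between two methylation tables
#'
#' Computed on shared CpGs (optionally restricted to regions), with
#' average ranks for ties.
#'
#' @param table_x,table_y `methyl_tbl` objects.
#' @param regions Optional interval tibble restricting the comparison.
#' @return One-row tibble: `rho`, `n`.
#' @export
beta_correlation <- function(table_x, table_y, regions = NULL) {
  shared <- dplyr::inner_join(
    tibble::as_tibble(table_x)[c("chrom", "pos", "beta")],
    tibble::as_tibble(table_y)[c("chrom", "pos", "beta")],
    by = c("chrom", "pos"), suffix = c("_x", "_y")
  )
  if (!is.null(regions)) {
    regions <- interval_normalize(regions)
    keep <- rep(FALSE, nrow(shared))
    for (i in seq_len(nrow(regions))) {
      keep <- keep | (shared$chrom == regions$chrom[i] &
        shared$pos >= regions$start[i] & shared$pos < regions$end[i])
    }
    shared <- shared[keep, ]
  }
  if (nrow(shared) < 3) {
    stop("fewer than 3 shared CpGs: correlation is undefined", call. = FALSE)
  }
  tibble::tibble(
    rho = stats::cor(shared$beta_x, shared$beta_y, method = "spearman"),
    n = nrow(shared)
  )
}

#' Write a run manifest
#'
#' Records package version, R version, timestamp, seed and parameters as
#' JSON so a simulation or analysis run is replayable.
#'
#' @param path Output path.
#' @param params Named list of run parameters.
#' @param seed Seed used for the run.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, params = list(), seed = NULL) {
  manifest <- list(
    package = "capmeth",
    version = as.character(utils::packageVersion("capmeth")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    params = params
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(path)
}
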