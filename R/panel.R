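#' Tile fixed-length capture probes over target intervals
#'
#' Probes of `probe_len` bases are laid left-to-right with step
#' `round(probe_len / tiling_density)`, so each target base is covered by
#' about `tiling_density` probes. The final probe of each region is
#' right-aligned to the region end so no target base is left uncovered.
#' Regions shorter than a probe get one probe centered on the region,
#' extended into the flanks and clipped at chromosome bounds. Probes whose
#' sequence contains an ambiguous base (N) are dropped: they cannot be
#' synthesized.
#'
#' @param targets Interval tibble; an optional `group` column labels
#'   target classes (e.g. "locus", "promoters") and is carried onto probes.
#' @param reference Named character vector, `DNAStringSet` or
#'   `sim_reference` supplying probe sequences.
#' @param probe_len Probe length in bases (default 120).
#' @param tiling_density Average per-base probe depth, a positive integer.
#' @return Tibble of probes: `probe_id`, `chrom`, `start`, `end`, `length`,
#'   `group`, `gc_fraction`, `masked_bases` (0), `copy_number` (1), `seq`.
#' @export
tile_probes <- function(targets, reference, probe_len = 120L, tiling_density = 3L) {
  seqs <- ref_sequences(reference)
  targets <- as_intervals(targets, reference = seqs)
  if (length(tiling_density) != 1 || is.na(tiling_density) || tiling_density < 1) {
    stop("`tiling_density` must be a positive integer", call. = FALSE)
  }
  probe_len <- as.integer(probe_len)
  if (probe_len < 1L) stop("`probe_len` must be >= 1", call. = FALSE)
  tiling_density <- as.integer(round(tiling_density))
  step <- max(1L, as.integer(round(probe_len / tiling_density)))
  group <- if ("group" %in% names(targets)) as.character(targets$group) else rep("target", nrow(targets))
  lens <- chrom_lengths(seqs)

  rows <- vector("list", nrow(targets))
  for (i in seq_len(nrow(targets))) {
    ch <- targets$chrom[i]
    s <- targets$start[i]
    e <- targets$end[i]
    if (e - s < probe_len) {
      centre <- (s + e) %/% 2L
      ps <- centre - probe_len %/% 2L
      pe <- ps + probe_len
      ps <- max(0L, ps)
      pe <- min(lens[[ch]], pe)
      starts <- ps
      ends <- pe
    } else {
      starts <- seq.int(s, e - probe_len, by = step)
      if (starts[length(starts)] + probe_len < e) {
        starts <- c(starts, e - probe_len)
      }
      ends <- starts + probe_len
    }
    rows[[i]] <- tibble::tibble(
      chrom = ch, start = as.integer(starts), end = as.integer(ends), group = group[i]
    )
  }
  probes <- dplyr::distinct(
    dplyr::bind_rows(rows),
    .data$chrom, .data$start, .data$end, .data$group
  )
  probes$seq <- substring(unname(seqs[probes$chrom]), probes$start + 1L, probes$end)
  probes <- probes[!grepl("N", probes$seq, fixed = TRUE), ]
  probes <- dplyr::arrange(probes, .data$chrom, .data$start, .data$end)
  tibble::tibble(
    probe_id = sprintf("probe_%s_%d_%d", probes$chrom, probes$start, probes$end),
    chrom = probes$chrom,
    start = probes$start,
    end = probes$end,
    length = probes$end - probes$start,
    group = probes$group,
    gc_fraction = gc_fraction_of(probes$seq),
    masked_bases = 0L,
    copy_number = 1L,
    seq = probes$seq
  )
}

#' Combine repeat-mask tracks into a consensus mask
#'
#' With the `least_stringent` policy a base is masked only when *every*
#' masker flags it (set intersection), keeping as much designable sequence
#' as possible; `most_stringent` masks a base any masker flags (union).
#'
#' @param tracks A list of interval tibbles, one per masker (a single
#'   tibble is also accepted).
#' @param policy `"least_stringent"` (intersection) or `"most_stringent"`
#'   (union).
#' @return Normalized interval tibble.
#' @export
consensus_mask <- function(tracks, policy = c("least_stringent", "most_stringent")) {
  policy <- match.arg(policy)
  if (is.data.frame(tracks)) tracks <- list(tracks)
  if (length(tracks) == 0) stop("at least one mask track is required", call. = FALSE)
  tracks <- purrr::map(tracks, interval_normalize)
  if (policy == "most_stringent") {
    interval_normalize(dplyr::bind_rows(tracks))
  } else {
    Reduce(interval_intersect, tracks)
  }
}

#' Annotate and reject probes overlapping a mask
#'
#' Each probe is annotated with `masked_bases`, its overlap with the mask;
#' probes whose masked fraction strictly exceeds `max_masked_fraction` are
#' removed. A tolerance (default 0.25) preserves probes at repeat edges.
#'
#' @param probes Probe tibble from [tile_probes()].
#' @param mask Interval tibble (e.g. from [consensus_mask()]).
#' @param max_masked_fraction Maximum tolerated masked fraction in `[0, 1]`.
#' @return Filtered probe tibble, input order preserved.
#' @export
filter_masked_probes <- function(probes, mask, max_masked_fraction = 0.25) {
  probes <- tibble::as_tibble(probes)
  if (nrow(probes) == 0) {
    probes$masked_bases <- integer()
    return(probes)
  }
  probes$masked_bases <- interval_overlap_bases(probes, mask)
  probes[probes$masked_bases / probes$length <= max_masked_fraction, ]
}

#' GC boost schedule
#'
#' A step function from GC fraction to probe copy number: copies are
#' constant up to the first breakpoint and step up on the left-open
#' intervals between breakpoints. The default doubling ladder is
#' GC <= 0.60 -> 1, (0.60, 0.65] -> 2, (0.65, 0.70] -> 4,
#' (0.70, 0.75] -> 8, > 0.75 -> 16.
#'
#' @param breaks Increasing GC breakpoints in `[0, 1]`.
#' @param copies Copy numbers, one more than `breaks`, non-decreasing.
#' @return A `boost_schedule` object.
#' @export
boost_schedule <- function(breaks = c(0.60, 0.65, 0.70, 0.75),
                           copies = c(1L, 2L, 4L, 8L, 16L)) {
  if (length(copies) != length(breaks) + 1L) {
    stop("`copies` must have one more element than `breaks`", call. = FALSE)
  }
  if (is.unsorted(breaks, strictly = TRUE)) {
    stop("`breaks` must be strictly increasing", call. = FALSE)
  }
  if (any(diff(copies) < 0) || any(copies < 1)) {
    stop("`copies` must be non-decreasing and >= 1 (schedule monotone in GC)", call. = FALSE)
  }
  structure(list(breaks = breaks, copies = as.integer(copies)), class = "boost_schedule")
}

#' Boost probe copy numbers by GC content
#'
#' GC-rich sequence captures poorly; replicating its probes (up to `cap`
#' copies) compensates. Copy numbers are assigned from each probe's
#' `gc_fraction` through a monotone [boost_schedule()].
#'
#' @param probes Probe tibble.
#' @param schedule A [boost_schedule()].
#' @param cap Maximum copy number (default 16).
#' @return Probe tibble with `copy_number` set; otherwise unchanged.
#' @export
boost_probes <- function(probes, schedule = boost_schedule(), cap = 16L) {
  if (!inherits(schedule, "boost_schedule")) {
    schedule <- boost_schedule(schedule$breaks, schedule$copies)
  }
  if (cap < 1) stop("`cap` must be >= 1", call. = FALSE)
  probes <- tibble::as_tibble(probes)
  idx <- findInterval(probes$gc_fraction, schedule$breaks, left.open = TRUE)
  probes$copy_number <- pmin(schedule$copies[idx + 1L], as.integer(cap))
  probes
}

#' Assemble a panel design
#'
#' Bundles probes, grouped targets and design parameters into one object
#' used by [in_silico_coverage()] and [panel_summary()].
#'
#' @param probes Probe tibble.
#' @param targets Interval tibble with optional `group` column.
#' @param params Named list of design parameters (recorded, not interpreted).
#' @return A `panel_design` object.
#' @export
panel_design <- function(probes, targets, params = list()) {
  targets <- as_intervals(targets)
  if (!"group" %in% names(targets)) targets$group <- "target"
  structure(
    list(probes = tibble::as_tibble(probes), targets = targets, params = params),
    class = "panel_design"
  )
}

#' @export
print.panel_design <- function(x, ...) {
  cat("<panel_design>\n")
  cat("  probes:  ", nrow(x$probes), " (", sum(x$probes$copy_number), " synthesized copies)\n", sep = "")
  cat("  targets: ", nrow(x$targets), " region(s) in ",
    length(unique(x$targets$group)), " group(s)\n",
    sep = ""
  )
  invisible(x)
}

#' In-silico coverage of the target groups
#'
#' Fraction of target bases under at least one probe footprint. Probe copy
#' numbers are ignored and footprints deduplicated: boosting changes
#' synthesis counts, never the covered sequence.
#'
#' @param design A [panel_design()].
#' @return Tibble with one row per target group plus an `overall` row:
#'   `group`, `target_bp`, `covered_bp`, `coverage`.
#' @export
in_silico_coverage <- function(design) {
  stopifnot(inherits(design, "panel_design"))
  probes <- design$probes
  footprint <- if (nrow(probes) == 0) {
    tibble::tibble(chrom = character(), start = integer(), end = integer())
  } else {
    interval_normalize(probes[c("chrom", "start", "end")])
  }
  groups <- unique(design$targets$group)
  per_group <- purrr::map(groups, function(g) {
    tg <- design$targets[design$targets$group == g, ]
    tw <- interval_total_width(tg)
    cov <- interval_total_width(interval_intersect(footprint, tg))
    tibble::tibble(group = g, target_bp = tw, covered_bp = cov)
  })
  out <- dplyr::bind_rows(per_group)
  tot_t <- interval_total_width(design$targets)
  tot_c <- interval_total_width(interval_intersect(footprint, design$targets))
  out <- dplyr::bind_rows(
    out,
    tibble::tibble(group = "overall", target_bp = tot_t, covered_bp = tot_c)
  )
  out$coverage <- ifelse(out$target_bp > 0, out$covered_bp / out$target_bp, 0)
  out
}

#' Panel accounting summary
#'
#' Per-group and total probe counts, synthesized copies, unique footprint
#' size and achieved tiling depth (probe bases over footprint bases).
#'
#' @param design A [panel_design()].
#' @return Tibble with columns `group`, `n_regions`, `n_probes`,
#'   `n_synthesized`, `footprint_kb`, `tiling`.
#' @export
panel_summary <- function(design) {
  stopifnot(inherits(design, "panel_design"))
  probes <- design$probes
  groups <- unique(design$targets$group)
  row_for <- function(g, pr, tg) {
    fp <- if (nrow(pr) == 0) 0L else interval_total_width(pr[c("chrom", "start", "end")])
    tibble::tibble(
      group = g,
      n_regions = nrow(tg),
      n_probes = nrow(pr),
      n_synthesized = if (nrow(pr) == 0) 0L else sum(pr$copy_number),
      footprint_kb = fp / 1000,
      tiling = if (fp > 0) sum(pr$length) / fp else 0
    )
  }
  has_group <- nrow(probes) > 0 && "group" %in% names(probes)
  per_group <- purrr::map(groups, function(g) {
    pr <- if (has_group) probes[probes$group == g, ] else probes[0, ]
    row_for(g, pr, design$targets[design$targets$group == g, ])
  })
  dplyr::bind_rows(per_group, row_for("total", probes, design$targets))
}
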