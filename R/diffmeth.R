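#' Per-CpG methylation differences between two samples
#'
#' Computes `delta = beta_a - beta_b` for every CpG covered in *both*
#' tables (sample A is the first argument; the sign is reported, never
#' folded). A CpG is a differentially methylated position (DMP) when
#' `|delta|` strictly exceeds `dmp_threshold`: a fixed effect-size rule,
#' not a statistical test, so no multiple-testing correction applies. A
#' delta of exactly the threshold is not a DMP.
#'
#' @param table_a,table_b `methyl_tbl` objects with the same coverage
#'   filter applied.
#' @param dmp_threshold DMP effect-size threshold on `|delta|`
#'   (default 0.1).
#' @return A `dmp_tbl`: `chrom`, `pos`, `beta_a`, `beta_b`, `delta`,
#'   `is_dmp`, `direction` (sign of delta), coordinate-sorted, one row per
#'   shared CpG.
#' @export
methylation_diff <- function(table_a, table_b, dmp_threshold = 0.1) {
  fa <- attr(table_a, "coverage_filter") %||% 0L
  fb <- attr(table_b, "coverage_filter") %||% 0L
  if (!identical(fa, fb)) {
    warning("tables carry different coverage filters (", fa, " vs ", fb, ")")
  }
  shared <- dplyr::inner_join(
    tibble::as_tibble(table_a)[c("chrom", "pos", "beta")],
    tibble::as_tibble(table_b)[c("chrom", "pos", "beta")],
    by = c("chrom", "pos"), suffix = c("_a", "_b")
  )
  if (nrow(shared) == 0) stop("no CpGs are shared between the two tables", call. = FALSE)
  out <- shared |>
    dplyr::mutate(
      delta = .data$beta_a - .data$beta_b,
      is_dmp = abs(.data$delta) > dmp_threshold,
      direction = sign(.data$delta)
    ) |>
    dplyr::arrange(.data$chrom, .data$pos)
  class(out) <- c("dmp_tbl", class(tibble::tibble()))
  attr(out, "dmp_threshold") <- dmp_threshold
  out
}

#' Call differentially methylated regions
#'
#' A DMR is a maximal run of at least `min_consecutive` *consecutive*
#' shared CpGs that are all DMPs with the same direction. Adjacency is in
#' the shared-CpG list; `max_gap` optionally bounds the genomic distance
#' between neighbours (unlimited by default, since shared-CpG adjacency
#' can span large gaps in a sparse panel).
#'
#' @param dmps A `dmp_tbl` from [methylation_diff()], sorted.
#' @param min_consecutive Minimum run length (default 2).
#' @param max_gap Maximum base gap between neighbouring member CpGs.
#' @return Tibble of DMRs: `chrom`, `start`, `end` (half-open, covering
#'   the CpG dinucleotides), `n_cpgs`, `direction`, `positions` (list
#'   column of member CpG positions).
#' @export
call_dmrs <- function(dmps, min_consecutive = 2L, max_gap = Inf) {
  empty <- tibble::tibble(
    chrom = character(), start = integer(), end = integer(),
    n_cpgs = integer(), direction = numeric(), positions = list()
  )
  if (nrow(dmps) == 0) {
    return(empty)
  }
  out <- purrr::map(split(tibble::as_tibble(dmps), dmps$chrom), function(d) {
    d <- dplyr::arrange(d, .data$pos)
    n <- nrow(d)
    brk <- c(
      TRUE,
      d$is_dmp[-1] != d$is_dmp[-n] |
        (d$is_dmp[-1] & d$is_dmp[-n] & d$direction[-1] != d$direction[-n]) |
        (d$pos[-1] - d$pos[-n]) > max_gap
    )
    d$run <- cumsum(brk)
    d <- d[d$is_dmp, ]
    d <- d[d$run %in% names(which(table(d$run) >= min_consecutive)), ]
    if (nrow(d) == 0) {
      return(NULL)
    }
    d |>
      dplyr::group_by(.data$run) |>
      dplyr::summarise(
        chrom = .data$chrom[1],
        start = min(.data$pos),
        end = max(.data$pos) + 2L,
        n_cpgs = dplyr::n(),
        direction = .data$direction[1],
        positions = list(.data$pos),
        .groups = "drop"
      ) |>
      dplyr::select(-"run")
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    return(empty)
  }
  dplyr::arrange(res, .data$chrom, .data$start)
}

#' Cross-method (BS/EM) consensus DMPs
#'
#' Keeps CpGs measured by both conversion chemistries where the
#' methylation difference strictly exceeds `primary_threshold` in one
#' method, is at least `secondary_threshold` in the other, and the sign
#' agrees. Each record notes which method passed the primary threshold.
#'
#' @param bs_dmps,em_dmps `dmp_tbl` objects for the same sample pair.
#' @param primary_threshold Strict threshold one method must exceed
#'   (default 0.10).
#' @param secondary_threshold Inclusive threshold for the other method
#'   (default 0.05).
#' @return Tibble: `chrom`, `pos`, `delta_bs`, `delta_em`, `direction`,
#'   `primary_method` (`"BS"`, `"EM"` or `"both"`).
#' @export
cross_method_consensus <- function(bs_dmps, em_dmps,
                                   primary_threshold = 0.10,
                                   secondary_threshold = 0.05) {
  shared <- dplyr::inner_join(
    tibble::as_tibble(bs_dmps)[c("chrom", "pos", "delta")],
    tibble::as_tibble(em_dmps)[c("chrom", "pos", "delta")],
    by = c("chrom", "pos"), suffix = c("_bs", "_em")
  )
  bs_primary <- abs(shared$delta_bs) > primary_threshold
  em_primary <- abs(shared$delta_em) > primary_threshold
  bs_secondary <- abs(shared$delta_bs) >= secondary_threshold
  em_secondary <- abs(shared$delta_em) >= secondary_threshold
  same_dir <- sign(shared$delta_bs) == sign(shared$delta_em) & sign(shared$delta_bs) != 0
  keep <- same_dir & ((bs_primary & em_secondary) | (em_primary & bs_secondary))
  out <- shared[keep, ]
  out$direction <- sign(out$delta_bs)
  out$primary_method <- dplyr::case_when(
    bs_primary[keep] & em_primary[keep] ~ "both",
    bs_primary[keep] ~ "BS",
    TRUE ~ "EM"
  )
  out
}

#' Annotate records with their nearest genomic feature
#'
#' The nearest feature on the same chromosome is selected by midpoint
#' distance; the reported `distance` is the gap to the feature interval
#' (0 when the position lies inside it). Midpoint ties go to the
#' lexicographically smallest feature id and are flagged.
#'
#' @param x Tibble with `chrom` and `pos` columns (e.g. consensus DMPs).
#' @param features Interval tibble with a `name` column (promoters/genes).
#' @return `x` with `feature`, `distance` and `tie` columns appended.
#' @export
annotate_nearest_feature <- function(x, features) {
  features <- as_intervals(features)
  if (nrow(features) == 0) stop("feature set is empty", call. = FALSE)
  if (!"name" %in% names(features)) {
    features$name <- sprintf("feature_%d", seq_len(nrow(features)))
  }
  x <- tibble::as_tibble(x)
  x$feature <- NA_character_
  x$distance <- NA_integer_
  x$tie <- FALSE
  for (ch in unique(x$chrom)) {
    fi <- features[features$chrom == ch, ]
    xi <- which(x$chrom == ch)
    if (nrow(fi) == 0) next
    mid <- (fi$start + fi$end) / 2
    for (i in xi) {
      d <- abs(x$pos[i] - mid)
      best <- which(d == min(d))
      tie <- length(best) > 1
      if (tie) best <- best[order(fi$name[best])]
      b <- best[1]
      inside <- x$pos[i] >= fi$start[b] & x$pos[i] < fi$end[b]
      gap <- if (inside) 0L else
        as.integer(max(fi$start[b] - x$pos[i], x$pos[i] - (fi$end[b] - 1L)))
      x$feature[i] <- fi$name[b]
      x$distance[i] <- gap
      x$tie[i] <- tie
    }
  }
  x
}
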