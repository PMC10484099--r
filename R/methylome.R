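#' Call per-cytosine methylation from read observations
#'
#' For every reference cytosine interrogated by a read's conversion strand
#' (top-strand Cs by OT reads; bottom-strand Cs, i.e. top-strand Gs, by OB
#' reads), a C call counts as methylated and a T (A on the bottom strand)
#' as unmethylated. Other mismatches are ignored for methylation. Reads
#' never inform positions their conversion strand cannot interrogate: a
#' directional-protocol correctness requirement. Context (CpG/CHG/CHH) is
#' annotated from the reference trinucleotide, never from the reads.
#'
#' @param observations Observation tibble from [simulate_capture_reads()]
#'   or [read_observations()].
#' @param reference Reference sequences.
#' @param min_base_quality Retained for FASTQ-derived inputs; observation
#'   tables carry no qualities, so it is not used here.
#' @return Tibble of cytosine records: `chrom`, `pos` (0-based), `strand`,
#'   `context`, `meth_count`, `unmeth_count`, coordinate-sorted.
#' @export
call_cytosines <- function(observations, reference, min_base_quality = 20L) {
  seqs <- ref_sequences(reference)
  lens <- chrom_lengths(seqs)
  if (any(!(observations$chrom %in% names(lens))) ||
    any(observations$end > lens[observations$chrom]) ||
    any(observations$start < 0)) {
    stop("observation beyond reference bounds", call. = FALSE)
  }

  acc <- list()
  k <- 0L
  for (ch in unique(observations$chrom)) {
    schars <- strsplit(seqs[[ch]], "", fixed = TRUE)[[1]]
    refc <- which(schars == "C") # 1-based
    refg <- which(schars == "G")
    obs <- observations[observations$chrom == ch, ]
    for (i in seq_len(nrow(obs))) {
      sites <- if (obs$strand[i] == "OT") refc else refg
      lo <- findInterval(obs$start[i], sites) + 1L # first site > start (1-based > start)
      hi <- findInterval(obs$end[i], sites) # last site <= end
      if (hi < lo) next
      p1 <- sites[lo:hi]
      offs <- p1 - obs$start[i]
      bases <- substring(obs$seq[i], offs, offs)
      if (obs$strand[i] == "OT") {
        meth <- bases == "C"
        keep <- meth | bases == "T"
      } else {
        meth <- bases == "G"
        keep <- meth | bases == "A"
      }
      if (!any(keep)) next
      k <- k + 1L
      acc[[k]] <- tibble::tibble(
        chrom = ch, pos = p1[keep] - 1L,
        strand = if (obs$strand[i] == "OT") "+" else "-",
        meth = meth[keep]
      )
    }
  }
  if (k == 0L) {
    return(tibble::tibble(
      chrom = character(), pos = integer(), strand = character(),
      context = character(), meth_count = integer(), unmeth_count = integer()
    ))
  }
  calls <- dplyr::bind_rows(acc) |>
    dplyr::group_by(.data$chrom, .data$pos, .data$strand) |>
    dplyr::summarise(
      meth_count = sum(.data$meth),
      unmeth_count = sum(!.data$meth),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$chrom, .data$pos)
  calls$context <- cytosine_context(seqs, calls$chrom, calls$pos, calls$strand)
  calls[c("chrom", "pos", "strand", "context", "meth_count", "unmeth_count")]
}

# Context of a cytosine from the reference trinucleotide. `pos` is the
# 0-based position of the reference C (+ strand) or G (- strand).
cytosine_context <- function(seqs, chrom, pos, strand) {
  svec <- unname(seqs[chrom])
  plus <- strand == "+"
  ctx <- rep("CHH", length(pos))
  n1 <- character(length(pos))
  n2 <- character(length(pos))
  n1[plus] <- substring(svec[plus], pos[plus] + 2L, pos[plus] + 2L)
  n2[plus] <- substring(svec[plus], pos[plus] + 3L, pos[plus] + 3L)
  n1[!plus] <- substring(svec[!plus], pos[!plus], pos[!plus])
  n2[!plus] <- substring(svec[!plus], pos[!plus] - 1L, pos[!plus] - 1L)
  partner <- ifelse(plus, "G", "C")
  ctx[n1 == partner] <- "CpG"
  ctx[n1 != partner & n2 == partner & n1 != ""] <- "CHG"
  ctx
}

#' Merge the two strands of each CpG into one unit
#'
#' The + strand C at position p and the - strand C (reference G) at p + 1
#' of the same palindromic CpG are merged by summing counts; the unit is
#' reported at p. Non-CpG records are excluded. When only one strand was
#' covered the merged record equals that strand's record, still reported
#' at the + strand coordinate.
#'
#' @param records Cytosine records from [call_cytosines()].
#' @param sample_id,library Labels for the resulting table.
#' @return A `methyl_tbl` of strand-merged CpG records (unfiltered).
#' @export
merge_cpg_strands <- function(records, sample_id = "sample", library = "BS") {
  if (!"context" %in% names(records)) {
    stop("records must be context-annotated (run call_cytosines())", call. = FALSE)
  }
  cg <- records[records$context == "CpG", ]
  # a + record at p must pair with a CpG-context - record at p + 1
  plus <- cg[cg$strand == "+", c("chrom", "pos")]
  minus_all <- records[records$strand == "-", c("chrom", "pos", "context")]
  if (nrow(plus) > 0 && nrow(minus_all) > 0) {
    pair <- dplyr::inner_join(
      dplyr::mutate(plus, mpos = .data$pos + 1L),
      minus_all,
      by = c("chrom", "mpos" = "pos")
    )
    if (any(pair$context != "CpG")) {
      stop("cannot merge records from different contexts at one CpG unit", call. = FALSE)
    }
  }
  merged <- cg |>
    dplyr::mutate(unit = ifelse(.data$strand == "+", .data$pos, .data$pos - 1L)) |>
    dplyr::group_by(.data$chrom, .data$unit) |>
    dplyr::summarise(
      meth_count = sum(.data$meth_count),
      unmeth_count = sum(.data$unmeth_count),
      .groups = "drop"
    ) |>
    dplyr::rename(pos = "unit")
  methyl_table(merged, sample_id = sample_id, library = library)
}

#' Construct a strand-merged methylation table
#'
#' @param records Tibble with `chrom`, `pos`, `meth_count`, `unmeth_count`.
#' @param sample_id Sample label.
#' @param library Library kind, `"BS"` or `"EM"` (or `"DNA"`).
#' @param coverage_filter Minimum coverage already applied (0 = none).
#' @return A `methyl_tbl`: coordinate-sorted tibble with `coverage` and
#'   `beta` columns and `sample_id`/`library`/`coverage_filter` attributes.
#' @export
methyl_table <- function(records, sample_id = "sample", library = "BS",
                         coverage_filter = 0L) {
  x <- tibble::as_tibble(records)
  x <- dplyr::arrange(x, .data$chrom, .data$pos)
  x$coverage <- x$meth_count + x$unmeth_count
  x$beta <- ifelse(x$coverage > 0, x$meth_count / x$coverage, NA_real_)
  class(x) <- c("methyl_tbl", class(tibble::tibble()))
  attr(x, "sample_id") <- sample_id
  attr(x, "library") <- library
  attr(x, "coverage_filter") <- as.integer(coverage_filter)
  x
}

#' Filter a methylation table by coverage
#'
#' Keeps records with `meth_count + unmeth_count >= min_cov` (inclusive,
#' matching common practice for a "10X" filter) and records the filter on
#' the table. Idempotent.
#'
#' @param table A `methyl_tbl`.
#' @param min_cov Minimum coverage, >= 1.
#' @return Filtered `methyl_tbl`.
#' @export
filter_coverage <- function(table, min_cov = 10L) {
  if (min_cov < 1) stop("`min_cov` must be >= 1", call. = FALSE)
  out <- table[table$coverage >= min_cov, ]
  methyl_table(out[c("chrom", "pos", "meth_count", "unmeth_count")],
    sample_id = attr(table, "sample_id") %||% "sample",
    library = attr(table, "library") %||% "BS",
    coverage_filter = max(min_cov, attr(table, "coverage_filter") %||% 0L)
  )
}

#' Estimate conversion efficiency from non-CpG cytosines
#'
#' Outside neurons and stem cells, true non-CpG methylation is near zero,
#' so the apparent methylation fraction at CHG/CHH sites estimates the
#' conversion failure rate: methylated calls divided by total calls,
#' pooled and per context.
#'
#' @param records Cytosine records from [call_cytosines()].
#' @return Tibble with rows `CHG`, `CHH` and pooled `non-CpG`:
#'   `context`, `meth`, `total`, `fraction`.
#' @export
conversion_efficiency <- function(records) {
  ncpg <- records[records$context %in% c("CHG", "CHH"), ]
  if (nrow(ncpg) == 0 || sum(ncpg$meth_count + ncpg$unmeth_count) == 0) {
    stop("no non-CpG calls: conversion efficiency is undefined", call. = FALSE)
  }
  per <- ncpg |>
    dplyr::group_by(context = .data$context) |>
    dplyr::summarise(
      meth = sum(.data$meth_count),
      total = sum(.data$meth_count + .data$unmeth_count),
      .groups = "drop"
    )
  pooled <- tibble::tibble(
    context = "non-CpG", meth = sum(per$meth), total = sum(per$total)
  )
  out <- dplyr::bind_rows(per, pooled)
  out$fraction <- out$meth / out$total
  out
}

#' Write a methylation table in Bismark coverage format
#'
#' Columns: chromosome, 1-based start, 1-based end (equal to start for
#' strand-merged units), methylation percentage, methylated count,
#' unmethylated count. The percentage is recomputed from counts on every
#' write, so write -> read -> write is byte-stable.
#'
#' @param table A `methyl_tbl`.
#' @param path Output path (conventionally `.cov`).
#' @return `path`, invisibly.
#' @export
write_bismark_cov <- function(table, path) {
  pct <- round(100 * table$meth_count / (table$meth_count + table$unmeth_count), 6)
  df <- tibble::tibble(
    chrom = table$chrom,
    start = table$pos + 1L,
    end = table$pos + 1L,
    pct = pct,
    meth = table$meth_count,
    unmeth = table$unmeth_count
  )
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a Bismark coverage file
#'
#' @param path Path to a `.cov` file (1-based inclusive positions,
#'   percentage 0-100); converted to 0-based positions and fractional
#'   betas internally.
#' @param sample_id,library Labels for the table.
#' @return A `methyl_tbl`.
#' @export
read_bismark_cov <- function(path, sample_id = basename(path), library = "BS") {
  df <- readr::read_tsv(path,
    col_names = c("chrom", "start", "end", "pct", "meth", "unmeth"),
    col_types = "ciidii", progress = FALSE
  )
  methyl_table(
    tibble::tibble(
      chrom = df$chrom, pos = df$start - 1L,
      meth_count = df$meth, unmeth_count = df$unmeth
    ),
    sample_id = sample_id, library = library
  )
}

#' Write cytosine records as a cytosine report
#'
#' Bismark-style cytosine report: chromosome, 1-based position, strand,
#' methylated count, unmethylated count, context.
#'
#' @param records Cytosine records from [call_cytosines()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cytosine_report <- function(records, path) {
  df <- tibble::tibble(
    chrom = records$chrom, pos = records$pos + 1L, strand = records$strand,
    meth = records$meth_count, unmeth = records$unmeth_count,
    context = records$context
  )
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a cytosine report written by [write_cytosine_report()]
#'
#' @param path Input path.
#' @return Cytosine record tibble (0-based positions).
#' @export
read_cytosine_report <- function(path) {
  df <- readr::read_tsv(path,
    col_names = c("chrom", "pos", "strand", "meth", "unmeth", "context"),
    col_types = "ciciic", progress = FALSE
  )
  tibble::tibble(
    chrom = df$chrom, pos = df$pos - 1L, strand = df$strand,
    context = df$context, meth_count = df$meth, unmeth_count = df$unmeth
  )
}
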