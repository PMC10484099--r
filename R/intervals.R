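#' Validate a genomic interval table
#'
#' Intervals are plain tibbles with at least `chrom`, `start` and `end`
#' columns. Coordinates are 0-based, half-open throughout the package;
#' conversion to 1-based formats happens only inside readers/writers.
#'
#' @param x Data frame with `chrom`, `start`, `end` (extra columns kept).
#' @param reference Optional reference (named character vector,
#'   `DNAStringSet` or `sim_reference`); when given, intervals must fall
#'   inside the corresponding chromosome.
#' @return A tibble with validated interval columns.
#' @export
as_intervals <- function(x, reference = NULL) {
  x <- tibble::as_tibble(x)
  missing <- setdiff(c("chrom", "start", "end"), names(x))
  if (length(missing) > 0) {
    stop("interval table lacks column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  x$chrom <- as.character(x$chrom)
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  bad <- x$start < 0L | x$end <= x$start
  if (any(bad)) {
    i <- which(bad)[1]
    stop("invalid interval ", fmt_interval(x$chrom[i], x$start[i], x$end[i]),
      " (need 0 <= start < end)",
      call. = FALSE
    )
  }
  if (!is.null(reference)) {
    lens <- chrom_lengths(reference)
    unknown <- !(x$chrom %in% names(lens))
    if (any(unknown)) {
      i <- which(unknown)[1]
      stop("interval ", fmt_interval(x$chrom[i], x$start[i], x$end[i]),
        " is on a sequence absent from the reference",
        call. = FALSE
      )
    }
    over <- x$end > lens[x$chrom]
    if (any(over)) {
      i <- which(over)[1]
      stop("interval ", fmt_interval(x$chrom[i], x$start[i], x$end[i]),
        " extends beyond the end of ", x$chrom[i],
        call. = FALSE
      )
    }
  }
  x
}

# IRanges view of one-chromosome interval rows (1-based closed internally).
.ir <- function(df) IRanges::IRanges(start = df$start + 1L, end = df$end)

.from_ir <- function(chrom, r) {
  tibble::tibble(
    chrom = chrom,
    start = IRanges::start(r) - 1L,
    end = IRanges::end(r)
  )
}

#' Normalize intervals: sort and merge overlapping/adjacent runs
#'
#' @inheritParams as_intervals
#' @return Tibble of disjoint sorted intervals.
#' @export
interval_normalize <- function(x) {
  x <- as_intervals(x)
  if (nrow(x) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(), end = integer()))
  }
  out <- purrr::map(split(x, x$chrom), function(d) {
    .from_ir(d$chrom[1], IRanges::reduce(.ir(d)))
  })
  dplyr::arrange(dplyr::bind_rows(out), .data$chrom, .data$start)
}

#' Intersect two interval sets
#'
#' @param a,b Interval tibbles.
#' @return Normalized tibble of bases present in both `a` and `b`.
#' @export
interval_intersect <- function(a, b) {
  a <- interval_normalize(a)
  b <- interval_normalize(b)
  shared <- intersect(unique(a$chrom), unique(b$chrom))
  out <- purrr::map(shared, function(ch) {
    r <- IRanges::intersect(.ir(a[a$chrom == ch, ]), .ir(b[b$chrom == ch, ]))
    .from_ir(ch, r)
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(), end = integer()))
  }
  dplyr::arrange(res, .data$chrom, .data$start)
}

#' Union of two interval sets
#'
#' @inheritParams interval_intersect
#' @return Normalized tibble of bases present in either set.
#' @export
interval_union <- function(a, b) {
  interval_normalize(dplyr::bind_rows(
    as_intervals(a)[c("chrom", "start", "end")],
    as_intervals(b)[c("chrom", "start", "end")]
  ))
}

#' Total number of bases covered by an interval set
#'
#' @inheritParams as_intervals
#' @return Integer base count after normalization.
#' @export
interval_total_width <- function(x) {
  x <- interval_normalize(x)
  sum(x$end - x$start)
}

# Per-row overlap (in bases) of `x` with the union of `mask`.
interval_overlap_bases <- function(x, mask) {
  x <- as_intervals(x)
  if (nrow(x) == 0) {
    return(integer())
  }
  mask <- interval_normalize(mask)
  out <- integer(nrow(x))
  for (ch in unique(x$chrom)) {
    xi <- which(x$chrom == ch)
    mc <- mask[mask$chrom == ch, ]
    if (nrow(mc) == 0) next
    qr <- .ir(x[xi, ])
    sr <- .ir(mc)
    hits <- IRanges::findOverlaps(qr, sr)
    if (length(hits) == 0) next
    ov <- IRanges::width(IRanges::pintersect(
      qr[S4Vectors::queryHits(hits)],
      sr[S4Vectors::subjectHits(hits)]
    ))
    agg <- tapply(ov, S4Vectors::queryHits(hits), sum)
    out[xi[as.integer(names(agg))]] <- as.integer(agg)
  }
  out
}

#' Read a BED file (0-based half-open)
#'
#' The first three columns become `chrom`, `start`, `end`; columns four to
#' six, when present, are `name`, `score`, `strand`. Extra columns are kept
#' with their file names.
#'
#' @param path Path to a BED3+ file.
#' @return Interval tibble.
#' @export
read_bed <- function(path) {
  df <- readr::read_tsv(path,
    col_names = FALSE, comment = "#",
    show_col_types = FALSE, progress = FALSE
  )
  std <- c("chrom", "start", "end", "name", "score", "strand")
  n <- min(ncol(df), length(std))
  names(df)[seq_len(n)] <- std[seq_len(n)]
  as_intervals(df)
}

#' Write intervals as BED (0-based half-open)
#'
#' @param x Interval tibble; `chrom`, `start`, `end` are written first,
#'   then any of `name`, `score`, `strand` and remaining columns in order.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  x <- as_intervals(x)
  lead <- intersect(c("chrom", "start", "end", "name", "score", "strand"), names(x))
  x <- x[c(lead, setdiff(names(x), lead))]
  readr::write_tsv(x, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
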