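#' Pile up read observations per reference position
#'
#' One column per covered position, with per-read base calls aggregated by
#' base, conversion strand and library kind. Each observation row is one
#' sequenced molecule, so overlapping mates can never double-count: the
#' simulator emits one record per fragment.
#'
#' @param observations Observation tibble.
#' @param reference Reference sequences.
#' @return A `pileup_tbl`: `chrom`, `pos` (0-based), `ref`, `base`,
#'   `strand`, `library`, `n`, coordinate-sorted.
#' @export
pileup <- function(observations, reference) {
  seqs <- ref_sequences(reference)
  lens <- chrom_lengths(seqs)
  if (any(observations$end > lens[observations$chrom]) || any(observations$start < 0)) {
    stop("observation beyond reference bounds", call. = FALSE)
  }
  chunks <- split(
    seq_len(nrow(observations)),
    ceiling(seq_len(nrow(observations)) / 4000)
  )
  acc <- purrr::map(chunks, function(idx) {
    o <- observations[idx, ]
    w <- nchar(o$seq)
    tibble::tibble(
      chrom = rep(o$chrom, w),
      pos = rep(o$start, w) + sequence(w) - 1L,
      base = unlist(strsplit(o$seq, "", fixed = TRUE), use.names = FALSE),
      strand = rep(o$strand, w),
      library = rep(o$library, w)
    ) |>
      dplyr::count(.data$chrom, .data$pos, .data$base, .data$strand, .data$library)
  })
  out <- dplyr::bind_rows(acc) |>
    dplyr::group_by(.data$chrom, .data$pos, .data$base, .data$strand, .data$library) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop") |>
    dplyr::arrange(.data$chrom, .data$pos)
  out$ref <- substring(unname(seqs[out$chrom]), out$pos + 1L, out$pos + 1L)
  out <- out[c("chrom", "pos", "ref", "base", "strand", "library", "n")]
  class(out) <- c("pileup_tbl", class(tibble::tibble()))
  out
}

# TRUE where the (ref, alt) allele pair cannot be distinguished on the
# given conversion strand: C/T collapses on OT reads, G/A on OB reads.
confounded_ct <- function(r, b) (r == "C" & b == "T") | (r == "T" & b == "C")
confounded_ga <- function(r, b) (r == "G" & b == "A") | (r == "A" & b == "G")

#' Diploid genotype calling from a pileup
#'
#' An explicit minimal model replaces black-box caller defaults: with a
#' flat prior over \{hom_ref, het, hom_alt\} and a fixed per-base error
#' rate e, each informative read contributes P(base | genotype, e), a het
#' emitting each allele with probability 1/2. The call is the posterior
#' argmax; GQ is the phred-scaled probability the call is wrong. Sites
#' with informative depth below `min_depth` are emitted as no-calls so
#' replicate-concordance statistics stay well defined.
#'
#' In `bisulfite_aware` mode, converted-library reads whose conversion
#' strand confounds the allele pair (C/T on OT, G/A on OB) are excluded
#' from the informative set at those sites; sites where the exclusion
#' drops the depth below `min_depth` are flagged conversion-ambiguous.
#'
#' @param pu A `pileup_tbl` from [pileup()].
#' @param reference Reference sequences (for error messages on bad refs).
#' @param error_rate Per-base error rate in (0, 0.5).
#' @param min_depth Minimum informative depth for a call (default 30).
#' @param bisulfite_aware Exclude conversion-confounded reads.
#' @return Tibble of calls, one row per covered position: `chrom`, `pos`,
#'   `ref`, `alt` (NA for hom_ref/no_call), `genotype`
#'   (`hom_ref`/`het`/`hom_alt`/`no_call`), `gq`, `depth` (informative),
#'   `excluded`, `conv_ambiguous`.
#' @export
call_genotypes <- function(pu, reference, error_rate = 0.001, min_depth = 30L,
                           bisulfite_aware = FALSE) {
  if (error_rate <= 0 || error_rate >= 0.5) {
    stop("`error_rate` must be in (0, 0.5)", call. = FALSE)
  }
  pu <- tibble::as_tibble(pu)
  pu <- pu[pu$base %in% DNA_BASES, ]
  if (any(!pu$ref %in% DNA_BASES)) {
    bad <- which(!pu$ref %in% DNA_BASES)[1]
    stop("non-ACGT reference base at ", pu$chrom[bad], ":", pu$pos[bad], call. = FALSE)
  }
  key <- paste(pu$chrom, pu$pos)
  pos_tbl <- dplyr::distinct(pu[c("chrom", "pos", "ref")])
  pkey <- paste(pos_tbl$chrom, pos_tbl$pos)
  np <- nrow(pos_tbl)
  row_of <- match(key, pkey)
  col_of <- match(pu$base, DNA_BASES)

  fill <- function(sel) {
    m <- matrix(0, np, 4, dimnames = list(NULL, DNA_BASES))
    if (any(sel)) {
      idx <- cbind(row_of[sel], col_of[sel])
      # accumulate (several strand/library rows can map to one cell)
      v <- tapply(pu$n[sel], paste(row_of[sel], col_of[sel]), sum)
      at <- do.call(rbind, strsplit(names(v), " ", fixed = TRUE))
      m[cbind(as.integer(at[, 1]), as.integer(at[, 2]))] <- as.numeric(v)
    }
    m
  }
  n_all <- fill(rep(TRUE, nrow(pu)))
  conv <- pu$library != "DNA"
  n_ot <- fill(conv & pu$strand == "OT")
  n_ob <- fill(conv & pu$strand == "OB")

  ref <- pos_tbl$ref
  ref_idx <- match(ref, DNA_BASES)

  # informative non-ref counts per candidate alt, under the exclusion rule
  alt_counts <- matrix(-Inf, np, 4)
  for (b in seq_along(DNA_BASES)) {
    bb <- DNA_BASES[b]
    cnt <- n_all[, b]
    if (bisulfite_aware) {
      ct <- confounded_ct(ref, bb)
      ga <- confounded_ga(ref, bb)
      cnt <- cnt - ct * n_ot[, b] - ga * n_ob[, b]
    }
    alt_counts[, b] <- cnt
  }
  alt_counts[cbind(seq_len(np), ref_idx)] <- -Inf
  alt_idx <- max.col(alt_counts, ties.method = "first")
  alt_n <- alt_counts[cbind(seq_len(np), alt_idx)]
  # fall back to the raw argmax, then the transition partner, when no
  # informative alt evidence exists (needed to define the het model)
  raw <- n_all
  raw[cbind(seq_len(np), ref_idx)] <- -Inf
  raw_idx <- max.col(raw, ties.method = "first")
  raw_n <- raw[cbind(seq_len(np), raw_idx)]
  ti_idx <- match(transition_of[ref], DNA_BASES)
  alt_idx <- ifelse(alt_n > 0, alt_idx, ifelse(raw_n > 0, raw_idx, ti_idx))
  alt <- DNA_BASES[alt_idx]

  n_inf <- n_all
  if (bisulfite_aware) {
    ct_sel <- confounded_ct(ref, alt)
    ga_sel <- confounded_ga(ref, alt)
    n_inf <- n_all - ct_sel * n_ot - ga_sel * n_ob
  }
  dp <- rowSums(n_inf)
  excluded <- as.integer(round(rowSums(n_all) - dp))
  refn <- n_inf[cbind(seq_len(np), ref_idx)]
  altn <- n_inf[cbind(seq_len(np), alt_idx)]
  othern <- dp - refn - altn

  e <- error_rate
  l_hom_ref <- refn * log(1 - e) + (altn + othern) * log(e / 3)
  l_hom_alt <- altn * log(1 - e) + (refn + othern) * log(e / 3)
  p_major <- 0.5 * (1 - e) + 0.5 * (e / 3)
  l_het <- (refn + altn) * log(p_major) + othern * log(e / 3)
  ll <- cbind(l_hom_ref, l_het, l_hom_alt)
  mx <- pmax(ll[, 1], ll[, 2], ll[, 3])
  post <- exp(ll - mx)
  post <- post / rowSums(post)
  gt_i <- max.col(post, ties.method = "first")
  p_best <- post[cbind(seq_len(np), gt_i)]
  gq <- pmin(99L, as.integer(round(-10 * log10(pmax(1e-10, 1 - p_best)))))
  genotype <- c("hom_ref", "het", "hom_alt")[gt_i]
  called <- dp >= min_depth
  genotype[!called] <- "no_call"
  conv_amb <- bisulfite_aware & excluded > 0L & !called

  tibble::tibble(
    chrom = pos_tbl$chrom,
    pos = pos_tbl$pos,
    ref = ref,
    alt = ifelse(genotype %in% c("het", "hom_alt"), alt, NA_character_),
    genotype = genotype,
    gq = ifelse(called, gq, NA_integer_),
    depth = as.integer(round(dp)),
    excluded = excluded,
    conv_ambiguous = conv_amb
  )
}

#' Extract variant calls (non-reference genotypes)
#'
#' @param calls Call tibble from [call_genotypes()].
#' @return Rows with genotype `het` or `hom_alt`.
#' @export
variant_calls <- function(calls) {
  calls[calls$genotype %in% c("het", "hom_alt"), ]
}

#' Replicate concordance of two variant call sets
#'
#' A variant is shared when chromosome, position, alt allele and genotype
#' all agree. Both per-sample overlap fractions are reported.
#'
#' @param calls_a,calls_b Call tibbles (full calls or [variant_calls()]).
#' @return One-row tibble: `n_a`, `n_b`, `shared`, `frac_a`, `frac_b`.
#' @export
replicate_overlap <- function(calls_a, calls_b) {
  va <- variant_calls(calls_a)
  vb <- variant_calls(calls_b)
  shared <- nrow(dplyr::inner_join(
    va[c("chrom", "pos", "alt", "genotype")],
    vb[c("chrom", "pos", "alt", "genotype")],
    by = c("chrom", "pos", "alt", "genotype")
  ))
  tibble::tibble(
    n_a = nrow(va), n_b = nrow(vb), shared = shared,
    frac_a = if (nrow(va) > 0) shared / nrow(va) else NA_real_,
    frac_b = if (nrow(vb) > 0) shared / nrow(vb) else NA_real_
  )
}

#' Write genotype calls as VCF v4.2
#'
#' Variant and no-call records are written with GT, GQ and DP; sites
#' flagged conversion-ambiguous carry the `CONVAMB` INFO flag. All fields
#' are recomputed from the call table on every write, so
#' write -> read -> write is byte-stable.
#'
#' @param calls Call tibble from [call_genotypes()] (usually
#'   [variant_calls()]).
#' @param path Output path.
#' @param sample_id Sample column name.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path, sample_id = "sample") {
  gt <- dplyr::case_when(
    calls$genotype == "het" ~ "0/1",
    calls$genotype == "hom_alt" ~ "1/1",
    calls$genotype == "hom_ref" ~ "0/0",
    TRUE ~ "./."
  )
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=capmeth",
    "##INFO=<ID=CONVAMB,Number=0,Type=Flag,Description=\"Conversion-ambiguous site\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Informative depth\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample_id)
  )
  info <- ifelse(!is.na(calls$conv_ambiguous) & calls$conv_ambiguous, "CONVAMB", ".")
  body <- sprintf(
    "%s\t%d\t.\t%s\t%s\t.\tPASS\t%s\tGT:GQ:DP\t%s:%s:%d",
    calls$chrom, calls$pos + 1L, calls$ref,
    ifelse(is.na(calls$alt), ".", calls$alt),
    info, gt,
    ifelse(is.na(calls$gq), ".", as.character(calls$gq)),
    calls$depth
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a VCF written by [write_vcf()] or [write_truth_vcf()]
#'
#' Minimal single-sample VCF reader for this package's dialect.
#'
#' @param path Input path.
#' @return Call tibble with 0-based `pos`.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0) {
    return(tibble::tibble(
      chrom = character(), pos = integer(), ref = character(),
      alt = character(), genotype = character(), gq = integer(),
      depth = integer(), excluded = integer(), conv_ambiguous = logical()
    ))
  }
  f <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
  sample_f <- strsplit(f[, 10], ":", fixed = TRUE)
  gt <- vapply(sample_f, `[`, character(1), 1)
  gq <- vapply(sample_f, function(v) if (length(v) >= 2) v[2] else NA_character_, character(1))
  dp <- vapply(sample_f, function(v) if (length(v) >= 3) v[3] else NA_character_, character(1))
  genotype <- dplyr::case_when(
    gt %in% c("0/1", "1/0", "0|1", "1|0") ~ "het",
    gt %in% c("1/1", "1|1") ~ "hom_alt",
    gt %in% c("0/0", "0|0") ~ "hom_ref",
    TRUE ~ "no_call"
  )
  tibble::tibble(
    chrom = f[, 1],
    pos = as.integer(f[, 2]) - 1L,
    ref = f[, 4],
    alt = ifelse(f[, 5] == ".", NA_character_, f[, 5]),
    genotype = genotype,
    gq = suppressWarnings(as.integer(gq)),
    depth = suppressWarnings(as.integer(dp)),
    excluded = NA_integer_,
    conv_ambiguous = grepl("CONVAMB", f[, 8], fixed = TRUE)
  )
}
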