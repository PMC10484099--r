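#' Conversion chemistry model
#'
#' Directional conversion chemistry for methylation libraries: unmethylated
#' cytosines are read as thymines, methylated cytosines are left unchanged.
#' `failure_rate` is the probability an unmethylated C escapes conversion
#' (appearing methylated); `overconversion_rate` the probability a
#' methylated C is converted anyway. Defaults echo typical residual non-CpG
#' methylation: bisulfite 1.5%, enzymatic 0.6%.
#'
#' @param kind `"none"` (unconverted DNA library), `"BS"` or `"EM"`.
#' @param failure_rate,overconversion_rate Probabilities in `[0, 1]`;
#'   defaults per `kind`.
#' @return A `conversion_model` object.
#' @export
conversion_model <- function(kind = c("none", "BS", "EM"),
                             failure_rate = NULL, overconversion_rate = NULL) {
  kind <- match.arg(kind)
  defaults <- list(none = c(0, 0), BS = c(0.015, 0.005), EM = c(0.006, 0.005))[[kind]]
  failure_rate <- failure_rate %||% defaults[1]
  overconversion_rate <- overconversion_rate %||% defaults[2]
  stopifnot(failure_rate >= 0, failure_rate <= 1,
            overconversion_rate >= 0, overconversion_rate <= 1)
  structure(
    list(
      kind = kind,
      failure_rate = if (kind == "none") 0 else failure_rate,
      overconversion_rate = if (kind == "none") 0 else overconversion_rate,
      library = if (kind == "none") "DNA" else kind,
      directional = TRUE
    ),
    class = "conversion_model"
  )
}

# Per-chromosome lookup vectors mapping a 1-based genomic position to the
# true beta of the CpG unit interrogated there (NA = not a CpG cytosine).
# `betaC` indexes top-strand Cs of CpGs, `betaG` the paired top-strand Gs
# (bottom-strand Cs).
beta_lookup <- function(truth, condition) {
  seqs <- ref_sequences(truth$reference)
  col <- if (condition == "A") "beta_a" else "beta_b"
  out <- list(C = list(), G = list())
  for (ch in names(seqs)) {
    L <- nchar(seqs[[ch]])
    bc <- rep(NA_real_, L)
    bg <- rep(NA_real_, L)
    if (!is.null(truth$cpg)) {
      cp <- truth$cpg[truth$cpg$chrom == ch, ]
      bc[cp$pos + 1L] <- cp[[col]]
      bg[cp$pos + 2L] <- cp[[col]]
    }
    out$C[[ch]] <- bc
    out$G[[ch]] <- bg
  }
  out
}

#' Simulate probe-weighted capture of sequencing fragments
#'
#' Fragments are drawn uniformly along the genome with truncated-normal
#' insert lengths (the fragmentation target, ~250 bp). A fragment is
#' retained with probability `min(1, capture_coef * sum(copy_number))` over
#' the probes it overlaps, so probe boosting is observable in coverage;
#' fragments touching no probe are admitted at `off_target_rate`. Each
#' retained fragment picks a haplotype and a conversion strand (OT reads
#' interrogate top-strand cytosines, OB reads bottom-strand cytosines,
#' i.e. top-strand Gs), draws per-molecule CpG methylation Bernoulli(beta),
#' applies the conversion chemistry and finally i.i.d. sequencing errors.
#'
#' Reads carry their true origin, so downstream quantification and
#' genotyping are testable without an aligner; paired FASTQ can still be
#' written with [write_fastq()] for external pipelines. One observation row
#' is one molecule, so mate overlap never double-counts evidence.
#'
#' @param truth A `diploid_truth` (run [assign_methylation()] first for
#'   converted libraries).
#' @param panel A [panel_design()] or probe tibble.
#' @param n_fragments Number of fragments drawn before capture selection.
#' @param condition `"A"` or `"B"`: which truth methylation column to use.
#' @param conversion A [conversion_model()].
#' @param insert_mean,insert_sd Insert-length distribution (bases); lengths
#'   are truncated to `[read_len, 2 * insert_mean]`.
#' @param read_len Read length for FASTQ emission.
#' @param off_target_rate Admission probability for off-target fragments.
#' @param seq_error Per-base sequencing error rate.
#' @param capture_coef Capture probability per unit of summed probe copy
#'   number (saturates at 1).
#' @param seed Integer seed.
#' @return Tibble of read observations: `read_id`, `chrom`, `start`, `end`,
#'   `strand` (OT/OB), `haplotype`, `library`, `condition`, `seq`.
#' @export
simulate_capture_reads <- function(truth, panel, n_fragments = 20000L,
                                   condition = c("A", "B"),
                                   conversion = conversion_model("none"),
                                   insert_mean = 250, insert_sd = 30,
                                   read_len = 150L, off_target_rate = 0.01,
                                   seq_error = 0.001, capture_coef = 0.2,
                                   seed = 1L) {
  condition <- match.arg(condition)
  stopifnot(inherits(truth, "diploid_truth"), n_fragments >= 1)
  probes <- if (inherits(panel, "panel_design")) panel$probes else tibble::as_tibble(panel)
  if (nrow(probes) == 0) stop("`panel` has no probes", call. = FALSE)
  if (!"copy_number" %in% names(probes)) probes$copy_number <- 1L
  seqs <- ref_sequences(truth$reference)
  lens <- chrom_lengths(seqs)
  lut <- beta_lookup(truth, condition)
  fail <- conversion$failure_rate
  over <- conversion$overconversion_rate
  ncr <- truth$non_cpg_rate %||% 0

  withr::with_seed(seed, {
    chroms <- sample(names(lens), n_fragments, TRUE, prob = lens)
    ins <- round(stats::rnorm(n_fragments, insert_mean, insert_sd))
    lo <- read_len
    hi <- min(2 * insert_mean, max(lens))
    for (it in 1:50) {
      bad <- ins < lo | ins > hi | ins > lens[chroms]
      if (!any(bad)) break
      ins[bad] <- round(stats::rnorm(sum(bad), insert_mean, insert_sd))
    }
    ins <- pmin(pmax(ins, lo), pmin(hi, lens[chroms]))
    start <- as.integer(floor(stats::runif(n_fragments) * (lens[chroms] - ins + 1)))

    weight <- numeric(n_fragments)
    for (ch in unique(chroms)) {
      idx <- which(chroms == ch)
      pc <- probes[probes$chrom == ch, ]
      if (nrow(pc) == 0) next
      hits <- IRanges::findOverlaps(
        IRanges::IRanges(start[idx] + 1L, start[idx] + ins[idx]),
        IRanges::IRanges(pc$start + 1L, pc$end)
      )
      if (length(hits) == 0) next
      agg <- tapply(pc$copy_number[S4Vectors::subjectHits(hits)], S4Vectors::queryHits(hits), sum)
      weight[idx[as.integer(names(agg))]] <- as.numeric(agg)
    }
    prob <- ifelse(weight > 0, pmin(1, capture_coef * weight), off_target_rate)
    keep <- stats::runif(n_fragments) < prob
    if (!any(keep)) {
      stop("no fragments were retained by the capture model; increase `n_fragments`",
        call. = FALSE
      )
    }
    chroms <- chroms[keep]
    ins <- ins[keep]
    start <- start[keep]
    m <- sum(keep)
    hap <- sample(1:2, m, TRUE)
    strand <- sample(c("OT", "OB"), m, TRUE)

    hseq <- character(m)
    hseq[hap == 1L] <- unname(truth$haplotypes[[1]][chroms[hap == 1L]])
    hseq[hap == 2L] <- unname(truth$haplotypes[[2]][chroms[hap == 2L]])
    raws <- substring(hseq, start + 1L, start + ins)
    chs <- strsplit(raws, "", fixed = TRUE)

    convert <- conversion$kind != "none"
    out_seq <- character(m)
    for (i in seq_len(m)) {
      v <- chs[[i]]
      if (convert) {
        if (strand[i] == "OT") {
          cpos <- which(v == "C")
          if (length(cpos) > 0) {
            beta <- lut$C[[chroms[i]]][start[i] + cpos]
            beta[is.na(beta)] <- ncr
            meth <- stats::runif(length(cpos)) < beta
            u <- stats::runif(length(cpos))
            stays <- (meth & u > over) | (!meth & u < fail)
            v[cpos[!stays]] <- "T"
          }
        } else {
          gpos <- which(v == "G")
          if (length(gpos) > 0) {
            beta <- lut$G[[chroms[i]]][start[i] + gpos]
            beta[is.na(beta)] <- ncr
            meth <- stats::runif(length(gpos)) < beta
            u <- stats::runif(length(gpos))
            stays <- (meth & u > over) | (!meth & u < fail)
            v[gpos[!stays]] <- "A"
          }
        }
      }
      if (seq_error > 0) {
        err <- which(stats::runif(length(v)) < seq_error)
        if (length(err) > 0) {
          v[err] <- vapply(v[err], function(b) sample(setdiff(DNA_BASES, b), 1), character(1))
        }
      }
      out_seq[i] <- paste(v, collapse = "")
    }

    tibble::tibble(
      read_id = sprintf("frag%07d", seq_len(m)),
      chrom = chroms,
      start = start,
      end = start + ins,
      strand = strand,
      haplotype = hap,
      library = conversion$library,
      condition = condition,
      seq = out_seq
    )
  })
}

#' Write paired FASTQ from read observations
#'
#' R1 is the first `read_len` bases of the fragment, R2 the reverse
#' complement of the last `read_len` bases; qualities are constant.
#'
#' @param observations Observation tibble from [simulate_capture_reads()].
#' @param prefix Output prefix; writes `<prefix>_R1.fastq`, `<prefix>_R2.fastq`.
#' @param read_len Read length.
#' @return The two paths, invisibly.
#' @export
write_fastq <- function(observations, prefix, read_len = 150L) {
  n <- nchar(observations$seq)
  r1 <- substr(observations$seq, 1L, pmin(read_len, n))
  r2 <- revcomp(substr(observations$seq, pmax(1L, n - read_len + 1L), n))
  emit <- function(reads, mate) {
    path <- sprintf("%s_R%d.fastq", prefix, mate)
    lines <- as.vector(rbind(
      sprintf("@%s/%d", observations$read_id, mate),
      reads,
      "+",
      strrep("I", nchar(reads))
    ))
    writeLines(lines, path)
    path
  }
  invisible(c(emit(r1, 1L), emit(r2, 2L)))
}

#' Simulate strand-merged CpG counts directly from truth
#'
#' The counts-level fast path of the simulator: for each CpG unit the
#' observed methylated-call probability is
#' `beta * (1 - overconversion) + (1 - beta) * failure`, and methylated
#' counts are drawn Binomial(depth, p). Equivalent in distribution to
#' running reads through quantification at fixed per-site depth, without
#' the read plumbing; used for calibration studies at exact uniform depth.
#'
#' @param truth A `diploid_truth` with methylation assigned.
#' @param depth Per-CpG total count (scalar or per-site vector).
#' @param condition `"A"` or `"B"`.
#' @param conversion A [conversion_model()].
#' @param sample_id,library Labels recorded on the returned table.
#' @param seed Integer seed.
#' @return A `methyl_tbl` (see [methyl_table()]), unfiltered.
#' @export
simulate_counts <- function(truth, depth = 50L, condition = c("A", "B"),
                            conversion = conversion_model("BS"),
                            sample_id = paste0("sim_", condition[1]),
                            library = conversion$library, seed = 1L) {
  condition <- match.arg(condition)
  if (is.null(truth$cpg)) {
    stop("run assign_methylation() before simulate_counts()", call. = FALSE)
  }
  beta <- if (condition == "A") truth$cpg$beta_a else truth$cpg$beta_b
  p <- beta * (1 - conversion$overconversion_rate) +
    (1 - beta) * conversion$failure_rate
  n <- length(beta)
  depth <- rep_len(as.integer(depth), n)
  withr::with_seed(seed, {
    meth <- stats::rbinom(n, depth, p)
    methyl_table(
      tibble::tibble(
        chrom = truth$cpg$chrom, pos = truth$cpg$pos,
        meth_count = meth, unmeth_count = depth - meth
      ),
      sample_id = sample_id, library = library
    )
  })
}

#' Write read observations as TSV
#'
#' @param observations Observation tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(observations, path) {
  readr::write_tsv(observations, path, progress = FALSE)
  invisible(path)
}

#' Read an observation TSV written by [write_observations()]
#'
#' @param path Input path.
#' @return Observation tibble.
#' @export
read_observations <- function(path) {
  readr::read_tsv(path,
    col_types = readr::cols(
      read_id = "c", chrom = "c", start = "i", end = "i", strand = "c",
      haplotype = "i", library = "c", condition = "c", seq = "c"
    ),
    progress = FALSE
  )
}
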