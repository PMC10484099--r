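# First-order Markov model over A/C/G/T calibrated so that the stationary
# GC content and CpG dinucleotide rate hit their targets. Only the C row of
# the transition matrix differs from the base distribution: P(G | C) is set
# by the CpG rate and the removed/added G mass is redistributed over the
# remaining bases, then the base distribution is nudged by fixed-point
# iteration until the stationary distribution matches.
calibrate_markov <- function(gc_target, cpg_rate) {
  if (cpg_rate > 0.95 * gc_target / 2) {
    stop("infeasible spec: cpg_rate ", cpg_rate, " cannot be reached at GC ",
      gc_target, " (needs cpg_rate <= gc/2)",
      call. = FALSE
    )
  }
  base_p <- function(gc) c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  build_tm <- function(gc, p_cg) {
    p <- base_p(gc)
    crow <- p * (1 - p_cg) / (1 - p[["G"]])
    crow[["G"]] <- p_cg
    rbind(A = p, C = crow, G = p, T = p)
  }
  stationary <- function(tm) {
    v <- rep(0.25, 4)
    for (i in 1:200) v <- as.numeric(v %*% tm)
    stats::setNames(v, DNA_BASES)
  }
  gc_w <- gc_target
  p_cg <- cpg_rate / (gc_target / 2)
  for (i in 1:60) {
    tm <- build_tm(gc_w, p_cg)
    pi_ <- stationary(tm)
    gc_obs <- pi_[["C"]] + pi_[["G"]]
    gc_w <- clip01(gc_w + (gc_target - gc_obs))
    p_cg <- min(0.99, cpg_rate / pi_[["C"]])
  }
  build_tm(gc_w, p_cg)
}

markov_stationary <- function(tm) {
  v <- rep(0.25, 4)
  for (i in 1:200) v <- as.numeric(v %*% tm)
  stats::setNames(v, DNA_BASES)
}

# Emit n bases from the chain; returns a character scalar.
gen_markov_seq <- function(n, tm) {
  cum <- t(apply(tm, 1, cumsum))
  c1 <- cum[, 1]
  c2 <- cum[, 2]
  c3 <- cum[, 3]
  pi_ <- markov_stationary(tm)
  u <- stats::runif(n)
  idx <- integer(n)
  cpi <- cumsum(pi_)
  idx[1] <- 1L + (u[1] > cpi[1]) + (u[1] > cpi[2]) + (u[1] > cpi[3])
  for (i in seq_len(n)[-1]) {
    p <- idx[i - 1L]
    idx[i] <- 1L + (u[i] > c1[p]) + (u[i] > c2[p]) + (u[i] > c3[p])
  }
  paste(DNA_BASES[idx], collapse = "")
}

#' Simulate a reference genome
#'
#' Generates one or more chromosomes from a first-order Markov chain
#' calibrated to a target GC content and CpG dinucleotide rate, optionally
#' planting tandem repeats (recorded as a mask-track analogue) and a
#' diverged paralog copy of a segment (a pseudogene stand-in).
#'
#' @param n_chrom Number of chromosomes.
#' @param length Chromosome length in bases (scalar or per-chromosome).
#' @param gc_target Target GC fraction.
#' @param cpg_rate Target CpG dinucleotides per base.
#' @param repeat_spec Optional `list(n, unit_len, n_copies)`: plant `n`
#'   tandem repeats of a random `unit_len`-mer repeated `n_copies` times.
#' @param paralog_spec Optional `list(length, divergence)`: copy a segment
#'   elsewhere, mutated at the given per-base divergence.
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @return A `sim_reference`: list with `sequences` (named character),
#'   `gc_target`, `cpg_rate` and `features` (interval tibble of planted
#'   repeats/paralogs, empty when none were requested).
#' @export
simulate_reference <- function(n_chrom = 1L, length = 200000L, gc_target = 0.45,
                               cpg_rate = 0.02, repeat_spec = NULL,
                               paralog_spec = NULL, seed = 1L) {
  if (any(length < 1000L)) stop("`length` must be >= 1000", call. = FALSE)
  if (gc_target <= 0 || gc_target >= 1 || cpg_rate < 0) {
    stop("invalid gc_target/cpg_rate", call. = FALSE)
  }
  tm <- calibrate_markov(gc_target, cpg_rate)
  lens <- rep_len(as.integer(length), n_chrom)
  withr::with_seed(seed, {
    seqs <- stats::setNames(
      vapply(lens, gen_markov_seq, character(1), tm = tm),
      sprintf("chrS%d", seq_len(n_chrom))
    )
    features <- tibble::tibble(
      chrom = character(), start = integer(), end = integer(), type = character()
    )
    pi_ <- markov_stationary(tm)
    if (!is.null(repeat_spec)) {
      n_rep <- repeat_spec$n %||% 3L
      unit_len <- repeat_spec$unit_len %||% 15L
      n_copies <- repeat_spec$n_copies %||% 12L
      for (k in seq_len(n_rep)) {
        unit <- paste(sample(DNA_BASES, unit_len, TRUE, prob = pi_), collapse = "")
        tract <- strrep(unit, n_copies)
        w <- nchar(tract)
        for (try in 1:100) {
          ch <- sample(names(seqs), 1)
          pos <- sample.int(nchar(seqs[[ch]]) - w, 1) - 1L
          clash <- any(features$chrom == ch & features$start < pos + w & features$end > pos)
          if (!clash) break
        }
        substr(seqs[[ch]], pos + 1L, pos + w) <- tract
        features <- dplyr::bind_rows(
          features,
          tibble::tibble(chrom = ch, start = pos, end = pos + w, type = "repeat")
        )
      }
    }
    if (!is.null(paralog_spec)) {
      plen <- as.integer(paralog_spec$length %||% 5000L)
      div <- paralog_spec$divergence %||% 0.03
      ch <- names(seqs)[which.max(nchar(seqs))]
      L <- nchar(seqs[[ch]])
      src <- sample.int(L - plen, 1) - 1L
      repeat {
        dst <- sample.int(L - plen, 1) - 1L
        if (abs(dst - src) >= plen) break
      }
      seg <- strsplit(seq_at(seqs, ch, src, src + plen), "")[[1]]
      nmut <- stats::rbinom(1, plen, div)
      if (nmut > 0) {
        at <- sample.int(plen, nmut)
        seg[at] <- vapply(seg[at], function(b) sample(setdiff(DNA_BASES, b), 1), character(1))
      }
      substr(seqs[[ch]], dst + 1L, dst + plen) <- paste(seg, collapse = "")
      features <- dplyr::bind_rows(
        features,
        tibble::tibble(
          chrom = ch, start = c(src, dst), end = c(src + plen, dst + plen),
          type = c("paralog_source", "paralog_copy")
        )
      )
    }
    structure(
      list(
        sequences = seqs, gc_target = gc_target, cpg_rate = cpg_rate,
        features = dplyr::arrange(features, .data$chrom, .data$start)
      ),
      class = "sim_reference"
    )
  })
}

#' @export
print.sim_reference <- function(x, ...) {
  cat("<sim_reference> ", length(x$sequences), " sequence(s), ",
    sum(nchar(x$sequences)), " bp, GC target ", x$gc_target, "\n",
    sep = ""
  )
  invisible(x)
}

#' Write reference or haplotype sequences as FASTA
#'
#' @param x A `sim_reference`, named character vector or `DNAStringSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  seqs <- Biostrings::DNAStringSet(ref_sequences(x))
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

transition_of <- c(A = "G", G = "A", C = "T", T = "C")
transversions_of <- list(
  A = c("C", "T"), G = c("C", "T"), C = c("A", "G"), T = c("A", "G")
)

#' Simulate a diploid individual over a reference
#'
#' SNVs are placed by independent per-base sampling at `snv_rate`
#' (multiplied by `dense_multiplier` inside `dense_region`, emulating a
#' hyper-polymorphic locus). Each heterozygous variant is assigned to
#' exactly one haplotype; duplicated positions cannot arise because sites
#' are drawn without replacement.
#'
#' @param ref A `sim_reference` (or named character vector).
#' @param snv_rate Per-base SNV probability.
#' @param het_fraction Fraction of variants that are heterozygous.
#' @param dense_region Optional single-row interval tibble with elevated
#'   variant density.
#' @param dense_multiplier Rate multiplier inside `dense_region`.
#' @param titv_ratio Transition/transversion ratio used to draw alt alleles.
#' @param seed Integer seed.
#' @return A `diploid_truth`: list with `reference`, `haplotypes` (two
#'   named character vectors), and `variants`
#'   (`chrom`, `pos`, `ref`, `alt`, `genotype`, `haplotype`).
#' @export
simulate_diploid <- function(ref, snv_rate = 1e-3, het_fraction = 0.8,
                             dense_region = NULL, dense_multiplier = 10,
                             titv_ratio = 2, seed = 1L) {
  seqs <- ref_sequences(ref)
  if (snv_rate < 0 || het_fraction < 0 || het_fraction > 1) {
    stop("invalid rates", call. = FALSE)
  }
  if (!is.null(dense_region)) {
    dense_region <- as_intervals(dense_region, reference = seqs)
  }
  withr::with_seed(seed, {
    vars <- purrr::map(names(seqs), function(ch) {
      L <- nchar(seqs[[ch]])
      rate <- rep(snv_rate, L)
      if (!is.null(dense_region)) {
        dr <- dense_region[dense_region$chrom == ch, ]
        for (j in seq_len(nrow(dr))) {
          rate[(dr$start[j] + 1L):dr$end[j]] <- snv_rate * dense_multiplier
        }
      }
      pos <- which(stats::runif(L) < rate) - 1L
      if (length(pos) == 0) {
        return(NULL)
      }
      refb <- strsplit(substring(seqs[[ch]], pos + 1L, pos + 1L), "")
      refb <- vapply(refb, `[`, character(1), 1)
      is_ti <- stats::runif(length(pos)) < titv_ratio / (titv_ratio + 1)
      alt <- ifelse(is_ti, transition_of[refb],
        vapply(refb, function(b) sample(transversions_of[[b]], 1), character(1))
      )
      gt <- ifelse(stats::runif(length(pos)) < het_fraction, "het", "hom_alt")
      hap <- ifelse(gt == "het", sample(1:2, length(pos), TRUE), NA_integer_)
      tibble::tibble(
        chrom = ch, pos = pos, ref = refb, alt = unname(alt),
        genotype = gt, haplotype = hap
      )
    })
    variants <- dplyr::bind_rows(vars)
    if (nrow(variants) == 0) {
      variants <- tibble::tibble(
        chrom = character(), pos = integer(), ref = character(),
        alt = character(), genotype = character(), haplotype = integer()
      )
    }
    h1 <- seqs
    h2 <- seqs
    for (ch in unique(variants$chrom)) {
      v <- variants[variants$chrom == ch, ]
      s1 <- strsplit(seqs[[ch]], "")[[1]]
      s2 <- s1
      on1 <- v$genotype == "hom_alt" | (v$genotype == "het" & v$haplotype == 1L)
      on2 <- v$genotype == "hom_alt" | (v$genotype == "het" & v$haplotype == 2L)
      s1[v$pos[on1] + 1L] <- v$alt[on1]
      s2[v$pos[on2] + 1L] <- v$alt[on2]
      h1[[ch]] <- paste(s1, collapse = "")
      h2[[ch]] <- paste(s2, collapse = "")
    }
    structure(
      list(
        reference = if (inherits(ref, "sim_reference")) ref else
          structure(list(sequences = seqs, features = NULL), class = "sim_reference"),
        haplotypes = list(h1, h2),
        variants = variants,
        cpg = NULL,
        dmr_truth = NULL,
        non_cpg_rate = 0
      ),
      class = "diploid_truth"
    )
  })
}

#' @export
print.diploid_truth <- function(x, ...) {
  cat("<diploid_truth> ", nrow(x$variants), " variant(s)",
    if (!is.null(x$cpg)) paste0(", ", nrow(x$cpg), " CpG unit(s)") else "",
    "\n",
    sep = ""
  )
  invisible(x)
}

# Reference-strand CpG unit positions (0-based position of the + strand C).
cpg_positions <- function(seqs) {
  purrr::map(names(seqs), function(ch) {
    m <- gregexpr("CG", seqs[[ch]], fixed = TRUE)[[1]]
    if (m[1] == -1L) {
      return(NULL)
    }
    tibble::tibble(chrom = ch, pos = as.integer(m) - 1L)
  }) |> dplyr::bind_rows()
}

#' Assign true methylation levels to reference CpGs
#'
#' Each CpG unit (the symmetric pair of cytosines of one CpG dinucleotide)
#' receives a true methylation probability (beta) per condition, drawn
#' from a two-component Beta mixture that emulates the bimodal methylome.
#' CpGs inside `dmr_spec` intervals are shifted by `delta` in condition B,
#' planting recoverable differentially methylated regions. Non-CpG
#' cytosines carry `non_cpg_rate` (default 0) true methylation.
#'
#' @param truth A `diploid_truth` from [simulate_diploid()].
#' @param bimodal_mix `list(weight_low, low, high)`: mixing weight of the
#'   low-methylation component and the two `c(shape1, shape2)` Beta pairs.
#' @param dmr_spec Optional interval tibble with columns `chrom`, `start`,
#'   `end`, `delta` and optional `direction` (`"hyper"`, `"hypo"` or
#'   `"auto"`). `"auto"` shifts away from the nearer beta boundary (per
#'   region) so the planted effect survives clipping to `[0, 1]`.
#' @param non_cpg_rate True methylation of non-CpG cytosines.
#' @param seed Integer seed.
#' @return The `diploid_truth` with `cpg` (per-CpG `beta_a`, `beta_b`) and
#'   `dmr_truth` (planted regions with CpG counts and realized direction).
#' @export
assign_methylation <- function(truth,
                               bimodal_mix = list(weight_low = 0.45, low = c(1, 9), high = c(9, 1)),
                               dmr_spec = NULL, non_cpg_rate = 0, seed = 1L) {
  stopifnot(inherits(truth, "diploid_truth"))
  seqs <- ref_sequences(truth$reference)
  cpg <- cpg_positions(seqs)
  withr::with_seed(seed, {
    n <- nrow(cpg)
    low <- stats::runif(n) < bimodal_mix$weight_low
    beta_a <- numeric(n)
    beta_a[low] <- stats::rbeta(sum(low), bimodal_mix$low[1], bimodal_mix$low[2])
    beta_a[!low] <- stats::rbeta(sum(!low), bimodal_mix$high[1], bimodal_mix$high[2])
    beta_b <- beta_a
    dmr_truth <- NULL
    if (!is.null(dmr_spec) && nrow(dmr_spec) > 0) {
      dmr_spec <- tibble::as_tibble(dmr_spec)
      if (!"direction" %in% names(dmr_spec)) dmr_spec$direction <- "auto"
      realized <- character(nrow(dmr_spec))
      n_cpgs <- integer(nrow(dmr_spec))
      for (j in seq_len(nrow(dmr_spec))) {
        inside <- cpg$chrom == dmr_spec$chrom[j] &
          cpg$pos >= dmr_spec$start[j] & cpg$pos < dmr_spec$end[j]
        n_cpgs[j] <- sum(inside)
        if (n_cpgs[j] == 0) {
          warning(
            "dmr_spec interval ",
            fmt_interval(dmr_spec$chrom[j], dmr_spec$start[j], dmr_spec$end[j]),
            " contains no CpG"
          )
          realized[j] <- "none"
          next
        }
        dir <- dmr_spec$direction[j]
        if (dir == "auto") {
          dir <- if (mean(beta_a[inside]) > 0.5) "hypo" else "hyper"
        }
        sgn <- if (dir == "hyper") 1 else -1
        beta_b[inside] <- clip01(beta_a[inside] + sgn * abs(dmr_spec$delta[j]))
        realized[j] <- dir
      }
      dmr_truth <- dplyr::mutate(dmr_spec, n_cpgs = n_cpgs, realized_direction = realized)
    }
    truth$cpg <- dplyr::mutate(cpg, beta_a = beta_a, beta_b = beta_b)
    truth$dmr_truth <- dmr_truth
    truth$non_cpg_rate <- non_cpg_rate
    truth
  })
}

#' Write truth variants as VCF v4.2
#'
#' @param truth A `diploid_truth`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_vcf <- function(truth, path) {
  v <- truth$variants
  gt <- dplyr::case_when(
    v$genotype == "hom_alt" ~ "1|1",
    v$genotype == "het" & v$haplotype == 1L ~ "1|0",
    TRUE ~ "0|1"
  )
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=capmeth_truth",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ttruth"
  )
  body <- sprintf(
    "%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT\t%s",
    v$chrom, v$pos + 1L, v$ref, v$alt, gt
  )
  writeLines(c(header, body), path)
  invisible(path)
}
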