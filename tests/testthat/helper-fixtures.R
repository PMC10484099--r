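# Shared fixtures, built once per test run. Everything is generated in
# code; nothing is read from disk.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# 50 kb single-chromosome reference used across modules.
shared_ref <- function() {
  memo("ref50", function() {
    simulate_reference(
      n_chrom = 1, length = 50000, gc_target = 0.5, cpg_rate = 0.02, seed = 42
    )
  })
}

# Diploid truth over shared_ref with a variant-dense region and bimodal
# methylation, no planted DMRs.
shared_truth <- function() {
  memo("truth50", function() {
    truth <- simulate_diploid(
      shared_ref(),
      snv_rate = 1e-3, het_fraction = 0.8,
      dense_region = tibble::tibble(chrom = "chrS1", start = 5000, end = 15000),
      dense_multiplier = 10, seed = 7
    )
    assign_methylation(truth, seed = 8)
  })
}

# Panel tiling the central 30 kb of shared_ref at 3X.
shared_design <- function() {
  memo("design50", function() {
    targets <- tibble::tibble(
      chrom = "chrS1", start = c(5000, 20000), end = c(18000, 35000),
      group = c("locus", "promoters")
    )
    probes <- boost_probes(tile_probes(targets, shared_ref()))
    panel_design(probes, targets, params = list(probe_len = 120, tiling = 3))
  })
}

# Panel tiling the whole of shared_ref, for depth-hungry genotyping runs.
whole_genome_design <- function() {
  memo("wg_design", function() {
    targets <- tibble::tibble(chrom = "chrS1", start = 0L, end = 50000L, group = "locus")
    panel_design(tile_probes(targets, shared_ref()), targets,
      params = list(probe_len = 120, tiling = 3)
    )
  })
}

# Converted read sets over the whole-genome panel (shared by the
# conversion-QC and concordance checks).
shared_conv_obs <- function(kind) {
  memo(paste0("obs_", kind), function() {
    simulate_capture_reads(
      shared_truth(), whole_genome_design(),
      n_fragments = 6000,
      conversion = conversion_model(kind),
      seed = if (kind == "BS") 101 else 102
    )
  })
}

shared_conv_cyt <- function(kind) {
  memo(paste0("cyt_", kind), function() {
    call_cytosines(shared_conv_obs(kind), shared_ref())
  })
}

# Tiny handmade reference with known cytosine layout:
# pos:  0123456789...
# seq:  A A C G T C T G A C G T
# CpG units at pos 2 (C2/G3) and pos 9 (C9/G10); C5 is CHG (C-T-G).
hand_ref <- function() {
  c(chrT = "AACGTCTGACGT")
}

# Build an observation row by hand (one fragment).
obs_row <- function(chrom, start, seq, strand = "OT", library = "DNA",
                    haplotype = 1L, condition = "A", id = "r1") {
  tibble::tibble(
    read_id = id, chrom = chrom, start = as.integer(start),
    end = as.integer(start + nchar(seq)), strand = strand,
    haplotype = haplotype, library = library, condition = condition, seq = seq
  )
}

# Random interval set on one chromosome, for interval-arithmetic oracles.
random_intervals <- function(n, max_pos = 1000, seed = 1) {
  withr::with_seed(seed, {
    start <- sample.int(max_pos - 20, n)
    width <- sample.int(60, n)
    tibble::tibble(
      chrom = "chrT",
      start = start,
      end = pmin(start + width, max_pos)
    )
  })
}

# Per-base logical mask over [0, max_pos) for an interval tibble.
base_mask <- function(x, max_pos) {
  m <- rep(FALSE, max_pos)
  for (i in seq_len(nrow(x))) {
    if (x$end[i] > x$start[i]) m[(x$start[i] + 1):x$end[i]] <- TRUE
  }
  m
}
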