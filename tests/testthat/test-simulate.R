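test_that("identical seeds reproduce identical references, different seeds differ", {
  a <- simulate_reference(length = 2000, seed = 3)
  b <- simulate_reference(length = 2000, seed = 3)
  expect_identical(a$sequences, b$sequences)
  c <- simulate_reference(length = 2000, seed = 4)
  expect_false(identical(a$sequences, c$sequences))
  fa <- withr::local_tempfile(fileext = ".fa")
  fb <- withr::local_tempfile(fileext = ".fa")
  write_fasta(a, fa)
  write_fasta(b, fb)
  expect_identical(readLines(fa), readLines(fb))
})

test_that("generated sequence hits GC and CpG targets at 100 kb", {
  ref <- simulate_reference(length = 100000, gc_target = 0.5, cpg_rate = 0.02, seed = 21)
  gc <- gc_fraction_of(ref$sequences[[1]])
  expect_gte(gc, 0.48)
  expect_lte(gc, 0.52)
  n_cpg <- length(gregexpr("CG", ref$sequences[[1]], fixed = TRUE)[[1]])
  expect_gte(n_cpg / 100000, 0.02 * 0.8)
  expect_lte(n_cpg / 100000, 0.02 * 1.2)
})

test_that("infeasible CpG density is rejected", {
  expect_error(
    simulate_reference(length = 2000, gc_target = 0.3, cpg_rate = 0.2, seed = 1),
    "infeasible"
  )
})

test_that("planted repeats and paralogs are recorded as features", {
  plain <- simulate_reference(length = 5000, seed = 5)
  expect_equal(nrow(plain$features), 0L)
  planted <- simulate_reference(
    length = 20000,
    repeat_spec = list(n = 2, unit_len = 10, n_copies = 8),
    paralog_spec = list(length = 1000, divergence = 0.05),
    seed = 5
  )
  expect_equal(sum(planted$features$type == "repeat"), 2L)
  expect_equal(sum(planted$features$type == "paralog_copy"), 1L)
  rep1 <- planted$features[planted$features$type == "repeat", ][1, ]
  tract <- substr(planted$sequences[[rep1$chrom]], rep1$start + 1, rep1$end)
  unit <- substr(tract, 1, 10)
  expect_equal(tract, strrep(unit, 8))
})

test_that("zero SNV rate leaves haplotypes identical to the reference", {
  ref <- simulate_reference(length = 2000, seed = 6)
  truth <- simulate_diploid(ref, snv_rate = 0, seed = 6)
  expect_equal(nrow(truth$variants), 0L)
  expect_identical(truth$haplotypes[[1]], ref$sequences)
  expect_identical(truth$haplotypes[[2]], ref$sequences)
})

test_that("variant counts follow the rate and het assignment follows het_fraction", {
  ref <- shared_ref()
  truth <- simulate_diploid(ref, snv_rate = 1e-3, het_fraction = 1, seed = 9)
  n <- nrow(truth$variants)
  expect_gte(n, 50 - 3 * sqrt(50))
  expect_lte(n, 50 + 3 * sqrt(50))
  expect_true(all(truth$variants$genotype == "het"))
  expect_true(all(truth$variants$ref != truth$variants$alt))
  # haplotypes differ from the reference exactly at the listed variants
  v <- truth$variants[truth$variants$chrom == "chrS1", ]
  s0 <- strsplit(ref$sequences[["chrS1"]], "")[[1]]
  s1 <- strsplit(truth$haplotypes[[1]][["chrS1"]], "")[[1]]
  s2 <- strsplit(truth$haplotypes[[2]][["chrS1"]], "")[[1]]
  diff1 <- which(s0 != s1) - 1L
  diff2 <- which(s0 != s2) - 1L
  expect_setequal(c(diff1, diff2), v$pos)
})

test_that("a dense region concentrates variants", {
  ref <- shared_ref()
  truth <- shared_truth()
  v <- truth$variants
  dense <- v$pos >= 5000 & v$pos < 15000
  rate_in <- sum(dense) / 10000
  rate_out <- sum(!dense) / 40000
  expect_gt(rate_in, 4 * rate_out)
})

test_that("methylation assignment is condition-neutral without a dmr_spec", {
  truth <- shared_truth()
  expect_equal(truth$cpg$beta_a, truth$cpg$beta_b)
  expect_true(all(truth$cpg$beta_a >= 0 & truth$cpg$beta_a <= 1))
})

test_that("planted deltas shift condition B by the requested amount", {
  ref <- shared_ref()
  truth <- simulate_diploid(ref, snv_rate = 0, seed = 1)
  spec <- tibble::tibble(
    chrom = "chrS1", start = 1000L, end = 3000L, delta = 0.3, direction = "hyper"
  )
  truth <- assign_methylation(truth, dmr_spec = spec, seed = 2)
  inside <- truth$cpg$pos >= 1000 & truth$cpg$pos < 3000
  expect_equal(
    truth$cpg$beta_b[inside],
    pmin(1, truth$cpg$beta_a[inside] + 0.3)
  )
  expect_equal(truth$cpg$beta_b[!inside], truth$cpg$beta_a[!inside])
  expect_equal(truth$dmr_truth$realized_direction, "hyper")
})

test_that("a CpG-free dmr interval warns and the 'auto' direction dodges clipping", {
  ref <- c(chrT = paste0(strrep("AT", 3000), "CG", strrep("AT", 500)))
  truth <- simulate_diploid(ref, snv_rate = 0, seed = 1)
  expect_warning(
    assign_methylation(
      truth,
      dmr_spec = tibble::tibble(chrom = "chrT", start = 0L, end = 100L, delta = 0.3),
      seed = 3
    ),
    "no CpG"
  )
  # auto direction: a high-methylation region is shifted down, not clipped
  truth2 <- assign_methylation(
    truth,
    bimodal_mix = list(weight_low = 0, low = c(1, 9), high = c(50, 1)),
    dmr_spec = tibble::tibble(
      chrom = "chrT", start = 6000L, end = 6002L, delta = 0.3, direction = "auto"
    ),
    seed = 4
  )
  expect_equal(truth2$dmr_truth$realized_direction, "hypo")
  expect_equal(truth2$cpg$beta_b, pmax(0, truth2$cpg$beta_a - 0.3))
})

test_that("a pure high-methylation mixture has mean beta above 0.9", {
  ref <- shared_ref()
  truth <- simulate_diploid(ref, snv_rate = 0, seed = 1)
  truth <- assign_methylation(
    truth,
    bimodal_mix = list(weight_low = 0, low = c(1, 9), high = c(10, 0.5)),
    seed = 5
  )
  expect_gt(mean(truth$cpg$beta_a), 0.9)
})

test_that("unconverted error-free reads match their haplotype exactly", {
  truth <- shared_truth()
  design <- shared_design()
  obs <- simulate_capture_reads(truth, design,
    n_fragments = 300,
    conversion = conversion_model("none"), seq_error = 0, seed = 31
  )
  for (i in seq_len(min(50, nrow(obs)))) {
    hap <- truth$haplotypes[[obs$haplotype[i]]][[obs$chrom[i]]]
    expect_identical(obs$seq[i], substr(hap, obs$start[i] + 1, obs$end[i]))
  }
})

test_that("complete conversion on unmethylated DNA leaves no C on the read strand", {
  truth <- shared_truth()
  truth$cpg$beta_a <- 0 # fully unmethylated
  design <- shared_design()
  obs <- simulate_capture_reads(truth, design,
    n_fragments = 300,
    conversion = conversion_model("BS", failure_rate = 0, overconversion_rate = 0),
    seq_error = 0, seed = 32
  )
  ot <- obs[obs$strand == "OT", ]
  ob <- obs[obs$strand == "OB", ]
  expect_false(any(grepl("C", ot$seq, fixed = TRUE)))
  expect_false(any(grepl("G", ob$seq, fixed = TRUE)))
})

test_that("insert lengths centre on the fragmentation target", {
  truth <- shared_truth()
  design <- shared_design()
  obs <- simulate_capture_reads(truth, design,
    n_fragments = 10000,
    insert_mean = 250, insert_sd = 30, off_target_rate = 1, seed = 33
  )
  expect_gt(nrow(obs), 5000)
  m <- mean(obs$end - obs$start)
  expect_gte(m, 249)
  expect_lte(m, 251)
})

test_that("capture enriches the panel footprint at least 10-fold", {
  truth <- shared_truth()
  design <- shared_design()
  obs <- simulate_capture_reads(truth, design,
    n_fragments = 6000,
    off_target_rate = 0.01, seed = 34
  )
  dt <- depth_track(obs, truth$reference)
  fp <- base_mask(
    interval_normalize(design$probes[c("chrom", "start", "end")]),
    50000
  )
  on_t <- mean(dt$chrS1[fp])
  off_t <- mean(dt$chrS1[!fp])
  expect_gte(on_t / max(off_t, 1e-9), 10)
})

test_that("read simulation is deterministic and origins are recoverable", {
  truth <- shared_truth()
  design <- shared_design()
  a <- simulate_capture_reads(truth, design, n_fragments = 500, seed = 35)
  b <- simulate_capture_reads(truth, design, n_fragments = 500, seed = 35)
  expect_identical(a, b)
  expect_true(all(a$end <= 50000))
  expect_true(all(a$haplotype %in% 1:2))
})

test_that("counts-level simulation converges to truth betas at high depth", {
  truth <- shared_truth()
  cnt <- simulate_counts(truth,
    depth = 500,
    conversion = conversion_model("none"), seed = 36
  )
  rmse <- sqrt(mean((cnt$beta - truth$cpg$beta_a)^2))
  bound <- sqrt(mean(truth$cpg$beta_a * (1 - truth$cpg$beta_a)) / 500)
  expect_lte(rmse, 1.1 * bound)
})
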