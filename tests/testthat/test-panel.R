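# Brute-force per-base probe depth over a target region.
probe_depth_at <- function(probes, chrom, positions) {
  vapply(positions, function(p) {
    sum(probes$chrom == chrom & probes$start <= p & p < probes$end)
  }, numeric(1))
}

test_that("a region equal to the probe length yields exactly one spanning probe", {
  ref <- c(chrT = strrep("ACGT", 100))
  probes <- tile_probes(
    tibble::tibble(chrom = "chrT", start = 40L, end = 160L),
    ref,
    probe_len = 120, tiling_density = 1
  )
  expect_equal(nrow(probes), 1L)
  expect_equal(probes$start, 40L)
  expect_equal(probes$end, 160L)
})

test_that("density 3 steps 40 bases and covers every target base", {
  ref <- c(chrT = strrep("ACGT", 100))
  probes <- tile_probes(
    tibble::tibble(chrom = "chrT", start = 0L, end = 200L),
    ref,
    probe_len = 120, tiling_density = 3
  )
  expect_equal(probes$start, c(0L, 40L, 80L))
  expect_equal(nrow(probes), 3L)
  depth <- probe_depth_at(probes, "chrT", 0:199)
  expect_true(all(depth >= 1))
})

test_that("sub-probe regions get one centered flank-extended probe, clipped at bounds", {
  ref <- c(chrT = strrep("ACGT", 100))
  probes <- tile_probes(
    tibble::tibble(chrom = "chrT", start = 180L, end = 240L),
    ref
  )
  expect_equal(nrow(probes), 1L)
  expect_equal(probes$length, 120L)
  expect_true(probes$start <= 180L && probes$end >= 240L)
  # region at the chromosome start: probe clipped, still covers the region
  edge <- tile_probes(tibble::tibble(chrom = "chrT", start = 0L, end = 30L), ref)
  expect_equal(edge$start, 0L)
  expect_true(edge$end >= 30L)
})

test_that("probes containing ambiguous bases are dropped", {
  ref <- c(chrT = paste0(strrep("AC", 100), strrep("N", 40), strrep("GT", 100)))
  probes <- tile_probes(
    tibble::tibble(chrom = "chrT", start = 0L, end = 440L),
    ref,
    probe_len = 100, tiling_density = 1
  )
  # starts would be {0, 100, 200, 300, 340}; the probe at 200 spans the N run
  expect_true(all(!grepl("N", probes$seq)))
  expect_equal(probes$start, c(0L, 100L, 300L, 340L))
})

test_that("tiled depth matches brute-force enumeration and mean depth tracks density", {
  ref <- shared_ref()
  withr::with_seed(99, {
    for (k in c(1, 2, 3, 5)) {
      start <- sample.int(30000, 1)
      len <- 120 * 10 + sample.int(2000, 1)
      tg <- tibble::tibble(chrom = "chrS1", start = start, end = start + len)
      probes <- tile_probes(tg, ref, tiling_density = k)
      depth <- probe_depth_at(probes, "chrS1", start:(start + len - 1))
      expect_true(all(depth >= 1))
      expect_gte(mean(depth), k - 0.5)
      expect_lte(mean(depth), k + 0.5)
    }
  })
})

test_that("consensus mask follows least/most stringent set semantics", {
  tracks <- list(
    tibble::tibble(chrom = "chrT", start = 0L, end = 100L),
    tibble::tibble(chrom = "chrT", start = 50L, end = 150L),
    tibble::tibble(chrom = "chrT", start = 60L, end = 80L)
  )
  least <- consensus_mask(tracks, "least_stringent")
  expect_equal(least, tibble::tibble(chrom = "chrT", start = 60L, end = 80L))
  most <- consensus_mask(tracks, "most_stringent")
  expect_equal(most, tibble::tibble(chrom = "chrT", start = 0L, end = 150L))
  single <- tibble::tibble(chrom = "chrT", start = 5L, end = 9L)
  expect_equal(consensus_mask(list(single), "least_stringent"), single)
  expect_equal(consensus_mask(list(single), "most_stringent"), single)
  expect_error(consensus_mask(list()), "at least one")
})

test_that("least-stringent is a subset and most-stringent a superset of every track", {
  tracks <- purrr::map(1:4, ~ random_intervals(12, seed = .x))
  least <- base_mask(consensus_mask(tracks, "least_stringent"), 1000)
  most <- base_mask(consensus_mask(tracks, "most_stringent"), 1000)
  for (tr in tracks) {
    m <- base_mask(tr, 1000)
    expect_true(all(!least | m)) # least subset of m
    expect_true(all(!m | most)) # m subset of most
  }
})

test_that("mask filtering annotates overlap and applies a strict threshold", {
  ref <- c(chrT = strrep("ACGT", 200))
  probes <- tile_probes(
    tibble::tibble(chrom = "chrT", start = 0L, end = 480L),
    ref,
    probe_len = 120, tiling_density = 1
  ) # probes at 0, 120, 240, 360
  mask <- tibble::tibble(chrom = "chrT", start = c(120L, 330L), end = c(240L, 360L))
  out <- filter_masked_probes(probes, mask, max_masked_fraction = 0.25)
  # fully masked probe removed; 30/120 = 0.25 not exceeded (strict >) retained
  expect_equal(out$start, c(0L, 240L, 360L))
  expect_equal(out$masked_bases, c(0L, 30L, 0L))
})

test_that("GC boosting follows the schedule, is monotone and capped", {
  probes <- tibble::tibble(
    probe_id = sprintf("p%d", 1:6), chrom = "chrT",
    start = seq(0, 600, by = 120)[1:6], end = seq(120, 720, by = 120)[1:6],
    length = 120L, group = "t",
    gc_fraction = c(0.40, 0.60, 0.62, 0.68, 0.74, 1.0),
    masked_bases = 0L, copy_number = 1L, seq = NA_character_
  )
  out <- boost_probes(probes)
  expect_equal(out$copy_number, c(1L, 1L, 2L, 4L, 8L, 16L))
  withr::with_seed(5, {
    gc <- runif(200)
    p2 <- probes[rep(1, 200), ]
    p2$gc_fraction <- gc
    cn <- boost_probes(p2)$copy_number
    ord <- order(gc)
    expect_true(all(diff(cn[ord]) >= 0))
    expect_true(all(cn >= 1 & cn <= 16))
  })
  expect_error(boost_schedule(copies = c(4L, 2L, 1L, 8L, 16L)), "monotone")
  expect_equal(boost_probes(probes, cap = 4L)$copy_number, c(1L, 1L, 2L, 4L, 4L, 4L))
})

test_that("in-silico coverage counts unique footprint bases only", {
  ref <- c(chrT = strrep("ACGT", 300))
  tg <- tibble::tibble(chrom = "chrT", start = 0L, end = 1000L)
  # exact tiling
  full <- panel_design(
    tile_probes(tg, ref, probe_len = 100, tiling_density = 1), tg
  )
  expect_equal(in_silico_coverage(full)$coverage, c(1, 1))
  # no probes
  none <- panel_design(
    tibble::tibble(
      chrom = character(), start = integer(), end = integer(),
      length = integer(), group = character(), gc_fraction = numeric(),
      copy_number = integer()
    ),
    tg
  )
  expect_equal(in_silico_coverage(none)$coverage, c(0, 0))
  # one 120-base probe on a 1000-base target
  one <- panel_design(
    tibble::tibble(
      chrom = "chrT", start = 100L, end = 220L, length = 120L,
      group = "t", gc_fraction = 0.5, copy_number = 1L
    ),
    tg
  )
  expect_equal(in_silico_coverage(one)$coverage, c(0.12, 0.12))
  # invariant under probe duplication (copy-number boosting)
  boosted <- one
  boosted$probes$copy_number <- 16L
  expect_equal(in_silico_coverage(boosted), in_silico_coverage(one))
})

test_that("panel summary accounting matches direct enumeration", {
  tg <- tibble::tibble(chrom = "chrT", start = 0L, end = 1000L)
  empty <- panel_design(
    tibble::tibble(
      chrom = character(), start = integer(), end = integer(),
      length = integer(), group = character(), copy_number = integer()
    ),
    tg
  )
  s0 <- panel_summary(empty)
  expect_equal(s0$n_probes, c(0L, 0L))
  expect_equal(s0$footprint_kb, c(0, 0))
  disjoint <- panel_design(
    tibble::tibble(
      chrom = "chrT", start = c(0L, 200L, 400L), end = c(120L, 320L, 520L),
      length = 120L, group = "t", copy_number = c(1L, 2L, 16L)
    ),
    tg
  )
  s1 <- panel_summary(disjoint)
  expect_equal(s1$footprint_kb[s1$group == "total"], 0.36)
  expect_equal(s1$n_synthesized[s1$group == "total"], 19L)
  overlapping <- panel_design(
    tibble::tibble(
      chrom = "chrT", start = c(0L, 40L), end = c(120L, 160L),
      length = 120L, group = "t", copy_number = 1L
    ),
    tg
  )
  s2 <- panel_summary(overlapping)
  expect_equal(s2$footprint_kb[s2$group == "total"], 0.16)
  expect_equal(s2$n_probes[s2$group == "total"], 2L)
})
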