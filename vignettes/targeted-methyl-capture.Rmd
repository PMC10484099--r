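---
title: "Targeted methyl-capture panels: design, simulation and analysis with capmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted methyl-capture panels: design, simulation and analysis with capmeth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capmeth)
```

## The problem

Hybridization-capture methyl sequencing enriches a defined set of genomic
regions — typically a disease-associated locus plus a panel of regulatory
regions such as gene promoters — and reads out both genetic variation and
CpG methylation from the same captured DNA. Splitting one captured library
into an unconverted (DNA) aliquot and one or two converted aliquots
(bisulfite, BS, or enzymatic, EM) yields variant calls and methylomes that
are directly comparable because they come from the same molecules.

capmeth implements the computational side of that workflow as composable,
tibble-first functions: panel design, an explicit generative model of the
sequencing experiment, and the downstream quantification, differential
methylation and genotyping rules. The simulator is first-class, tested
code: every downstream module is validated against the ground truth it
emits, without any external data.

## Panel design

### Probe tiling

Capture probes are fixed-length oligos (default `probe_len = 120` nt, the
standard for RNA bait designs). For a tiling density $k$ — the average
number of probes covering each target base — probes are laid left to right
with step $\mathrm{round}(L/k)$ and the final probe of each region is
right-aligned to the region end. The tiling density is stated by panel
vendors but the placement rule is not; this rule was chosen because it
guarantees (a) every target base is covered by at least one probe and (b)
the mean per-base depth is within $\pm 0.5$ of $k$ for regions at least
ten probes long. Both properties are tested against brute-force per-base
enumeration.

Regions shorter than one probe (promoter targets are typically 100–200 bp)
receive a single probe centred on the region and extended into the flanks,
clipped at chromosome bounds. The flank extension mirrors the proximal
off-target capture that hybridization panels show in practice (the reads
extending past probe ends), and is itself measurable with
`flank_coverage()`. Probes containing any ambiguous base (N) are dropped
rather than repaired: they could not be synthesized.

### Consensus masking

Repetitive sequence cross-hybridizes; designs therefore mask repeats
before placing probes. With several maskers available (RepeatMasker-style
annotations, k-mer maskers, mappability tracks), `consensus_mask()`
supports two policies: *least stringent* masks a base only when **every**
masker flags it (set intersection — keeps the most designable sequence),
and *most stringent* masks anything any masker flags (union). The
least-stringent policy is the default used throughout, matching the design
philosophy of maximizing coverage of a polymorphic locus.

A per-probe rejection rule is needed on top of the mask;
`filter_masked_probes()` removes a probe when its masked fraction
**strictly exceeds** `max_masked_fraction` (default 0.25). Vendors do not
publish their exact rejection rule; the 0.25 tolerance is a declared
default that preserves coverage at repeat edges while discarding probes
dominated by repeat sequence.

### GC boosting

GC-rich fragments capture and amplify poorly. Boosting compensates by
synthesizing extra copies of probes over GC-rich sequence, up to a 16×
cap. The published descriptions state the cap but not the mapping, so the
default `boost_schedule()` is a doubling ladder, monotone in GC and
configurable:

| GC fraction | copies |
|---|---|
| ≤ 0.60 | 1 |
| (0.60, 0.65] | 2 |
| (0.65, 0.70] | 4 |
| (0.70, 0.75] | 8 |
| > 0.75 | 16 |

`in_silico_coverage()` reports the fraction of target bases under at least
one probe footprint. Copy numbers are deliberately ignored there — whether
the quoted in-silico coverage of a commercial design counts boosted copies
is not documented, and unique footprint is the conservative, invariant
choice (boosting then provably never changes reported coverage).

## The simulator

`simulate_reference()` draws chromosomes from a first-order Markov chain
calibrated by fixed-point iteration so the stationary GC content and CpG
dinucleotide rate hit their targets (defaults 0.45 and 0.02; the CpG rate
is promoter-like rather than genome-average because capture panels are
promoter-enriched). Tandem repeats and a diverged paralog (a pseudogene
stand-in) can be planted and are recorded as features.

`simulate_diploid()` places SNVs by per-base sampling at `snv_rate`
(default $10^{-3}$), multiplied inside a designated variant-dense region
to emulate a hyper-polymorphic locus such as an HLA class II region. Each
heterozygous variant lands on exactly one haplotype. `assign_methylation()`
gives every CpG unit a true methylation probability $\beta$ from a
two-component Beta mixture (defaults: 45% low, Beta(1, 9); 55% high,
Beta(9, 1)), the classic bimodal methylome. A `dmr_spec` shifts chosen
intervals by $\delta$ in condition B. Its `direction = "auto"` mode shifts
each region away from the nearer boundary of $[0,1]$: with a bimodal
background, a fixed-sign shift of 0.3 would be clipped to nearly nothing
at already-methylated regions, making planted effects unrecoverable by
construction rather than by any property of the caller.

`simulate_capture_reads()` models the experiment: fragment starts are
uniform; insert lengths are Normal(250, 30) truncated to
$[\mathrm{read\_len},\, 2 \times \mathrm{insert\_mean}]$ (the 250 bp
fragmentation target of capture protocols); a fragment is retained with
probability $\min(1,\ c_0 \sum \mathrm{copy\_number})$ over the probes it
overlaps ($c_0 = 0.2$), the simplest model under which probe boosting is
observable in coverage; off-target fragments are admitted at
`off_target_rate` (default 0.01, which yields the ≥ 10× on/off-target
enrichment the tests check). Each retained molecule picks a haplotype and
a conversion strand (the library is directional: OT reads interrogate
top-strand cytosines, OB reads bottom-strand cytosines), draws per-CpG
methylation Bernoulli($\beta$), and is then converted and sequenced with
i.i.d. errors.

The conversion chemistry is two parameters per library:
`failure_rate`, the probability an unmethylated C survives conversion
(apparent methylation), and `overconversion_rate`, the probability a
methylated C converts anyway. Defaults are BS 1.5% / EM 0.6% failure —
chosen to echo the residual non-CpG methylation levels typically reported
for the two chemistries — and 0.5% overconversion, a stand-in for an
undocumented quantity. These defaults are study conditions, not estimates.

Reads carry their true origin (chromosome, start, haplotype, conversion
strand), so quantification and genotyping are tested without
re-implementing an aligner; alignment is deliberately out of scope, and
paired FASTQ is still emitted for users who want to run external
pipelines. One observation row is one molecule, so overlapping mates can
never double-count evidence.

`simulate_counts()` is the counts-level fast path: it draws per-CpG
methylated counts Binomial(depth, $p$) with
$p = \beta(1-\mathrm{over}) + (1-\beta)\,\mathrm{fail}$, equivalent in
distribution to the read path at fixed per-site depth. Calibration
properties that require exact uniform depth (the RMSE bound below) use it.

## Quantification

`call_cytosines()` counts, for every reference cytosine a read's
conversion strand can interrogate, C calls (methylated) versus T calls
(unmethylated); other mismatches are ignored for methylation. Reads never
inform positions their conversion strand cannot interrogate — a
directional-protocol correctness requirement. Context (CpG/CHG/CHH) comes
from the reference trinucleotide, never from reads.

`merge_cpg_strands()` merges the symmetric pair of cytosines of each CpG
by summing counts, reporting the unit at the plus-strand coordinate; the
methylation level is $\beta = m/(m+u)$, methylated calls over total calls.
`filter_coverage()` applies the standard depth filter; the comparison is
**inclusive** (`>= min_cov`, default 10), since "filtered for 10X" in
common usage keeps sites at exactly 10.

Conversion efficiency is estimated from non-CpG cytosines: outside neurons
and stem cells true non-CpG methylation is near zero, so the apparent
methylation fraction at CHG+CHH sites estimates the conversion failure
rate. The pooled fraction is primary; per-context (CHG vs CHH) fractions
are reported alongside, since published conversion figures rarely state
which convention they use.

With ideal chemistry and uniform depth $d$, the per-CpG estimate is
unbiased binomial, so its RMSE obeys
$\mathrm{RMSE} \le 1.1\sqrt{\overline{\beta(1-\beta)}/d}$ — the 1.1 factor
absorbs sampling noise of the bound itself. This is tested with the
`none` conversion model because chemistry bias (≈ failure_rate at
unmethylated sites) is a separate, separately-tested phenomenon.

## Differential methylation

The caller implements fixed effect-size rules, not statistical tests (so
no multiple-testing machinery applies — a deliberate property of the
method being reproduced, documented as such):

* **DMP**: a CpG covered in both samples with
  $|\Delta\beta| > 0.1$ (strict: exactly 0.1 is not a DMP).
  $\Delta\beta = \beta_A - \beta_B$ with A the first-named sample; the
  sign is reported, never folded.
* **DMR**: a maximal run of at least 2 *consecutive shared* CpGs that are
  all DMPs with the same direction. Requiring a consistent direction makes
  hyper- and hypomethylated regions distinct objects. No genomic gap limit
  applies by default (shared-CpG adjacency can legitimately span sparse
  panel gaps); `max_gap` is available.
* **Cross-method consensus**: a CpG measured by both chemistries is kept
  when $|\Delta| > 0.10$ in one method, $|\Delta| \ge 0.05$ in the other,
  and the direction agrees.

`annotate_nearest_feature()` attaches the nearest promoter/gene. Nearness
is midpoint distance; the reported distance is the gap to the feature
interval (0 inside); midpoint ties go to the lexicographically smallest
feature id and are flagged.

## Genotyping

`call_genotypes()` is an explicit minimal diploid model: flat prior over
\{hom_ref, het, hom_alt\}, fixed per-base error rate $e$, and per-read
likelihoods $P(b \mid g, e)$ with a het emitting each allele with
probability 1/2. The call is the posterior argmax and GQ is the
phred-scaled probability the call is wrong. Sites with informative depth
below `min_depth` (default 30, the customary capture-genotyping filter)
are emitted as *no-calls* rather than low-confidence calls, which keeps
replicate-overlap statistics well defined. Only SNVs are modelled.

Converted libraries confound specific allele pairs: on an OT read every
unmethylated C reads as T, so C/T alleles are indistinguishable; likewise
G/A on OB reads. In `bisulfite_aware` mode such reads are excluded from
the informative set at those sites. The complementary strand is
unaffected (an OB read reports a top-strand C faithfully), so genuine
C>T variants remain callable from half the reads, while the
methylation-driven artifacts the naive mode produces at unmethylated CpGs
vanish entirely — both behaviours are asserted in the test suite.

## What the simulator does and does not emulate

Emulated: diploid haplotypes with a variant-dense region, bimodal CpG
methylation with plantable DMRs, probe-weighted capture with boosting and
off-target admission, directional BS/EM conversion with failure and
overconversion, uniform sequencing error, proximal flank capture.

Not emulated: alignment and mapping ambiguity (reads carry their origin),
PCR duplicates and UMI behaviour, per-cycle quality profiles and M-bias,
indels and structural variation, batch effects between libraries. Passing
tests therefore demonstrate correctness of the *rules and estimators* on
an idealized experiment; they do not certify performance on real reads,
where mapping and duplication dominate error budgets.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere internally; conversion to
  1-based formats (Bismark coverage, VCF) happens only in readers/writers,
  and writers recompute derived fields from counts so
  write → read → write is byte-stable.
* All samplers take an integer `seed` and restore RNG state afterwards;
  identical seeds give byte-identical outputs.
* Empty inputs: empty probe sets yield zero coverage and all-zero
  summaries; an empty mask-track list, zero shared CpGs, an empty feature
  set and zero retained fragments are errors (the last with advice to
  raise `n_fragments`); a zero-width flank window is reported NA.
* Ties: equal genotype posteriors resolve to the first of
  hom_ref/het/hom_alt; equal alt-allele support resolves in base order;
  feature-midpoint ties resolve lexicographically and are flagged.
* The Markov calibration rejects infeasible requests
  (`cpg_rate` > 0.95 × gc/2, the attainable bound for a first-order
  chain).

## Problem sizes

The shipped test-suite and acceptance scenarios run on 50 kb (module
checks, conversion QC at ≥ 50,000 non-CpG calls, genotyping at mean depth
≈ 60) and 200 kb (full-workflow smoke) genomes with 6,000–20,000 fragments
per library — sizes chosen so a complete run takes a few minutes on one
CPU while leaving every estimate's sampling error an order of magnitude
inside the property tolerances (e.g. conversion-rate recovery to ±0.002
uses > 300,000 non-CpG calls, s.e. ≈ 0.0002).

## Limitations

The capture model is linear-with-saturation in summed probe copy number;
real capture efficiency saturates earlier and depends on GC, fragment
length and hybridization kinetics, so boosting effects here are
qualitative. The genotype model's fixed error rate ignores quality
recalibration. Conversion parameters are library-wide constants, not
fragment-level random effects. None of these affect the definitions of
the estimators, which is what this package fixes in code.
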