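---
title: "Methods: spliced-alignment transformation and variant-call benchmarking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spliced-alignment transformation and variant-call benchmarking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicevar)
```

## The problem

Variant callers built for DNA alignments assume each read is a contiguous
block of aligned bases. Spliced long-read RNA-seq alignments violate that
assumption: a full-length transcript read aligns as exon blocks joined by
`N` (reference-skip) CIGAR operations hundreds or thousands of bases long.
Two consequences follow. First, a read whose intron spans a candidate site
contributes no base there, so the effective ("exonic") coverage is lower
than the raw read overlap; second, the `N` gaps themselves enter the local
alignment context that image-based deep-learning callers consume, degrading
their calls. `splicevar` implements the standard remedy — split each read
at its `N` operations so each exon becomes an independent record — plus the
flag repair that makes the remedy safe: after a generic split, only one
fragment of a read keeps the primary-alignment flag and the others are
marked supplementary, and callers that ignore supplementary records then
see a fraction of the true coverage. `correct_flags()` (and the composed
`transform_spliced_alignments()`) give every fragment the parent read's
original flag, nothing else.

## The transformation, precisely

For one record with 1-based start `pos` and CIGAR ops `o_1..o_k`:

* The ops are partitioned into segments at the `N` ops. Segment *i+1*
  starts at the previous segment's reference end plus the intervening `N`
  length (plus any trimmed boundary deletion, below).
* Query bases (sequence and qualities) are partitioned across segments in
  read order; leading soft/hard clips stay on the first fragment, trailing
  clips on the last.
* Boundary handling where the input is ambiguous: a `D` op abutting an `N`
  is trimmed and its length added to the next fragment's start; an `I` op
  abutting an `N` becomes a soft clip on the adjacent fragment. This is a
  documented design choice, not an inference about any other tool's
  internals: it is the unique local rule that keeps every fragment opening
  and closing on an aligned (M/=/X) base — valid SAM — while preserving the
  full set of aligned (reference, query) base pairs. Segments left with no
  aligned base are dropped and counted.
* Flags, read names, MAPQ and tags other than NM/MD are carried to every
  fragment unchanged (NM/MD are invalidated by splitting and dropped). An
  optional MAPQ remap (255 to 60) exists but is off by default.

The invariant the test suite enforces (and `scripts/acceptance.R`
recomputes over 1,000 random CIGARs against an independent per-base
projection oracle) is exact conservation: the union of the fragments'
aligned pairs equals the original record's, and the transform of an
already-transformed file is the identity.

Coordinates are 1-based closed throughout the package, matching SAM, VCF
and the Bioconductor ranges stack that the implementation sits on;
conversion to 0-based half-open happens only at the BED boundary. All
positional rules below are stated in that convention.

## Callset operations

`filter_and_partition()` drops records with QUAL below 15 — the comparison
is inclusive (kept iff QUAL ≥ 15), reading "lower than 15 filtered out"
literally — then partitions survivors into SNPs, indels, and a rest bucket
(MNPs, heterozygous-alternative records, symbolic alleles). A genotype with
two distinct non-reference alleles is classified `het_alt` regardless of
allele shapes, because such sites are ambiguous between variant types.

`clair3_mix()` implements the mixed calling strategy: SNPs from the raw
spliced BAM, indels from the transformed BAM, concatenated and
position-sorted; where both callsets report the same (chrom, pos) only the
higher-QUAL record survives. Deduplication is by *position only* — the
motivating situation is one SNP and one indel at the same site — and at
equal QUAL the SNP is kept; "remove the lowest" is undefined at equality,
so the tie-break is fixed and tested rather than left to sort order.

`normalize_variants()` canonicalises records before matching (the matching
rule itself is a package choice: exact (chrom, pos, ref, alt) equality,
genotype ignored — stricter than position-only): shared trailing then
leading bases are trimmed keeping at least one reference base, and indels
are left-aligned to their earliest equivalent position. Tests verify
idempotence and agreement with an oracle that enumerates all equivalent
representations by applying them to the reference.

## Truth-region construction

The high-confidence cascade keeps a variant iff

1. no 201-bp window containing it holds more than 3 variants (the window
   slides per base, i.e. *any* such window removes the variant — verified
   against exhaustive window enumeration; a run of exactly 3 is kept);
2. its long-read exonic coverage is at least 1 (the site is expressed);
3. its short-read depth lies within inclusive bounds — a fixed floor
   (default 20) and optionally a ceiling, or nearest-rank percentiles
   (e.g. 5th/95th) of the per-variant-site depth distribution. Percentiles
   are computed over the variant sites' own depths, not genome-wide,
   because that is the distribution the bounds are meant to trim; with
   fixed bounds the three predicates are conjunctive, so the kept set is
   order-independent (tested).

The prose convention "coverage higher than 20" versus "at least 20" is
resolved as inclusive ≥, and both thresholds are configurable.

## Per-site annotation

*Coverage.* `site_read_profile()` counts a read toward `exonic_cov` iff an
M/=/X base covers the site and toward `n_span_count` iff an `N` op spans
it; reads not overlapping the site count toward neither. The
intron-containing-read proportion is `n_span / (exonic + n_span)`,
undefined (NA) at zero overlap. The five-read configuration — three exonic,
two intron-spanning — yields coverage 3 and proportion 0.4.

*Junction proximity.* A site is "near" a splice junction iff at least half
of the reads exonically covering it share the same junction (exact intron
start and end) *and* the site is within 20 bp of that junction's nearest
exonic edge (`intron_start - 1` or `intron_end + 1`, minimum over the
two). Intron-spanning reads are not "reads containing the site" — the
denominator uses exonic coverage, consistent with the coverage definition
above. For indels the normalized leftmost base anchors the distance.

*Homopolymer context.* Maximal single-base runs of length ≥ 3 (the plotted
length classes need a lower bound; 3 is the smallest run distinguishable
from a dinucleotide context, and it is configurable) are found by linear
scan. A deletion is `hp` iff all deleted bases lie inside one run; an
insertion iff its insertion point is inside or immediately flanking a run
and every inserted base equals the run base. Defined for indels only —
SNP input is an error, not a silent `non_hp`.

*Allele counting and ASE.* `allele_counts()` re-implements per-allele
counting at biallelic het SNPs: aligned bases equal to ref or alt with
base quality ≥ 20 (a conventional pileup floor; configurable) are counted;
N bases, third alleles, and deletion- or intron-spanning reads are
excluded from both counts. `ase_classify()` excludes sites below the
short-read (40) and long-read (20) coverage floors *before* testing, so
the BH pass runs only over tested sites; then per site
`chi2 = (ref − n/2)²/(n/2) + (alt − n/2)²/(n/2)` with 1 df, q-values by
Benjamini–Hochberg, ASE iff q < 0.05. The suite checks the closed form
((30,10) → 10, p ≈ 1.57e−3), the BH example ((0.01, 0.02, 0.04) →
(0.03, 0.03, 0.04)), the null calibration at coverage 40 over 2,000
simulated balanced sites (raw type-I error within 0.05 ± 0.02, and BH
essentially silent), and power > 0.95 for a 90:10 imbalance at coverage
100 over 500 sites.

## Benchmarking

`match_callset()` partitions normalized keys into TP/FP/FN; `prf_metrics()`
computes precision, recall and F1, flagging empty denominators instead of
emitting NaN. Stratified evaluation restricts the truth to each stratum
before matching and assigns false positives by the called site's own
annotation (an FP has no truth annotation to inherit). The coverage sweep
evaluates at each minimum-coverage threshold; t = 0 reproduces the
unstratified result. `intersection_counts()` enumerates membership
patterns of the callsets plus truth over the union of keys — patterns
without the truth set are pure false-positive patterns, the truth-only
pattern is the universally missed fraction. `two_by_two_chi2()` is the
plain Pearson statistic (continuity correction off by default, matching
the named test; available as an option), with a zero marginal treated as
an error rather than a 0/0.

## What the fixture generator emulates — and what it does not

`sim_fixture()` builds, deterministically per seed: a single contig with
three 3-exon genes (exons 300/200/300 bp, introns 150 bp), 50 full-length
spliced reads per gene, substitution errors at 0.001 per base (HiFi-like),
a 0.4 middle-exon skip fraction on gene 1 — so middle-exon sites there see
an intron-containing-read proportion of 0.4, the regime where splitting
matters — balanced haplotype sampling except gene 3 at 0.9 (an ASE gene),
homopolymer runs of length 5 and 6 embedded in gene 2 with one indel each,
and 6 SNPs + 4 indels planted ≥ 25 bp from junctions and ≥ 10 bp apart
(the first SNP homozygous-alt, the rest het and phased). Short
contiguous reads (depth 60, length 100) provide allele counts and the
short-read coverage track. Reads are emitted pre-aligned with truthful
coordinates; no aligner runs, so expected coverages, proportions and
allele fractions are known exactly and tests are hermetic.

The generator deliberately does not emulate: platform-specific error
profiles (no homopolymer-length-dependent indel errors by default),
alignment ambiguity near junctions (reads are placed truthfully, so the
misalignment-driven component of real junction effects is absent),
multi-isoform complexity beyond single-exon skipping, paired-end
structure, or genotype errors in the truth. Passing tests therefore
demonstrate correctness of the *operations* under known inputs, not
real-data performance of any external caller.

## Problem sizes and numerical choices

The suite and the acceptance script use: 1,000 random CIGARs for
projection conservation; 500 multi-exon reads for flag conservation; 200
random sets each for the merge and density-filter brute-force comparisons;
2,000/500 simulated sites for ASE calibration/power; and the default
fixture (150 spliced + 1,440 short reads, 10 variants) for end-to-end
round trips — sizes at which every brute-force oracle is exact and the
whole suite runs in about two minutes. Ties, degenerate inputs and
boundaries are fixed explicitly: QUAL ≥ 15 inclusive; merge ties keep the
SNP; zero-coverage proportions are NA; zero-depth junction context is
`near = FALSE` with supporting fraction 0; empty metric denominators are
0 with a `degenerate` flag; percentiles are nearest-rank; a 2×2 table with
a zero marginal is an error.

## Known limitations

* Arbitrary SAM tags are not round-tripped through file I/O (the in-memory
  `tags` column is honoured by the writer and the splitter); the method
  itself depends only on flag, CIGAR, sequence and qualities.
* Single-sample VCFs only, matching the analysis design.
* ASE is per-site; aggregation of sites to genes is out of scope.
* `match_callset()` requires allele identity; a caller reporting a
  different-but-overlapping representation that survives normalization as
  a distinct key counts as FP + FN, not TP.
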