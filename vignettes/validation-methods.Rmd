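---
title: "Methods: concordance, precision and QC simulation for WGS validation"
author: "VariantAgreement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: concordance, precision and QC simulation for WGS validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical methods: the
models and matching rules it implements, the tunable parameters and their
defaults, the design choices made where more than one reasonable convention
exists, what the synthetic-data generator does and does not emulate, and the
numerical details that matter for reproducibility.

## 1. Genotype-aware variant matching

### Normalization

Variant representations are canonicalized before any comparison:

* indels are left-aligned against the reference and trimmed to a single
  anchor base, using the standard loop (drop a shared trailing base,
  extending leftward with the preceding reference base whenever an allele
  would become empty; then trim shared leading bases while both alleles keep
  one base beyond the anchor);
* multi-base substitutions are decomposed into per-base SNVs that inherit
  the genotype;
* SNVs pass through unchanged.

Normalization is idempotent, and the test suite checks it against an
independent brute-force oracle that enumerates all sequence-equivalent
representations and picks the leftmost.

### Classification

A true positive is an exact `(chrom, pos, ref, alt, genotype)` match within
the comparison region; truth-only records are false negatives and eval-only
records are false positives. Two conventions exist for a zygosity mismatch
at a shared site: the definitional reading (the truth genotype is missed
*and* a wrong genotype is asserted) produces one FN plus one FP, while a
stricter published convention charges only an FP. The package defaults to
FN + FP and exposes `gtMismatch = "fp_only"` for the other reading; both are
tested.

**True negatives.** Agreement studies report TN counts but rarely define
them. The package uses: TN = (bases in the region) − (distinct region
positions covered by any truth or eval variant footprint), where an indel's
footprint is its reference-allele span. This reproduces the order of
magnitude of published per-context TN columns (region size × samples, minus
a small variant footprint) and makes NPA insensitive to how many samples
worth of region are pooled. The region used for TN is always an explicit
argument — the package never guesses whether a published TN was restricted
to a context∩panel intersection.

**Stratification** assigns each TP/FP/FN to *every* context interval its
footprint overlaps and every predicate (type, zygosity) it satisfies;
strata deliberately overlap, as published context tables do. Per-context TN
is recomputed over the context∩region intersection; predicate strata keep
the whole-region TN since zygosity does not partition reference positions.

**Recurrent artifacts.** Keys discordant in ≥ `minFraction` of samples
(default 0.20 — no published threshold exists, so the default is
configurable and reported) can be flagged and excluded before
reclassification. The boundary is inclusive.

## 2. Agreement statistics

PPA = TP/(TP+FN), NPA = TN/(TN+FP); a zero denominator yields an undefined
flag (`NA`), never a zero. Results are stored at full precision;
`asPercent()` applies half-up rounding to two decimals only as a
presentation layer, which is why an NPA of 99.99956% prints as 100%.

Two point estimates are supported because published tables mix them: pooled
("micro", the default) and per-sample mean ("macro"). The packaged fixture
marks one printed row (insertions) whose value is consistent only with
macro averaging; the fixture test asserts the mismatch rather than deciding
which convention the source used.

Intervals: per-sample normal approximation mean ± z·sd/√n (z = 1.96
default), the form used in clinical validation submissions, clamped to
[0, 1] because the normal interval can exceed the parameter space; and
pooled binomial intervals (Wald closed-form, Wilson via `prop.test`), which
are the statistically preferable choice for pooled proportions. Wald and
Wilson agree within 10⁻³ by n = 10⁶, which the suite verifies.

## 3. Inter-laboratory precision

The Jaccard coefficient is computed over exact variant+genotype keys,
restricted to an explicit region (whether a published precision analysis
was restricted to the reportable range is not stated anywhere, so the
region is an argument, not an assumption). Two empty call sets have
Jaccard 1: replicates that both call nothing agree perfectly.

Published equivalence claims of the form "between-lab differences were
smaller than within-lab variability" are descriptive; the package makes the
claim checkable with a permutation test. The statistic is mean(within-lab
pairwise Jaccard) − mean(between-lab pairwise Jaccard); lab labels are
permuted within each sample across its (lab, replicate) units; the p-value
is one-sided for "between labs worse than within" with the standard
(1 + #{perm ≥ obs}) / (n + 1) estimator, so it is valid (never
anti-conservative) at any permutation count.

**Granularity matters.** With 2 labs × 2 replicates there are only 3
distinct pairings per sample, so the smallest attainable p-value over two
samples is ≈ 0.11 and a 5% test can never reject. The calibration and power
analyses therefore use 2 labs × 3 replicates × 3 samples (10 pairings per
sample, 10³ combinations), at which the test's type-I error sits at the
nominal 5% (checked over 500 exchangeable-lab replicates) and a lab with a
systematic 5× miss rate is detected with power > 0.8. The power scenario
models a *systematic* lab deficiency (the same calls missed in every
replicate of that lab), which is the alternative this statistic is designed
for; independent random excess noise in one lab degrades within-lab and
between-lab agreement almost equally and is better caught by per-lab
accuracy than by this contrast.

## 4. Reportable-range construction

The pipeline is pad → add sites → subtract exclusions → annotate coverage:

* **Padding**: each exon extends 15 bases into the upstream intron and 6
  into the downstream intron, strand-aware (on the minus strand the
  genomic-left pad is the downstream one); overlapping padded exons merge;
  pads clamp at the first coordinate.
* **Site additions**: known P/LP positions and PGx star-allele sites
  outside the padded exons enter as single-base intervals.
* **Exclusions**: GC-rich windows (strictly > 0.75 GC over 100 bp, sliding
  with step 1 — the published rule is marked "typically", so both
  parameters are configuration), homopolymer runs ≥ 10 bp and di-/tri-
  nucleotide tandem repeats ≥ 6 units (no published thresholds exist;
  defaults are reported in the output), plus named exclusions supplied as
  input — pseudogene-homology regions are an *input*, not something the
  package detects.
* **Coverage**: positions lacking 20× depth in ≥ 20% of samples are
  *annotated*, not excluded, following the published decision that no
  low-coverage region was poor enough to drop. The ≥ boundary reading of
  "in 20% of the samples" is a package decision and configurable.
* **Precedence**: exclusions override added sites; a requested P/LP or PGx
  site falling inside an exclusion is surfaced in a conflict report rather
  than silently kept or dropped, because the source material does not state
  the precedence.

Interval arithmetic is 1-based closed in memory (`GRanges`) and 0-based
half-open on disk (BED); the conversion lives only in the I/O layer. The
builder is a fixpoint: rebuilding from its own output with zero pads
changes nothing.

## 5. QC simulation and limit of detection

Published QC thresholds are derived by degrading aligned reads; this
package degrades the *site-level read-count observations* those reads
produce — the statistical object the thresholds act on — which keeps the
analysis at desk scale without read simulation. The genotype caller is a
deliberately transparent binomial-likelihood argmax with allele-fraction
models ε (hom-ref), 0.5 (het) and 1−ε (hom-alt), uniform prior, ties broken
toward hom-ref (the fewest reportable calls); ε defaults to 0.01.

* **Downsampling**: retention f thins each site jointly — total
  ~Binomial(depth, f), alt count hypergeometric given the total — which is
  exactly uniform read removal; sequential thinning composes
  multiplicatively in distribution (KS-checked).
* **Duplicates**: duplicate rate r at constant yield reduces unique depth
  to Binomial(depth, 1−r), so the curve is computed through the identical
  seeded pipeline as downsampling at 1−r; at matching levels and seed the
  two curves are bit-identical by construction.
* **Contamination**: with contaminating fraction α, each read reflects the
  contaminant's expected allele fraction with probability α, so alt counts
  are Binomial(depth, (1−α)·AF_host + α·AF_cont). The estimator is
  α̂ = max(0, 2·(median non-consensus allele fraction at homozygous-called
  sites − ε)). It is calibrated for the informative panel — host-homozygous
  sites where the contaminant is heterozygous, the configuration
  contamination panels target — since there the mixture gives
  median ≈ ε + α/2. Two caveats are inherent to the stated estimator: the
  read-count median is discrete (at depth 40 it moves in steps of 1/40,
  giving biases up to ≈ 0.02 at the tested α values, within the accepted
  RMSE of 0.03 but not uniformly under 0.01), and heavily contaminated
  sites can be called heterozygous and drop out of the homozygous set,
  truncating the median at large α.
* **Limit of detection**: heterozygous-truth sites are simulated across an
  allele-fraction grid at fixed depth; the reported band is the longest
  contiguous run of grid levels with het-call accuracy ≥ 0.99 (the
  published "confident and accurate" is not quantified; 0.99 is the
  package's threshold, configurable). Under the symmetric het model the
  band always contains 0.5 for adequate depth.
* **Threshold selection** scans from the least-degraded level and stops at
  the first failure, returning the most-degraded level passed — a
  conservative prefix rule that refuses to step over a dip in a
  non-monotone curve. The sensitivity floor is a required user input; no
  published floor exists.

## 6. PGx star-allele calling

Diplotypes are assigned by transparent rules rather than haplotype
inference: an allele is fully matched homozygous (all defining variants
hom-alt) or heterozygous (all het). Nested definitions resolve to the most
specific (largest) fully matched set; identical defining sets are flagged.
Two fully het alleles at disjoint sites are reported in *trans* and flagged
ambiguous, because an unphased call set cannot exclude the cis compound
haplotype — published pipelines delegate this to orthogonal assays. Partial
or mixed-zygosity matches and calls at definition sites matching no allele
become conflicts. Ploidy is an input (haploid genes return one allele);
sex inference and structural-variant star alleles are out of scope.
Concordance tabulation scores an exact unordered allele-pair match per
method and pools across methods.

## 7. The synthetic cohort generator

`generateCohort()` emulates the *structure* of a multi-lab validation
cohort: per-sample truth call sets on one linear reference fragment
(multi-chromosome layouts are represented by concatenated labeled
fragments), evaluation call sets per (lab, replicate, sample) derived from
truth by independent per-type false-negative dropping, zygosity flipping
(het ↔ hom-alt at the truth site, so the genotype-mismatch path is
exercised), and false-call injection at truth-free positions with the same
type mix, plus labeled context intervals, a Poisson coverage matrix with
engineered low-coverage pockets, and a GC/homopolymer/micro-repeat
controllable reference.

Defaults are chosen once as plausible desk-scale study conditions: a
3:1:1 SNV/insertion/deletion mix, 60% heterozygous, truncated-geometric
indel lengths on 1–50 bases concentrating mass below ~10 (validation
accuracy is typically characterized for events up to ~20 bases), human-like
41% GC background, 35× mean coverage. Variant placement is uniform without
footprint overlap (rejection sampling with a 52-base guard).

What the generator does **not** emulate — and hence what passing tests do
not demonstrate about real data: read-level error models (no FASTQ/BAM),
alignment and mapping artifacts, systematic context-dependent caller
biases, haplotype phasing, structural variants, and real per-gene variant
densities. The generator shows that the *statistics* are computed
correctly under known error structure, not that any sequencing pipeline
achieves particular values.

Determinism: every stochastic operation runs under an explicit seed through
one guarded RNG scope, so identical configuration plus seed yields
bit-identical cohorts, curves and serialized files, and the ambient RNG
state of the session is never disturbed.

## 8. Problem sizes and numerical choices

The test and acceptance suites use sizes chosen to make binomial noise
negligible relative to the assertions: 500 random truth/eval pairs of up to
50 variants for oracle equivalence; ≥ 10,000 injected variants for rate
recovery (3 binomial SEs); 500 replicates for permutation-test calibration
(nominal 5% ± 2 SE ≈ [0.03, 0.07]); 5 kb fragments for brute-force scanner
equality; 2,000–5,000 sites × 20 replicates for QC curves and the
contamination estimator. Floating-point boundaries that implement inclusive
rules (≥ 20% of samples, ≥ minFraction of samples) subtract 10⁻¹² before
comparison so that exact fractions like 2/10 are not lost to representation
error. Likelihood ties in the caller are resolved within 10⁻⁹ toward
hom-ref.

## 9. Known limitations

* No haplotype-aware complex-variant matching: equivalence is at the level
  of normalized keys, not alignment-path enumeration, so a complex locus
  represented as different-but-equivalent *sets* of variants will not match.
* The TN definition, while explicit and reproducible, is one of several
  defensible conventions; published TN columns cannot be reproduced exactly
  without knowing the comparator's confident regions.
* The contamination estimator inherits median discreteness and
  homozygous-set truncation (see §5).
* PGx calling does not model gene deletions, hybrids or copy-number star
  alleles, and treats phase as unknowable.
* The fixed published-table fixtures reproduce printed statistics from
  printed counts; rows whose printed values are internally inconsistent are
  recorded as such rather than corrected.
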