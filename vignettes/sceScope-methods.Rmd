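---
title: "Localizing and interpreting sister chromatid exchanges with sceScope"
author: "sceScope authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localizing and interpreting sister chromatid exchanges with sceScope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Background

A sister chromatid exchange (SCE) is a crossover between the two sister
chromatids of a chromosome. In Strand-seq — single-cell sequencing of
only the inherited template strand — every read maps predominantly to
one reference strand (Watson, minus, or Crick, plus) until an SCE flips
the template state, so an SCE appears as a changepoint in read
directionality along the chromosome. In a haploid cell line each
chromosome carries a single template state, which makes the changepoint
signal clean enough for automated localization.

sceScope implements this analysis end to end: a seeded synthetic-data
module that plants SCEs, noise, feature enrichment and deletion-junction
microhomology with machine-readable ground truth; an SCE caller for
haploid read tables; a gap-aware circular-shift permutation test for
enrichment of SCEs at genomic features (common fragile sites,
centromeres, telomeres, gene bodies, G-quadruplex motifs); a binomial
hotspot statistic; and a deletion/microhomology cohort comparison for
tumors stratified by homologous-recombination status.

## SCE calling model

The caller consumes a per-cell read table (`chrom`, `pos`, `strand` in
`{W, C}`, `mapq`, `dup`) and proceeds in four stages.

1. **Filtering.** Only non-duplicate reads with mapping quality at
   least `minMapq = 10` are analyzed. Both thresholds live in
   `SCEParam` and are echoed into every run manifest.

2. **Flip correction.** A single read whose `flipWindow = 3` nearest
   neighbours on *each* side all carry the opposite strand is treated
   as a directionality error and inverted. "Embedded within an extended
   region" has no canonical width; three reads per side mirrors the
   three-read support rule below and is configurable. Flips are decided
   against the original labels and applied simultaneously, so the
   result is scan-order independent, and reads with too few neighbours
   (chromosome ends) are never flipped.

3. **Segmentation.** Strand is encoded +1 (Crick) / −1 (Watson) and the
   sequence is segmented by recursive binary segmentation: each segment
   is split at the index maximizing the absolute CUSUM statistic
   (leftmost index on ties). A split is accepted when Fisher's exact
   test on the two flanks' strand counts is significant and each flank
   holds at least `minSupport = 3` reads of its own majority direction.
   Because the split index is *chosen* as the maximum over all `n − 1`
   candidates, the exact test is Bonferroni-corrected by that number of
   candidates; `segAlpha = 0.01` is therefore a per-segment level.
   Without this correction, chance clusters of residual noise reads in
   long chromosomes are accepted as spurious changepoints. Adjacent
   segments with equal majority state are merged, so emitted segments
   strictly alternate.

4. **Event calling.** Each adjacent segment pair with at least three
   majority-direction reads on both sides becomes one SCE event. The
   event's uncertainty interval runs from the last majority-strand read
   of the left segment to the first majority-strand read of the right
   segment (0-based half-open, as in BED).

### Boundary uncertainty under strand-flip noise

A flipped read sitting directly at the junction is indistinguishable
from a genuine first read of the next segment, and with a 2% flip rate
roughly 4% of junctions carry such a read; a naive last-read/first-read
interval then excludes the true breakpoint. `callSCEs` therefore treats
the changepoint location as uncertain under an explicit error model:
every read assignment near the boundary is scored by its number of
misclassified reads, splits are weighted by
$(\varepsilon/(1-\varepsilon))^{\text{cost}}$ with $\varepsilon$ the
flip rate estimated by the correction stage, and the interval spans the
smallest set of splits holding at least $1 - \texttt{segAlpha}$ of that
mass. With $\varepsilon = 0$ (clean data) this reduces exactly to the
narrow last-read/first-read interval. The widening is typically one to
two read spacings; intervals that remain wide are later removed by the
permutation test's size cutoff as unlocalized.

### Clonal events

A breakpoint observed at the same location (equal interval within
`matchSlop`, default exact) in strictly more than 25% of a cell line's
libraries is a stable rearrangement rather than a per-cell SCE and is
flagged recurrent; 25% exactly is not flagged, because the rule is a
strict inequality.

## Circular-shift permutation test

To ask whether SCEs co-locate with a feature track, the observed
overlap count (SCE intervals touching at least one feature by at least
1 bp, each SCE counted once) is compared with overlaps after random
circular shifts. For each of `nPerm = 1000` permutations one shift
`n ~ U[2 Mb, 50 Mb]` is drawn and applied to *all* SCEs on their own
chromosome; a single shared shift preserves the spatial pattern of the
SCE set and only decouples it from the feature coordinates. Coordinates
that run off the chromosome end wrap around to the beginning, treated
as circular; wrapping is implemented as a modulo so chromosomes shorter
than `n` behave consistently.

Assembly gaps are excluded *before* shifting: each chromosome's non-gap
segments are concatenated into a masked coordinate space in which the
bijection to reference coordinates is exact, shifts are performed
there, and permuted SCEs therefore can never land in a gap. The
enrichment statistic is the observed overlap normalized to the median
permuted overlap; the mean is also reported, since either summary can
be of interest, but the p-value definition follows the count rule:
`pEnrich` is the fraction of permutations with overlap at least the
observed value, `pDeplete` the fraction at most it, and a zero count is
reported as below the floor `1/nPerm`. The one-sided 0.05 level
determines the reported direction. SCE intervals wider than the size
cutoff (100 kb for genes/CFS/centromere/telomere tests, 10 kb for
G-quadruplex tests) are treated as unlocalized and removed first.
`nPerm` can be raised to 10,000 where finer p-value resolution is
needed. When several features are tested in one report the per-feature
permutation p-values are reported as such; a Benjamini–Hochberg option
exists but is off by default.

Two calibration properties are enforced by the test suite: under
independence of SCEs and features the empirical p-values are uniform
(checked by a Kolmogorov–Smirnov test over 200 replicates), and with
half of 100 SCEs planted in a 5%-coverage track the test reports
`p < 1/nPerm` in essentially every run.

## Hotspots

Pooled over libraries, maximal regions where at least `minEvents = 2`
SCE intervals stack (interval-intersection depth) are candidate
hotspots. Their significance uses a capture–recapture-style binomial
bin model: dividing the genome into bins of the hotspot's size, the
count in one bin is Binomial(`N`, `binSize/genomeSize`) given `N` total
SCEs, and the reported p-value is the upper tail `P(X ≥ k)`; an
optional Bonferroni factor of `genomeSize/binSize` accounts for
scanning all bins.

## G-quadruplex motifs

Putative quadruplex-forming sequences are matched with the canonical
pattern `G{3,} N{1,x} G{3,} N{1,x} G{3,} N{1,x} G{3,}` where `N` is any
nucleotide and the loop cutoff `x` is 3, 7 or 12. Matching is leftmost
and greedy with non-overlapping successive matches, so counts are
monotone non-decreasing in `x`; whether overlapping matches should be
collapsed differently is underdetermined, and leftmost-greedy is the
decision here. Both strands are scanned by default (the complementary
C-run pattern), because quadruplexes are strand-specific structures.
The test suite pins the scanner to an independent backtracking
implementation on randomized G-rich sequences.

## Deletions at common fragile sites and junction microhomology

Common fragile sites (CFSs) are consumed as a BED track; intervals
fully enveloped within another CFS are removed (keeping the enclosing
site), and only autosomes are analyzed. A deletion counts as in-CFS
only when the *entire* deleted interval lies within a single CFS —
straddling a boundary, or spanning two adjacent CFSs while inside
neither alone, does not count.

Junction microhomology is computed from the reference: `mhFwd` is the
longest common prefix of the deleted sequence and the sequence starting
at the deletion end, `mhRev` the longest common suffix of the deleted
sequence and the sequence ending at the deletion start. The reported
`mhLength = mhFwd + mhRev`, capped at the deletion length, is the
standard junction-microhomology convention; because the one-sided
convention is also defensible, both components are kept in the output
so alternative summaries can be derived. Comparisons are
case-insensitive and terminate at the first `N`. Microhomology so
defined is invariant under sliding a deletion within its placement
ambiguity window, which the tests assert directly.

Cohorts labelled homologous-recombination deficient (HRD) or proficient
(HRP) — labels consumed, not computed — are compared per metric
(fraction of deletions in CFS; among those, fraction with
`mhLength ≥ 2` bp, the signature of polymerase-theta-mediated end
joining) with a two-sided Wilcoxon rank-sum test on per-sample values,
Benjamini–Hochberg-corrected across metrics. Because per-sample means
and pooled percentages answer different questions and the original
summaries' convention is ambiguous, both are reported, along with a
clearly labelled pooled two-proportion test.

## The synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated.

* **Genomes.** Chromosome lengths are free parameters; assembly gaps
  occupy exactly `round(gapFraction × size)` bases, split into ~500 kb
  intervals placed uniformly without overlap. Simulated sequence is
  uniform-random A/C/G/T with `N` in gaps.
* **Libraries.** Reads are placed uniformly on non-gap space at
  `depth = 200` reads per non-gap Mb by default — typical Strand-seq
  library depth, as the source experiments do not pin a value — with
  template strand alternating at planted breakpoints, strand labels
  flipped with probability 2%, 5% duplicate flags and 5% MAPQ < 10 by
  default. Planted breakpoints keep a minimum spacing of two mean read
  gaps (`2e6/depth` bp) so that adjacent events remain resolvable in
  principle. Coverage waviness, GC bias, mappability structure and
  paired-end reads are *not* modelled; recovery rates measured here
  therefore speak to the changepoint logic, not to alignment artifacts
  of real libraries.
* **Feature tracks and enrichment.** Non-overlapping fixed-length
  intervals rejected against gaps; SCE sets with a controlled fraction
  of midpoints planted inside the track.
* **Deletion cohorts.** Defaults mirror a breast-cancer cohort of 96
  HRD and 411 HRP samples with ~500 deletions each, CFS-containment
  fractions 0.19 vs 0.15 and junction microhomology drawn from
  geometric distributions with `p` 0.252 (HRD) and 0.314 (HRP), chosen
  so that `P(MH ≥ 2) = (1 − p)²` equals 0.56 and 0.47. Deletion length
  is uniform on 10–100 kb by default. Microhomology is planted only on
  the 3' side, by copying the first `m` deleted bases immediately after
  the deletion end; planting on both sides would confound the recovery
  oracle. The bases bracketing the planted run are then forced to
  mismatch so that recomputation recovers exactly `m` — degenerate
  random extensions would otherwise contaminate the equality check.
  Sequence planting needs pairwise-disjoint junction windows and is
  meant for cohorts of a few thousand deletions; large cohorts carry
  the planted `mhLength` directly.

Every generator call takes an explicit seed, uses one RNG stream,
restores the caller's RNG state, and records the seed in its truth
output; identical seeds give byte-identical outputs.

## Numerical and interface choices

* Coordinates are 0-based half-open (BED) at every file boundary;
  in-memory intervals are standard `GRanges`. 1-based inclusive TSV
  input is converted by an explicit flag on `readIntervals`.
* CUSUM ties break to the leftmost index; the clonal rule and the
  MAPQ rule are `>`-strict and `≥`-inclusive respectively, matching
  their stated forms.
* Empty SCE sets, empty tracks, and zero permuted medians set a
  `degenerate` flag on the permutation result rather than erroring.
* Fisher's exact test is used for flank comparison because flank
  counts near chromosome ends can be small; at large counts it agrees
  with the chi-squared test.
* Problem sizes in the test suite (one 100 Mb chromosome, 50
  libraries, 200 null replicates, 20 power replicates, 507-sample
  cohorts) are the package's chosen validation scale: large enough for
  the binomial tolerances stated in the tests, small enough to run
  routinely.

## Worked example

```{r example, eval = FALSE}
library(sceScope)

genome <- simulateGenome(1, 1e8, gapFraction = 0.05, seed = 1)
sim <- simulateStrandSeqLibrary(genome, nSCEs = 5, depth = 200,
                                flipErrorRate = 0.02, seed = 2)
res <- callSCEsFromReads(sim$reads, SCEParam(), libraryId = "cell01")
res$events
evaluateSCECalls(res$events, sim$truth$breakpoints)

track <- simulateFeatureTrack(genome, 50, 1e5, name = "CFS", seed = 3)
sces <- plantEnrichedSCEs(genome, track, 100, 0.5, seed = 4)
runPermutationTest(sces, track, genome, PermParam(nPerm = 1000),
                   seed = 5, featureName = "CFS")
```

## Known limitations

* Haploid model only: Watson and Crick are exhaustive states. Diploid
  or aneuploid strand-state genotyping and copy-number segmentation are
  out of scope, as is any copy-number-aware breakpoint classification.
* No merging of nearby events is performed; whether the original
  procedure merged close calls is unstated, so none is done here.
* The permutation model assumes features and gaps are fixed and only
  SCEs move; feature tracks with strong chromosome-scale clustering
  reduce the effective number of distinct shifts.
* Microhomology uses exact matching; mismatch-tolerant homeology is not
  modelled.
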