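---
title: "Methods: Monte Carlo overlap enrichment for genomic tracks"
author: "trackenrich"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Monte Carlo overlap enrichment for genomic tracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trackenrich)
```

## The question the package answers

A recurring question in regulatory genomics is whether two genomic
annotations co-localize: do disease-associated regions from a GWAS fall
inside active chromatin (promoters, enhancers, transcribed regions) of a
particular cell type more often than chance would predict?  `trackenrich`
answers this for *segment tracks* (disjoint labelled intervals, e.g. an
11-state chromatin segmentation or a set of association regions) and
*point tracks* (SNP positions) on a shared genome layout.  All
coordinates are 0-based half-open (BED convention), strand is ignored,
and every statistic depends only on covered bases, so tracks are held in
canonical form (sorted, disjoint, adjacency-merged).

## The enrichment statistic

For a chromatin-state track $S$ and a query track $Q$ within an analysis
universe $U$ (the whole genome or one bin), the enrichment ratio is

$$ E = \frac{|S \cap Q| / |S|}{|(U \setminus S) \cap Q| / |U \setminus S|}, $$

the proportion of state bases covered by the query divided by the same
proportion for non-state bases.  $E = 1$ means proportional coverage;
$E = 0$ when the query misses the state entirely.  When the query covers
no base of the complement the ratio is undefined and the package raises a
typed error rather than returning infinity.  When the state (or its
complement) is empty within a bin the proportion itself is undefined;
binned analyses record `NA` enrichment for such bins instead of failing.

## The length-preserving null model

Significance is assessed against a Monte Carlo null in which the
*locations* of the state's segments vary while their empirical length
structure is held fixed.  Within each contiguous analysis region (a
chromosome for global tests, a chromosome arm for local tests) with $n$
segments, the multiset of $n$ segment lengths and the multiset of $n+1$
gap lengths (counting both flanks to the region boundaries) are each
independently and uniformly permuted, then reassembled as
gap, segment, gap, ..., gap.  This preserves the segment-length and
inter-segment-length distributions *exactly* — a permutation, not a
resampling from fitted distributions.  We chose the permutation reading
because it is exactly conservative: every null sample is a genome that
could have produced the observed length statistics.  A resampling
variant (drawing lengths from a fitted distribution) would be a natural
extension but is intentionally not implemented.

The query track stays fixed.  One test draws $N$ null samples (default
$N = 20{,}000$) and recomputes the overlap statistic with the *same code
path* used for the observed value, eliminating estimator mismatch.
The one-sided p-value counts null samples at least as large as the
observed overlap, with ties counted as extreme, and is floored at $1/N$:

$$ p = \max(k, 1)/N, \qquad k = \#\{T^{(b)} \ge T_{obs}\}. $$

With $N = 20{,}000$ the smallest reportable p-value is $0.00005$.
Depletion (enrichment $< 1$) is not tested separately; it simply yields
p near 1 under the one-sided convention.

One practical subtlety: a randomized track cannot in general be both
adjacency-coalesced ("canonical") and preserve the segment-length
multiset exactly.  The two conflict in one edge case — when a zero-length flank gap is permuted
into the interior, two segments become exactly adjacent, and coalescing
them would merge their lengths.  `randomize_track()` therefore returns
intervals that are sorted and disjoint but *not* adjacency-coalesced:
length multisets are preserved for every input and seed, and all
covered-base statistics are unaffected.

## Global and local (binned) testing

The global test randomizes independently within each chromosome, keeping
per-chromosome track mass fixed (no cross-chromosome leakage).  The
local test uses a `BinPartition`, typically chromosome arms built from a
UCSC cytoband table: p arm $[0, b)$ and q arm $[b, L)$ where $b$ is the
start of the first q band; acrocentric chromosomes without annotated p
bands get a single q bin.  The number of bins is derived from the input
cytoband table, never hard-coded.

Bins in which the query covers no base carry no information about
enrichment and are excluded from testing *and* from the multiplicity
adjustment (they are reported in the `excluded_bins` attribute, not as
p = 1 rows, which would dilute the FDR).  Across the retained bins of
one state track, Benjamini–Hochberg step-up flags are set at level
`fdr_q` (default 0.10).  Adjusting per state track (rather than pooling
all states) matches the per-column significance marking of binned
report tables; the grouping is an explicit, configurable choice.

## Case-control differential tracks

To ask whether a state's overlap with the query is *cell-type specific*,
two cell types' same-state tracks are reduced to their specific parts:
bases present in both are removed, the remainder labelled `case` and
`control`.  The observed statistic is the overlap (bp) between
case-labelled intervals and the query.  The null uniformly permutes the
label sequence over the fixed interval positions, preserving the number
of case labels genome-wide.  Labels attach to *intervals*, not base
pairs, so interval-length heterogeneity is part of the null — the
literal exchangeability reading.  Whether per-chromosome label counts
should also be fixed is not determined by the procedure's description;
the genome-wide count is what is implemented.  The accompanying effect
size is the fold enrichment difference,
$(\text{case overlap}/\text{case bp}) / (\text{ctrl overlap}/\text{ctrl bp})$.

## Point-in-state tests

For SNP positions the statistic is the count of points inside the state
(half-open membership: a point at an interval's first base counts, at
its end coordinate it does not).  The null randomizes the *state track*,
exactly as for region tests, with the points fixed — not a uniform-point
null, which would be a different (and here unimplemented) model.
Enrichment is the observed count divided by the mean null count; this
converges to (fraction of points in state)/(coverage fraction) on large
genomes, a property the test suite checks at 5% tolerance.  The
percentage column is reported to 2 decimals.

## Query regions of fixed genetic width

Association regions are built as windows of fixed genetic width
(default 0.25 cM) centred, in map coordinates, on each lead SNP.  The
genetic map is piecewise linear (bp → cM, exact at knots, no silent
extrapolation).  Inversion back to physical coordinates floors the left
boundary and ceils the right (maximal region); inside zero-recombination
plateaus the outermost physical positions are taken, again the maximal,
conservative-inclusion choice.  Windows reaching past a chromosome end
are clipped, never wrapped; a cM target beyond the map's range clamps to
the map endpoint only when the map itself reaches the chromosome
boundary there — otherwise the map domain is too short and the package
raises an extrapolation error.  Overlapping windows from nearby leads
merge on track construction.

## Seeds and determinism

Every stochastic routine derives its stream from one master seed plus a
string key (`"global:<label>"`, `"local:<label>:<bin>"`, `"points:…"`,
`"chromatin"`, …) via a fixed integer hash below $2^{31}$.  Identical
inputs and seeds give bit-identical results end-to-end, including the
written TSVs; different tracks/bins get effectively independent
substreams.

## What the synthetic-data generator emulates

`simulate_chromatin()` produces alternating background/state segments
with geometric (memoryless) lengths; the per-segment state is chosen
with probability proportional to `fraction / mean_len`, and the mean gap
is set so realized genome fractions match their targets.
`simulate_query()` places region starts from a two-component mixture —
uniform over target-state bases with weight $ef \cdot c / (ef \cdot c + (1 - c))$,
otherwise uniform over non-state bases — so the in/out start-density
ratio is exactly the enrichment factor $ef$, and $ef = 1$ reduces
exactly to uniform placement.  `simulate_points()` lands each point in
the target state with probability `multiplier` × coverage fraction (an
infeasible product > 1 is an error, not a silent cap).

This emulates what the tests need — controllable coverage fractions,
length scales, planted enrichments, background gaps that exercise the
randomization's gap handling — and deliberately nothing more.  Real
segmentations have non-geometric length distributions, state-transition
grammar, assembly gaps and chromosome-scale heterogeneity.  Because the
null model preserves whatever lengths it is given, the *validity* of the
tests does not depend on this realism; what passing calibration/power
checks on synthetic data shows is that the machinery is correct and
well-calibrated under known ground truth, not that any particular real
dataset will show enrichment.

## Simulation sizes used by the test suite

The suite's statistical checks use sizes chosen to make the checks
informative while keeping the full run comfortably interactive:
per-base-oracle equivalence on 1,000 random tracks over ≤ 2 kb genomes;
null-conservation on 1,000 random tracks plus a chi-square uniformity
check over the 12 enumerable arrangements of a 2-segment/3-gap bin at
12,000 draws; type-I calibration with 500 replicates of a 2 Mb genome
(state fraction 0.15, mean segment 2 kb, 30 query regions of mean 3 kb,
500 points) at $N = 200$ null samples; power and parameter recovery with
100 replicates of a 10 Mb genome (state fraction 0.2, mean segment
10 kb, 100 regions of mean width 500 bp, enrichment factor 3) at
$N = 400$.  The narrow-region/wide-segment power design keeps the
coverage-ratio estimator close to the planted start-density factor
(regions spill only ~2.5% of their bases across segment boundaries), so
factor recovery within ±0.5 is a fair ask; with wide regions relative to
segments the coverage enrichment is intrinsically diluted and the
estimator measures a smaller quantity.

## Degenerate inputs and tie-breaking

- A segment exactly filling its bin has no randomization freedom: the
  null is degenerate and p = 1 by the tie rule.
- Ties between null samples and the observed statistic always count as
  extreme (this makes small-sample p-values conservative, visible in the
  slightly sub-nominal rejection rates of the discrete point test).
- Empty tracks are valid everywhere except where a proportion over their
  bases is requested (typed `undefined_proportion_error`).
- Readers reject out-of-layout coordinates and malformed lines (with
  line numbers) rather than clamping or guessing; the point-list reader
  requires an explicit 0-/1-based declaration in its header.

## Known limitations

- No analytic null approximation is provided; very small p-values are
  bounded by $1/N$ and cost $O(N)$ randomizations.
- The case-control test has no binned (local) variant.
- LD expansion of SNP lists and genetic-map estimation are out of scope;
  both arrive as inputs.
- The randomization assumes segments do not span bin boundaries; tracks
  must be restricted to the analysis bins first (binned drivers do this
  automatically, and `randomize_track()` errors otherwise).
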