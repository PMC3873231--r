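---
title: "chromabind: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chromabind: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromabind)
```

chromabind maps where a chromatin-bound factor sits in a genome and what
chromatin context it occupies. This vignette documents the statistical
models behind each stage, the parameters that matter (with units and
defaults), the design decisions taken where the design was genuinely
open, what the synthetic-data generators do and do not emulate, and the
known limitations. Nothing stated here goes beyond what the package's
tests and `scripts/acceptance.R` themselves compute.

## Coordinates and containers

All coordinates are 0-based, half-open `[start, end)` — BED-native —
throughout; any 1-based display is labeled. Intervals and transcripts
live in plain data frames; per-base fragment coverage lives in a
`coverage_track` (depth vector per chromosome, total mapped fragment
count for per-million scaling, and the fragment-extension length,
default 300 bp). Interval overlap (≥ 1 bp by definition) and disjoining
are delegated to GenomicRanges/IRanges.

Two conventions recur and are worth stating once. Transcript-relative
windows on the minus strand are flipped so "downstream" always means
5'→3'; the interval ties for nearest-gene assignment break by distance
then lexicographic id. The center of an interval of length L is
`start + floor(L/2)` for both parities.

## DamID array normalization

The two-step normalization removes within-chip GC/dye structure, then
between-chip distributional differences.

**Step one (within chip).** Probes are binned by GC fraction. The
initial bin width follows the normal-scale zero-stage rule
`h = 3.49 · sigma_hat · n^(-1/3)` with
`sigma_hat = min(sd, IQR/1.349)`; this robust plug-in minimizes
asymptotic mean integrated squared error for histogram-type binning and
needs no tuning. Bins are contiguous in GC; adjacent bins with fewer
than `min_bin_probes` (default 500) probes are merged left-to-right
(smallest GC first) until every bin reaches the floor; identical GC
values always share a bin. Within each bin a robust lowess (span 2/3,
3 robustifying iterations — the classic defaults) predicts log₂(cy5)
from log₂(cy3); the normalized signal is the residual divided by the
bin's median absolute residual. Genuine local enrichment is sparse and
so survives as residual outliers that the robust fit refuses to chase.
A numerically zero residual spread (an exact fit) cannot serve as a
scale unit; below 1e-10 log₂ units the residuals are returned unscaled
with a warning.

In this two-color design the Dam-only control is the cy3 channel of the
same chip, so the lowess regression of cy5 on cy3 is simultaneously the
dye correction and the control adjustment; no additional cross-chip
ratioing is applied.

**Step two (between chips).** Quantile normalization equalizes the
replicate chips: every chip's sorted vector becomes the rank-wise mean
of the sorted inputs. Tied entries receive the mean of the values their
ranks map to, which preserves within-chip ranks; note that under ties
the "sorted columns identical" identity necessarily holds only for
tie-free data. The implementation is checked in the tests against
`limma::normalizeQuantiles` on tie-free input and against a brute-force
rank-average oracle under ties.

## Peak calling

The caller computes, per probe, a window `[center - w/2, center + w/2]`
(defaults `w = 2000` bases; the window is genomic, truncating at
chromosome ends so k shrinks accordingly). Across the k probes in the
window and r replicate chips it counts x exceedances of the pooled
100·s-th percentile threshold (`s = 0.95`, linear-interpolation
percentile, strict `>`). The p-value is the inclusive upper tail
`P(X >= x)` of a hypergeometric draw of `k·r` values from `N·r` pooled
values of which M exceed the threshold. M is the empirical exceedance
count by default; the nominal `ceiling((1-s)·N·r)` is available behind
`empirical_m = FALSE` (the two differ under ties). Peaks are maximal
runs of consecutive probes with `p < 0.001`; runs shorter than
`min_probes = 6` are discarded. A gene is a peak target when a peak
overlaps `[TSS - 3000, TSS + 3000)` by at least 1 bp; a peak ending
exactly at `TSS - 3000` does not qualify under the half-open
convention.

Two properties anchor the suite: the tail function agrees exactly with
an exhaustive enumeration oracle for all populations up to 25, and on
no-effect simulations the fraction of probes below the threshold stays
within a small multiple of p (windows overlap, so per-probe p-values
are valid marginally but not independent — the calibration bound is
aggregate, 5p over 20 seeds).

An important operating regime, visible in the algebra and reproduced by
the generators: with the pooled threshold at quantile s, the exceedance
probability of a truly enriched probe cannot exceed
`(1 - s) / (enriched fraction)`. When more than `1 - s` of the probe
mass is enriched the threshold climbs into the enriched distribution
and recovery degrades no matter how large the effect; when the enriched
fraction is below `1 - s`, essentially all enriched values exceed and
null probes become strongly sub-threshold. The default simulation keeps
the planted fraction near 3.5% for this reason.

## Overlap statistics

The circular permutation test works on disjoined units (e.g. disjoined
array probes). One set's membership vector is rotated within each
chromosome by an independent offset drawn uniformly from 1..n (n =
units on that chromosome), wrapping at the chromosome end, so
per-chromosome marked counts are conserved by construction. The overlap
statistic is the count of doubly-marked units. For a single chromosome
the mean over all n rotations is exactly `|A|·|B|/n`, which the tests
verify by enumeration. The empirical p uses the +1 correction and
two-sided min-tail doubling capped at 1; the 95% CI is the percentile
interval `observed / perm-quantile(0.975, 0.025)`. The number of
permutations defaults to 20000 in `overlap_test_params()`; the demo
report uses 2000 to stay quick.

Gene-set enrichment is a two-sided Fisher exact test per set on the
target/set 2×2 table, BH-adjusted across sets.

## Promoter classes

For a 1001 bp window centered on the TSS, 500 bp subwindows are scanned
at a 5 bp step. Per subwindow: GC content over called (non-N) bases,
CpG observed = count of CG dinucleotides fully inside, CpG expected =
`#C·#G/L`, ratio = observed/expected (0 when expected is 0). HCP iff
any subwindow has ratio > 0.75 and GC > 0.55; LCP iff no subwindow has
ratio > 0.48; ICP otherwise. Subwindows with more than 50% N are
skipped; an all-N sequence is an error.

Design choice: subwindow starts are placed symmetrically around the
sequence midpoint (the forward grid plus its mirror image). CG counts
and GC content are individually strand-symmetric, so with a symmetric
window set the classification is *exactly* invariant under reverse
complement at any step size — at step 1 the grid is simply every start.
Step 1 and step 5 agree on all test fixtures.

## Profiles, heatmaps, chromatin state

TSS metagenes tile `window`-bp windows (default 70) left-aligned across
`[TSS - flank, TSS + flank)` (remainder truncated), per-base mean depth
per window, unweighted mean over transcripts with a Monte-Carlo SE;
windows leaving the chromosome drop out for that transcript. Gene-body
models use genes strictly longer than 2 kb, 100 equal bins TSS→TES.
Promoter heatmap matrices bin −7..+3 kb around the TSS into 20 bins
(500 bp each) and rank rows by descending total ranking signal,
emitting passenger matrices in the same order. The iterative gene
filter applies, in order: chromosome restriction, non-missing
expression, at least one probe per TSS bin, unique TSS, and neighbor
exclusion (no other TSS within 7 kb upstream / 3 kb downstream,
strand-oriented), reporting counts after each step; the MAD row filter
retains rows with mean absolute deviation strictly above 1.0.

Mark presence over the genome uses non-overlapping 1 kb bins and a
rank-curve threshold: sort bin values ascending, scale rank and value
to [0, 1], and take the value at the point farthest below the unit
diagonal — the tangent point where the convex curve's slope passes 1,
ties resolved to the highest index (so an exactly linear ramp
thresholds at the final point). RPKM from a depth track is computed as
fragment equivalents, `sum(depth)/extension · 1e9 / (bin_len ·
total_mapped)`; a depth track cannot recover the exact count of
fragments overlapping a bin, and this estimator is monotone in
coverage, which preserves the presence-monotonicity property. TSS-level
presence slides 1 kb bins at 100 bp steps across TSS ± 3 kb and marks
presence if any bin exceeds the threshold.

Bound 1 kb bins are classified into patterns with an explicit
precedence (the underlying classes are not mutually exclusive, so
percentages are only well-defined under an order): 1 = H3K4me3 + TSS,
2 = H3K27me3 + TSS, 3 = H3K9me3, 4 = H3K27ac without TSS, 5 = no mark,
everything else "other"; percentages over bound bins sum to 100.

The CpG-island methylation table bins fractions as `x = 0` exactly,
`0 < x < 0.1`, then ten-point bins with the last closed at 1. Islands
are "bound" on ≥ 1 bp peak overlap. The per-bin comparison of the bound
column against the total column (the total *includes* the bound
islands, matching the marginals of the reference table it reproduces; comparing against the complement is a one-line change) is a
pooled two-proportion z-test by default — a sensible reading of a
"two-tailed t-test" on count data; `prop.test` with continuity
correction is available via the `test` argument. The choice does not
affect the extreme (< 2.2e-16) bins.

## ChIA-PET and MNase

PET pairs are kept when at least one end overlaps a TSS ± 3 kb window;
the overlapping end becomes end 1 (if both, the closer; ties keep the
input order). Each end scores the factor's fragments in
`[center - 500, center + 500)` per million mapped; a gene id attaches
only to ends at a TSS window, nearest TSS first, ties lexicographic.
Pairs are sorted by end-1 score descending (stable) and split into 10
groups with `group = ceiling(rank · 10 / n)`, so sizes differ by at
most one.

MNase fragments are size-selected to 120–180 bp inclusive and collapsed
to midpoints (`start + floor(len/2)`); conditions are downsampled
without replacement to a common count with a fixed seed. Transcripts
split into four equal-size occupancy quartiles by factor signal in
TSS ± 3 kb (rank-based, ties by id). Per quartile, the TSS-aligned
1 bp midpoint profile is divided by its own mean over ± 5 kb — making
the pre-smoothing mean exactly 1, which the tests assert to 1e-12 —
and smoothed with a centered moving average of width 50 with symmetric
edge truncation.

## The synthetic-data module

Generators are deterministic given `sim_params(seed)`; each stage
derives an independent RNG stream from (seed, stage name) via a
polynomial rolling hash, so adding a stage never perturbs another's
draws.

Default study conditions (all in `sim_params()`): a 2 × 1 Mb genome
with 60 transcripts placed by a half-clustered / half-isolated gap
mixture (so a realistic share of genes has close neighbors for the
filter chain); probes of 50 bp on a genome-wide 250 bp lattice across
TSS ± 5 kb (a fixed array design — overlapping promoter tiles share
probes rather than doubling local density); r = 2 replicate chips;
planted log₂ enrichment 2.5 at 12% of genes' promoters (TSS ± 1.5 kb),
bound TSSs separated by > 6.5 kb so each planted region resolves as its
own run; a linear GC dye bias of amplitude 2 on the cy5 channel and
per-channel noise sd 0.4. ChIP tracks plant a bimodal promoter shape
(70% flanking modes 1.5 kb either side of the TSS with sd 500, 30%
promoter core, so the composite dips at the TSS while the
TSS-containing 1 kb bin retains enough mass to pass presence
thresholds), a 5'→3' decaying gene-body component starting past the
NDR, a TES bump, and enhancer components co-planted with H3K27ac at
intergenic loci kept clear of TSSs (± 3.5 kb) and of gene bodies
(± 8 kb, outside the reach of the broad gene-anchored marks). Island
methylation is a two-mode Beta mixture (means 0.04 / 0.96, a 9% slice
of the low mode exactly 0) with bound-promoter islands drawn low with
weight 0.9. PET pairs anchor near the flanking promoter modes (the TSS
itself is the planted dip) and decoys avoid all TSS windows. MNase
fragments are N(147, 15) truncated to [100, 200] with phased nucleosome
positions (+1 at +120, −1 at −180, repeat length 190 bp, Gaussian
jitter 30 bp, amplitude 0.75) flanking an NDR; under depletion the
−1/+2/+3/+4 nucleosomes of the highest-occupancy quarter of promoters
are down-weighted by 0.5.

Several of these values were set by explicit calibration of the study
design rather than taste, and the reasoning is part of the record: the
250 bp lattice makes the window draw size k·r = 18, whose discrete
hypergeometric tail just below the 0.001 threshold is ~1.7e-4 (denser
lattices put the tail near 9e-4 and inflate false runs); the 12% bound
fraction keeps the planted probe mass below 1 − s (see the peak-calling
section); the low (5%) track background keeps Poisson doubles in 1 kb
bins from crossing the sparse-data presence thresholds.

What the generators do *not* emulate: read-level sequencing error,
mappability and repeat structure, realistic base composition (promoter
sequence is a token mixture tuned to the three CpG classes), copy
number, replicate-specific batch structure beyond a shared probe
baseline, and the true physical coupling of marks within a nucleosome.
A green suite therefore demonstrates that the computations implement
their definitions and recover structure they were designed for under
the stated noise model — not that the pipeline is robust to every
artifact of real array or sequencing data.

## Problem sizes and runtime

The test and acceptance suites run the full pipeline at the default 60
transcripts (~1.9k probes) and the null calibration at 40 transcripts
over 20 seeds, with 2000 Monte-Carlo permutations against the exact
rotation expectation, 200 runs of 500 permutations for the null
uniformity of the permutation p (2000 disjoined units — at a few
hundred units the integer overlap statistic is too discrete for a
continuous-uniform KS reference regardless of correctness), and 1000
random sequences for reverse-complement invariance. These sizes are the
package's simulation study design; they keep any single test file in
seconds while leaving wide Monte-Carlo margins to every asserted bound.

## Known limitations

* The permutation test precomputes each chromosome's full rotation
  curve (O(n²) per chromosome), which is exact and fast to tens of
  thousands of units but not intended for millions.
* Coverage tracks are dense per-base vectors; genomes far beyond the
  simulated scale would want run-length encoding.
* The methylation bin comparison reproduces printed-table arithmetic
  exactly but the original study's non-extreme p-values depend on an
  unstated test variant; only the extreme bins are asserted.
* Peak calling assumes probes are ordered and windows are genomic;
  unordered input is sorted internally per chromosome, but probe sets
  with heterogeneous density will see window draw sizes (k·r) vary and
  with them the discreteness of the attainable p-values.
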