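# chromabind

Genomic location analysis of chromatin-bound factors, built around the
question of *where* a factor such as an MBD3/NuRD chromatin-remodeling
complex sits in a genome and *what chromatin context* it occupies:
promoters, gene bodies, enhancers, or repressed domains.

The package implements the complete computational chain used in
DamID + ChIP-style location studies:

* **Two-step DamID array normalization.** Probes are binned by GC
  content with bin widths from the normal-scale zero-stage rule
  (h = 3.49 σ̂ n^(−1/3), σ̂ = min(sd, IQR/1.349)), bins merged until
  each holds ≥ 500 probes; within each bin a robust lowess predicts
  log₂(cy5) from log₂(cy3) and the residuals, scaled by the bin's median
  absolute residual, become the normalized signal. Chips are then
  quantile-normalized so every replicate shares one distribution.
* **Replicate-spooling hypergeometric peak calling.** For each probe, a
  window of w bases (default 2000) centered on the probe pools the
  k·r normalized values of its k probes across r replicates; x of them
  exceed the pooled 100·s-th percentile (s = 0.95). The enrichment
  p-value is P(X ≥ x) for X ~ Hypergeometric(N·r, M, k·r), with M the
  total exceedance count; peaks are maximal runs of probes with
  p < 0.001, discarding runs of fewer than six probes. Target genes are
  those with a peak within 3 kb of the TSS.
* **Chromosome-bound circular permutation tests** for interval-set
  overlap over disjoined units, with odds ratio, empirical two-sided p
  and a percentile confidence interval; Fisher + Benjamini–Hochberg
  gene-set enrichment.
* **Promoter CpG classes** (HCP/ICP/LCP) from 500 bp subwindows of a
  1001 bp window around the TSS, using CpG observed/expected ratio
  (obs / (#C·#G/L)) and GC content with the 0.75/0.55/0.48 thresholds.
* **Profiles and heatmaps**: TSS metagenes (70 bp windows, ±5 kb),
  100-bin scaled gene-body models, −7..+3 kb promoter matrices ranked by
  factor signal, the iterative heatmap gene-filter chain, MAD row
  filtering, and peak-center profiles (60 bp windows) stratified by TSS
  overlap.
* **Chromatin state**: rank-curve (super-enhancer style) presence
  thresholds over 1 kb genomic bins, TSS mark co-occurrence with sliding
  1 kb bins at 100 bp steps, five-pattern classification of bound bins,
  and the CpG-island methylation table (x = 0 bin, ten-point bins, per-bin
  two-proportion comparison).
* **ChIA-PET anchor proximity**: pair filtering at TSS ± 3 kb anchors,
  per-end signal in ±500 bp windows scaled per million mapped fragments,
  descending rank order and ten groups.
* **MNase nucleosome metagenes**: 120–180 bp fragment size selection,
  midpoint conversion, seeded downsampling to matched depth, occupancy
  quartiles by factor signal at the TSS, per-quartile normalization to a
  unit ±5 kb mean and a period-50 moving average.
* **A seeded synthetic-data module** that generates all of the above
  inputs with planted ground truth (enriched promoter regions, enhancer
  links, methylation bimodality, phased nucleosomes with an NDR), so the
  whole pipeline is testable and calibratable without any external data.

## Worked example

An end-to-end run on synthetic data with planted truth:

```r
library(chromabind)
rep <- run_demo(demo_config(seed = 1, n_perm = 500))

rep$n
#> $transcripts [1] 60   $probes [1] 1854   $peaks [1] 7
#> $targets [1] 9        $planted_regions [1] 7

rep$recovery$recovered_fraction
#> [1] 1                      # every planted region recovered (Jaccard >= 0.5)

rep$overlap[c("observed", "expected", "odds_ratio", "pval")]
#> observed 86   expected 5.318   odds_ratio 16.17   pval 0.004

rep$enrichment
#>            set n_set n_overlap odds_ratio        pval        qval
#> 1 luminal_like    10         8    145.323 1.52877e-07 1.52877e-07

rep$promoter_classes
#> HCP ICP LCP
#>  37   7  16

rep$tss_shape
#> $left_max_pos [1] -1500   $right_max_pos [1] 1000
#> $tss_is_local_min [1] TRUE
```

Reading the output: the caller recovered all 7 planted bound-promoter
regions with no peaks away from the truth; the circular permutation test
sees 86 disjoined probe units shared between called peaks and planted
regions where 5.3 are expected by chance (odds ratio 16.2, empirical
p ≈ 0.004, the smallest value 500 permutations can resolve); the planted
"luminal-like" gene set is strongly enriched among peak target genes
(Fisher q ≈ 1.5e-07); and the factor's TSS composite shows the expected
two flanking maxima about 1.5 kb either side of a local minimum at the
TSS.

Individual stages are plain functions (`damid_normalize()`,
`probe_enrichment_pvalues()`, `call_peaks()`,
`permutation_overlap_test()`, `classify_promoter()`, `tss_profile()`,
`methylation_decile_table()`, `filter_anchor_pets()`,
`quartile_metagene()`, ...) over data frames, `coverage_track` objects
and plain-text formats (BED, bedGraph, refFlat-like TSV, GMT, FASTA),
so any one of them can be used on its own. See the methods vignette
(`vignettes/chromabind-methods.Rmd`) for the model, parameter and
design documentation.

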