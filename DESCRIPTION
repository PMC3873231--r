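Package: chromabind
Title: Genomic Location Analysis of Chromatin-Bound Factors from DamID
    Arrays and Sequencing Coverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for mapping where a chromatin-associated factor binds in
    a genome and what chromatin context it binds in.  Implements two-step
    DamID tiling-array normalization (within-chip GC/dye lowess correction
    followed by between-chip quantile normalization), a replicate-spooling
    sliding-window hypergeometric peak caller, chromosome-bound circular
    permutation tests for interval-set overlap, Fisher/BH gene-set
    enrichment, CpG-based promoter classification (high/intermediate/low
    CpG), TSS metagene and gene-body profiles, heatmap gene-filter chains,
    presence thresholds and pattern classification for histone marks,
    CpG-island methylation binning, ChIA-PET anchor proximity scoring, and
    MNase-seq nucleosome occupancy metagenes.  A seeded synthetic-data
    module generates array, coverage, methylation, interaction and
    nucleosome inputs with planted ground truth so every stage can be
    exercised and calibrated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    Biostrings,
    jsonlite,
    withr
Suggests:
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
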