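test_that("annotation generation is seed-deterministic and validates density", {
  p <- sim_params(seed = 5, n_transcripts = 20L)
  a1 <- make_genome_annotation(p)
  a2 <- make_genome_annotation(p)
  expect_identical(a1, a2)

  a0 <- make_genome_annotation(sim_params(seed = 5, n_transcripts = 0L))
  expect_equal(nrow(a0$transcripts), 0L)
  expect_s3_class(a0$layout, "genome_layout")

  expect_error(
    make_genome_annotation(sim_params(seed = 5, n_transcripts = 400L)),
    "denser")

  # planted regions live inside the genome and bound genes are a subset
  ann <- fx_annotation()
  validate_intervals(ann$truth$enriched_regions, ann$layout)
  expect_true(all(ann$truth$bound_genes %in% ann$transcripts$id))
  # enhancers never overlap a TSS +/- 3 kb window
  tssw <- data.frame(chrom = ann$transcripts$chrom,
                     start = pmax(0, ann$transcripts$tss - 3000),
                     end = ann$transcripts$tss + 3000)
  expect_false(any(overlap_any(ann$truth$enhancer_links, tssw)))
})

test_that("neighbor structure exercises the heatmap filter chain", {
  ann <- fx_annotation()
  tx <- ann$transcripts
  isolated <- vapply(seq_len(nrow(tx)), function(i) {
    plus <- tx$strand[i] != "-"
    lo <- if (plus) tx$tss[i] - 7000 else tx$tss[i] - 3000
    hi <- if (plus) tx$tss[i] + 3000 else tx$tss[i] + 7000
    others <- tx$tss[tx$chrom == tx$chrom[i] & tx$id != tx$id[i]]
    !any(others >= lo & others <= hi)
  }, logical(1))
  expect_gt(mean(isolated), 0.05)
  expect_lt(mean(isolated), 0.8)
})

test_that("DamID arrays carry the planted structure", {
  # noiseless limit: ratio exactly the effect inside truth, 0 outside
  p0 <- sim_params(seed = 9, n_transcripts = 20L, gc_bias_amplitude = 0,
                   noise_sd = 0)
  ann0 <- make_genome_annotation(p0)
  pr0 <- simulate_damid_arrays(ann0, p0)
  ratio <- pr0$log_cy5_1 - pr0$log_cy3_1
  expect_equal(ratio[pr0$planted], rep(p0$enrichment_effect,
                                       sum(pr0$planted)))
  expect_equal(ratio[!pr0$planted], rep(0, sum(!pr0$planted)))

  # default params: raw log-ratio correlates with GC before normalization
  pr <- fx_probes()
  raw <- pr$log_cy5_1 - pr$log_cy3_1
  expect_gt(abs(stats::cor(raw, pr$gc, method = "spearman")), 0.2)

  # null case: fusion and Dam-only channels exchangeable
  pvals <- vapply(1:5, function(s) {
    pn <- sim_params(seed = 200 + s, n_transcripts = 20L,
                     enrichment_effect = 0)
    prn <- simulate_damid_arrays(make_genome_annotation(pn), pn)
    stats::t.test(prn$log_cy5_1 - prn$log_cy3_1 -
                    (pn$gc_bias_amplitude * (prn$gc - mean(prn$gc))))$p.value
  }, numeric(1))
  expect_gt(min(pvals), 0.01)
})

test_that("ChIP tracks plant bimodal promoters and marked enhancers", {
  ann <- fx_annotation()
  tracks <- fx_tracks()
  tx <- dedup_transcripts(ann$transcripts)
  coarse <- tss_profile(tracks$mbd3, tx, flank = 2750, window = 500)
  shape <- tss_profile_shape(coarse)
  expect_true(shape$tss_is_local_min)
  expect_true(abs(shape$left_max_pos) >= 1000 &&
                abs(shape$left_max_pos) <= 2000)
  expect_true(shape$right_max_pos >= 1000 && shape$right_max_pos <= 2000)

  # enhancer loci: H3K27ac high, H3K4me3 low relative to background
  enh <- ann$truth$enhancer_links
  k27 <- window_counts(tracks$h3k27ac, enh, rpm = TRUE)
  k4 <- window_counts(tracks$h3k4me3, enh, rpm = TRUE)
  shift <- ifelse(enh$end + 20000 <=
                    ann$layout$chrom_lengths[enh$chrom], 20000, -20000)
  bg <- data.frame(chrom = enh$chrom, start = enh$start + shift,
                   end = enh$end + shift)
  expect_gt(mean(k27), 5 * mean(window_counts(tracks$h3k27ac, bg,
                                              rpm = TRUE)))
  expect_lt(mean(k4), mean(k27) / 5)

  # background-only: flat composite within Monte-Carlo error
  flat <- tss_profile(tracks$input, tx, flank = 2750, window = 500)
  expect_lt(diff(range(flat$value)) / mean(flat$value), 0.5)
})

test_that("methylation mixture is bimodal and respects the mixing weight", {
  ann <- fx_annotation()
  isl <- ann$islands
  all_low <- simulate_methylation(isl, sim_params(seed = 3,
                                                  meth_mix_weight = 1))
  expect_true(all(all_low$fraction < 0.5))
  all_high <- simulate_methylation(isl, sim_params(seed = 3,
                                                   meth_mix_weight = 0))
  expect_true(all(all_high$fraction > 0.5))

  meth <- simulate_methylation(isl, fx_params(),
                               bound = isl$gene %in%
                                 ann$truth$bound_genes)
  expect_true(all(meth$fraction >= 0 & meth$fraction <= 1))
  idx <- chromabind:::methylation_bin_index(meth$fraction)
  expect_gt(mean(idx %in% c(2L, 11L)), 0.6)
})

test_that("PET pairs respect links, decoys and the anchor filter", {
  ann <- fx_annotation()
  tx <- dedup_transcripts(ann$transcripts)

  none <- ann
  none$truth$enhancer_links <- ann$truth$enhancer_links[0, ]
  p_nodecoy <- sim_params(seed = 42, pet_decoy_rate = 0)
  expect_equal(nrow(simulate_pets(none, p_nodecoy)), 0L)

  pets_clean <- simulate_pets(ann, p_nodecoy)
  kept_clean <- filter_anchor_pets(pets_clean, tx)
  expect_equal(nrow(kept_clean), nrow(pets_clean))

  pets <- simulate_pets(ann, fx_params())
  kept <- filter_anchor_pets(pets, tx)
  expect_equal(nrow(kept), sum(pets$from_link))
})

test_that("MNase fragments show size structure, phasing and depletion", {
  ann <- fx_annotation()
  p <- fx_params()
  frags <- simulate_mnase(ann, p)
  len <- frags$end - frags$start
  expect_true(all(len >= 100 & len <= 200))
  expect_gt(mean(len >= 120 & len <= 180), 0.85)

  # phased midpoint density: autocorrelation peaks near the repeat length
  mp <- size_filter_midpoints(frags)$midpoints
  tx <- ann$transcripts
  counts <- numeric(4001)
  for (i in seq_len(nrow(tx))) {
    rel <- mp$pos[mp$chrom == tx$chrom[i]] - tx$tss[i]
    if (tx$strand[i] == "-") rel <- -rel
    rel <- rel[rel >= -2000 & rel <= 2000]
    counts <- counts + tabulate(rel + 2001, nbins = 4001)
  }
  ac <- stats::acf(counts, lag.max = 250, plot = FALSE)$acf[-1]
  lag_star <- which.max(ac[120:250]) + 119
  expect_lt(abs(lag_star - p$phasing_period), 10)

  # amplitude 0: flat density (no lag beats the unsmoothed baseline much)
  p_flat <- sim_params(seed = 42, phasing_amplitude = 0)
  f_flat <- simulate_mnase(ann, p_flat)
  mp_f <- size_filter_midpoints(f_flat)$midpoints
  cf <- numeric(4001)
  for (i in seq_len(nrow(tx))) {
    rel <- mp_f$pos[mp_f$chrom == tx$chrom[i]] - tx$tss[i]
    rel <- rel[rel >= -2000 & rel <= 2000]
    cf <- cf + tabulate(rel + 2001, nbins = 4001)
  }
  acf_flat <- stats::acf(cf, lag.max = 250, plot = FALSE)$acf[-1]
  expect_lt(max(acf_flat[120:250]), max(ac[120:250]) / 2)

  # depletion lowers occupancy at the planted nucleosome positions
  depl <- simulate_mnase(ann, p, depleted = TRUE)
  mp_d <- size_filter_midpoints(depl)$midpoints
  top <- ann$genes$mbd3_level >=
    stats::quantile(ann$genes$mbd3_level, 0.75, type = 7)
  occ <- function(m, sel) {
    tot <- 0
    for (i in which(sel)) {
      rel <- m$pos[m$chrom == tx$chrom[i]] - tx$tss[i]
      if (tx$strand[i] == "-") rel <- -rel
      centers <- c(-180, 120 + p$phasing_period * (1:3))
      tot <- tot + sum(vapply(centers, function(cn)
        sum(abs(rel - cn) <= 60), numeric(1)))
    }
    tot
  }
  expect_lt(occ(mp_d, top), 0.85 * occ(mp, top))
})

test_that("derived stage seeds are collision-free and in range", {
  names_grid <- c(outer(c("ks", "null", "mem", "perm"), 1:300, paste0))
  seeds <- vapply(names_grid, stage_seed, integer(1), seed = 1L)
  expect_false(any(duplicated(seeds)))
  expect_true(all(seeds >= 0 & seeds < 2^31))
  expect_false(stage_seed(1L, "a") == stage_seed(2L, "a"))
})

test_that("stage streams are independent of one another", {
  p <- sim_params(seed = 13, n_transcripts = 20L)
  ann <- make_genome_annotation(p)
  pr_direct <- simulate_damid_arrays(ann, p)
  invisible(simulate_chip_tracks(ann, p))
  invisible(simulate_pets(ann, p))
  pr_after <- simulate_damid_arrays(ann, p)
  expect_identical(pr_direct, pr_after)
})
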