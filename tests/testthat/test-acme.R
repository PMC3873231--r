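test_that("percentile threshold uses linear interpolation and strict exceedance", {
  expect_equal(percentile_threshold(1:100, 0.95), 95.05)
  expect_equal(percentile_threshold(c(1, 2, 3), 0.5), 2)
  expect_equal(percentile_threshold(rep(7, 50), 0.95), 7)
  expect_error(percentile_threshold(numeric(0), 0.95), "empty")
})

test_that("hypergeometric tail matches enumeration and is monotone", {
  expect_equal(hypergeom_tail(0, 4, 5, 20), 1)
  expect_equal(hypergeom_tail(4, 4, 5, 20), 5 / 4845)
  expect_equal(hypergeom_tail(2, 4, 5, 20), 1205 / 4845)
  expect_equal(hypergeom_tail(5, 4, 5, 20), 0)
  expect_error(hypergeom_tail(1, 4, 30, 20), "inconsistent")

  # literal enumeration over all C(20,4) draws for the printed example
  succ <- 1:5
  combos <- utils::combn(20, 4)
  hits <- colSums(matrix(combos %in% succ, nrow = 4))
  expect_equal(hypergeom_tail(2, 4, 5, 20), mean(hits >= 2))
  expect_equal(hypergeom_tail(4, 4, 5, 20), mean(hits >= 4))

  # monotone non-increasing in x
  tails <- vapply(0:10, hypergeom_tail, numeric(1), draws = 10,
                  successes = 12, population = 30)
  expect_true(all(diff(tails) <= 0))
})

test_that("window statistics spool replicates and match the oracle", {
  probes <- data.frame(chrom = "c1",
                       start = c(0, 500, 1000, seq(5000, 35000, by = 5000)),
                       end = c(0, 500, 1000, seq(5000, 35000, by = 5000)) + 50)
  # r = 2 chips; the four largest of the 20 pooled values sit in the
  # three clustered probes
  sig <- cbind(c(17, 19, 16, 1:7), c(18, 20, 8, 9:15))
  params <- acme_params(w = 2000, s = 0.8)
  ws <- probe_enrichment_pvalues(probes, sig, params)
  expect_equal(attr(ws, "M"), 4L)
  expect_equal(ws$k[2], 3L)
  expect_equal(ws$x[2], 4L)
  expect_equal(ws$pval[2], hyper_tail_oracle(4, 6, 4, 20))
  expect_equal(ws$pval[2], hypergeom_tail(4, 6, 4, 20))
  # isolated probes have k = 1
  expect_true(all(ws$k[4:10] == 1L))

  # all-equal signals: nothing exceeds a strict threshold, p = 1
  flat <- matrix(5, nrow(probes), 2)
  ws0 <- probe_enrichment_pvalues(probes, flat, acme_params())
  expect_equal(ws0$pval, rep(1, nrow(probes)))

  expect_error(probe_enrichment_pvalues(probes, sig[1:3, ]), "match")
})

test_that("peaks are maximal runs with the probe-count floor", {
  n <- 20
  probes <- data.frame(chrom = "c1", start = (0:(n - 1)) * 100,
                       end = (0:(n - 1)) * 100 + 50)
  mk <- function(sig_idx) {
    ws <- data.frame(k = 1L, x = 0L, pval = rep(1, n))
    ws$pval[sig_idx] <- 1e-6
    ws
  }
  expect_equal(nrow(call_peaks(probes, mk(1:5))), 0L)
  pk6 <- call_peaks(probes, mk(1:6))
  expect_equal(nrow(pk6), 1L)
  expect_equal(pk6$n_probes, 6L)
  expect_equal(pk6$start, 0)
  expect_equal(pk6$end, 550)
  # one intervening non-significant probe splits the run
  pk2 <- call_peaks(probes, mk(c(1:6, 8:13)))
  expect_equal(nrow(pk2), 2L)
})

test_that("target genes require a peak within the TSS radius", {
  tx <- data.frame(id = c("g1", "g2", "g3"), chrom = "c1", strand = "+",
                   tss = c(12000, 40000, 80000),
                   tes = c(20000, 50000, 90000), stringsAsFactors = FALSE)
  peaks <- data.frame(chrom = "c1", start = 9000, end = 9500)
  expect_equal(assign_target_genes(peaks, tx), "g1")
  # peak ending exactly at TSS - radius does not reach the window
  edge <- data.frame(chrom = "c1", start = 36000, end = 37000)
  expect_equal(assign_target_genes(edge, tx), character(0))
  expect_equal(assign_target_genes(peaks[0, ], tx), character(0))
})

test_that("planted regions are recovered and peaks are well-formed", {
  ann <- fx_annotation()
  peaks <- fx_peaks()
  rec <- peak_recovery(peaks, ann$truth$enriched_regions)
  expect_gte(rec$recovered_fraction, 0.9)
  expect_equal(rec$false_peaks, 0L)
  expect_true(all(peaks$n_probes >= 6))
  # pairwise disjoint within chromosome
  for (ch in unique(peaks$chrom)) {
    pc <- peaks[peaks$chrom == ch, ]
    if (nrow(pc) > 1) expect_true(all(pc$start[-1] >= pc$end[-nrow(pc)]))
  }
  # targets include most planted genes
  tx <- dedup_transcripts(ann$transcripts)
  targets <- assign_target_genes(peaks, tx)
  expect_gt(mean(ann$truth$bound_genes %in% targets), 0.9)
})

test_that("no-effect simulations stay quiet at default thresholds", {
  frac <- numeric(3); npk <- integer(3)
  for (s in 1:3) {
    p <- sim_params(seed = 500 + s, n_transcripts = 40L,
                    enrichment_effect = 0)
    ann <- make_genome_annotation(p)
    pr <- simulate_damid_arrays(ann, p)
    norm <- damid_normalize(pr, normalization_params(
      min_bin_probes = min(500L, nrow(pr) %/% 5L)))
    sig <- as.matrix(norm[, grep("^normalized_", names(norm))])
    ws <- probe_enrichment_pvalues(norm, sig)
    frac[s] <- mean(ws$pval < 0.001)
    npk[s] <- nrow(call_peaks(norm, ws))
  }
  # aggregate calibration bound; the 20-seed version lives in the
  # acceptance suite
  expect_lt(mean(frac), 5 * 0.001)
  expect_lte(sum(npk > 0), 1L)
})
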