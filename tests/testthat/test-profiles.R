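mk_tx <- function(tss, strand = "+", chrom = "chrT", id = NULL) {
  data.frame(id = id %||% paste0("t", seq_along(tss)), chrom = chrom,
             strand = strand, tss = tss,
             tes = ifelse(strand == "+", tss + 4000, tss - 4000),
             stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("TSS profiles place windows 5'->3' and average per base", {
  tr <- toy_track(depth = 3)
  prof <- tss_profile(tr, mk_tx(10000), flank = 2100, window = 70)
  expect_equal(prof$value, rep(3, 60))
  expect_equal(prof$position[1], -2100 + 35)

  # coverage only at TSS+100 on a plus-strand gene
  d <- rep(0, 20000); d[10100 + 1] <- 70   # one covered base, depth 70
  spike <- coverage_track(list(chrT = d), 10)
  pp <- tss_profile(spike, mk_tx(10000), flank = 2100, window = 70)
  expect_equal(which(pp$value > 0), floor((2100 + 100) / 70) + 1)
  expect_equal(sum(pp$value), 1)  # 70 depth over a 70 bp window

  # same fixture on a minus-strand gene: mirrored window index
  pm <- tss_profile(spike, mk_tx(10000, strand = "-"), flank = 2100,
                    window = 70)
  expect_equal(which(pm$value > 0), 60 - floor((2100 + 100) / 70))

  # strand flip mirrors the composite exactly
  withr::with_seed(51, {
    dd <- stats::rpois(20000, 2)
    trr <- coverage_track(list(chrT = dd), 10)
    fwd <- tss_profile(trr, mk_tx(10000), flank = 2100, window = 70)
    rev_ <- tss_profile(trr, mk_tx(10000, strand = "-"), flank = 2100,
                        window = 70)
    expect_equal(rev_$value, rev(fwd$value))
  })
})

test_that("gene-body profiles scale to percent bins and filter short genes", {
  tr <- toy_track(depth = 2, len = 60000)
  short <- data.frame(id = "s", chrom = "chrT", strand = "+",
                      tss = 10000, tes = 12000, stringsAsFactors = FALSE)
  expect_error(genebody_profile(tr, short, flank = 0), "longer than")

  tx <- data.frame(id = c("a", "b"), chrom = "chrT",
                   strand = c("+", "-"), tss = c(10000, 50000),
                   tes = c(16000, 44000), stringsAsFactors = FALSE)
  gb <- genebody_profile(tr, tx, flank = 0)
  expect_equal(gb$n_genes, 2L)
  expect_equal(gb$body$value, rep(2, 100))

  # 5'->3' decaying coverage gives monotone decreasing bins on both strands
  d <- numeric(60000)
  d[10001:16000] <- seq(6000, 1) / 1000          # + strand gene
  d[44001:50000] <- seq(1, 6000) / 1000          # - strand gene (3'->5')
  dec <- coverage_track(list(chrT = d), 10)
  gbd <- genebody_profile(dec, tx, flank = 0)
  expect_true(all(diff(gbd$body$value) < 0))
})

test_that("promoter matrices rank by total signal and carry passengers", {
  len <- 60000
  d <- numeric(len)
  d[10000 + seq(-6999, 3000)] <- 5   # gene a promoter interval (0-based)
  d[40000 + seq(-6999, 3000)] <- 7   # gene b promoter interval
  tr <- coverage_track(list(chrT = d), 10)
  tx <- data.frame(id = c("a", "b"), chrom = "chrT", strand = "+",
                   tss = c(10000, 40000), tes = c(15000, 45000),
                   stringsAsFactors = FALSE)
  pm <- promoter_matrix(tr, tx, passenger_tracks = list(x = tr),
                        extra = list(expr = c(a = 1, b = 2)))
  expect_equal(pm$order, c("b", "a"))
  expect_equal(ncol(pm$ranking), 20L)
  expect_equal(unname(pm$ranking["b", ]), rep(7, 20))
  expect_equal(rownames(pm$passengers$x), c("b", "a"))
  expect_equal(pm$extra$expr, c(b = 2, a = 1))
})

test_that("the heatmap gene filter applies its steps in order with counts", {
  tx <- rbind(mk_tx(c(20000, 21000), id = c("pair1", "pair2")),
              mk_tx(60000, id = "iso"),
              mk_tx(100000, id = "noexpr"),
              mk_tx(140000, id = "noprobe"))
  expr <- c(pair1 = 1, pair2 = 2, iso = 3, noexpr = NA, noprobe = 1)
  # probes tile every promoter except noprobe's
  cover <- do.call(rbind, lapply(c(20000, 21000, 60000, 100000),
                                 function(t0)
    data.frame(chrom = "chrT", start = seq(t0 - 7000, t0 + 2900, 100),
               end = seq(t0 - 7000, t0 + 2900, 100) + 50)))
  res <- damid_heatmap_gene_filter(tx, expr, cover)
  expect_equal(unname(res$counts),
               c(5, 5, 4, 3, 3, 1))
  expect_equal(res$ids, "iso")

  # brute-force neighbor recount on the synthetic fixture
  ann <- fx_annotation()
  atx <- ann$transcripts
  aexpr <- stats::setNames(rowMeans(ann$expression),
                           rownames(ann$expression))
  probes <- fx_probes()
  res2 <- damid_heatmap_gene_filter(atx, aexpr, probes)
  survivors <- atx[atx$id %in% res2$ids, ]
  for (i in seq_len(nrow(survivors))) {
    plus <- survivors$strand[i] != "-"
    lo <- if (plus) survivors$tss[i] - 7000 else survivors$tss[i] - 3000
    hi <- if (plus) survivors$tss[i] + 3000 else survivors$tss[i] + 7000
    others <- atx$tss[atx$chrom == survivors$chrom[i] &
                        atx$id != survivors$id[i]]
    expect_false(any(others >= lo & others <= hi))
  }
  expect_true(all(diff(unname(res2$counts)) <= 0))
})

test_that("MAD row filtering is strict at the threshold", {
  m <- rbind(const = c(1, 1, 1, 1), edge = c(0, 2, 0, 2),
             keep = c(0, 4, 0, 4))
  keep <- mad_row_filter(m, 1.0)
  expect_equal(unname(keep), c(FALSE, FALSE, TRUE))
})

test_that("peak-center profiles stratify by TSS overlap", {
  ann <- fx_annotation()
  tracks <- fx_tracks()
  tx <- dedup_transcripts(ann$transcripts)
  enh <- ann$truth$enhancer_links
  tss_peaks <- data.frame(chrom = tx$chrom[1:5],
                          start = tx$tss[1:5] - 250,
                          end = tx$tss[1:5] + 250)
  peaks <- rbind(tss_peaks, enh[, c("chrom", "start", "end")])
  prof <- peak_center_profile(tracks[c("h3k4me3", "h3k27ac")], peaks, tx,
                              flank = 3000, window = 60)
  non_tss <- prof[prof$stratum == "non_tss", ]
  expect_equal(unique(non_tss$n_peaks), nrow(enh))
  center <- abs(non_tss$position) <= 300
  edgewin <- abs(non_tss$position) >= 2400
  k27 <- non_tss[non_tss$track == "h3k27ac", ]
  k4 <- non_tss[non_tss$track == "h3k4me3", ]
  expect_gt(mean(k27$value[abs(k27$position) <= 300]),
            3 * mean(k27$value[abs(k27$position) >= 2400]))
  expect_lt(mean(k4$value[abs(k4$position) <= 300]),
            mean(k27$value[abs(k27$position) <= 300]) / 3)

  expect_warning(
    peak_center_profile(tracks["h3k4me3"], tss_peaks, tx),
    "empty non_tss")
})
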