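test_that("BED parsing handles BED3, BED6 and malformed input", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t0\t100", f)
  df <- read_bed(f)
  expect_equal(df$chrom, "chr1")
  expect_equal(df$start, 0)
  expect_equal(df$end, 100)

  bed6 <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                     start = c(0, 50, 10), end = c(10, 100, 20),
                     name = c("a", "b", "c"), score = c(1, 2.5, 3),
                     strand = c("+", "-", "."),
                     stringsAsFactors = FALSE)
  write_bed(bed6, f)
  expect_equal(read_bed(f), bed6)

  writeLines("chr1\t100\t50", f)
  expect_error(read_bed(f), "line 1")
  writeLines(c("chr1\t0\t10", "chr1\tx\t20"), f)
  expect_error(read_bed(f), "line 2")
})

test_that("transcript table round-trips through the refFlat-like TSV", {
  tx <- fx_annotation()$transcripts
  f <- withr::local_tempfile(fileext = ".tsv")
  write_transcripts(tx, f)
  back <- read_transcripts(f)
  expect_equal(back$id, tx$id)
  expect_equal(back$tss, tx$tss)
  expect_equal(back$tes, tx$tes)
  expect_equal(back$strand, tx$strand)
})

test_that("duplicate-locus transcripts collapse to the first id", {
  tx <- data.frame(id = c("b", "a", "c", "d"),
                   chrom = "chr1", strand = "+",
                   tss = c(1000, 1000, 1000, 2000),
                   tes = c(5000, 5000, 4000, 6000),
                   stringsAsFactors = FALSE)
  out <- dedup_transcripts(tx)
  # b and a share (chrom, TSS, TES): "a" (first by id) is kept;
  # c shares the TSS but not the TES and stays
  expect_setequal(out$id, c("a", "c", "d"))
  expect_equal(dedup_transcripts(tx[0, ]), tx[0, ])
})

test_that("overlap_any obeys half-open boundaries and matches brute force", {
  a <- data.frame(chrom = "c1", start = 0, end = 10)
  expect_true(overlap_any(a, data.frame(chrom = "c1", start = 9, end = 20)))
  expect_false(overlap_any(a, data.frame(chrom = "c1", start = 10, end = 20)))
  expect_false(overlap_any(a, data.frame(chrom = "c2", start = 0, end = 10)))

  withr::with_seed(7, {
    for (rep in 1:5) {
      x <- rand_intervals(30); y <- rand_intervals(25)
      brute <- vapply(seq_len(nrow(x)), function(i)
        any(y$chrom == x$chrom[i] &
              pmin(y$end, x$end[i]) - pmax(y$start, x$start[i]) >= 1),
        logical(1))
      expect_equal(overlap_any(x, y), brute)
      # symmetry of the >= 1 bp relation
      brute_yx <- vapply(seq_len(nrow(y)), function(i)
        any(x$chrom == y$chrom[i] &
              pmin(x$end, y$end[i]) - pmax(x$start, y$start[i]) >= 1),
        logical(1))
      expect_equal(overlap_any(y, x), brute_yx)
      expect_equal(any(overlap_any(x, y)), any(overlap_any(y, x)))
    }
  })
})

test_that("disjoin produces atomic units and is idempotent", {
  d <- disjoin_intervals(data.frame(chrom = "c1", start = c(0, 5),
                                    end = c(10, 15)))
  expect_equal(d$start, c(0, 5, 10))
  expect_equal(d$end, c(5, 10, 15))

  nested <- data.frame(chrom = "c1", start = c(0, 5), end = c(20, 10))
  dn <- disjoin_intervals(nested)
  expect_equal(dn$start, c(0, 5, 10))
  expect_equal(dn$end, c(5, 10, 20))

  disj <- data.frame(chrom = c("c1", "c1"), start = c(0, 50),
                     end = c(10, 60))
  expect_equal(disjoin_intervals(disj), disj)

  withr::with_seed(11, {
    x <- rand_intervals(40)
    d1 <- disjoin_intervals(x)
    expect_equal(disjoin_intervals(d1), d1)
    # pairwise disjoint and same covered bases
    cover <- function(df) sort(unlist(lapply(seq_len(nrow(df)), function(i)
      paste(df$chrom[i], seq(df$start[i], df$end[i] - 1)))))
    expect_equal(unique(cover(x)), cover(d1))
  })
})

test_that("window_counts gives per-base means, scales and clips", {
  tr <- toy_track(depth = 2)
  w <- data.frame(chrom = "chrT", start = 100, end = 170)
  expect_equal(window_counts(tr, w), 2)
  expect_equal(window_counts(toy_track(depth = 0), w), 0)

  # one 300 bp fragment fully inside a 600 bp window -> 0.5 pre-RPM
  frag <- data.frame(chrom = "chrT", start = 1000, end = 1300)
  tr1 <- track_from_fragments(frag, toy_layout(), total_mapped = 1e6)
  w600 <- data.frame(chrom = "chrT", start = 900, end = 1500)
  expect_equal(window_counts(tr1, w600), 0.5)
  expect_equal(window_counts(tr1, w600, rpm = TRUE), 0.5)

  # clipped windows use the clipped length as denominator, so uniform
  # depth stays uniform
  expect_warning(v <- window_counts(tr, data.frame(chrom = "chrT",
                                                   start = 19950,
                                                   end = 20100)),
                 "clipped")
  expect_equal(v, 2)

  # linearity in the track
  withr::with_seed(3, {
    d1 <- stats::rpois(5000, 2); d2 <- stats::rpois(5000, 1)
    t1 <- coverage_track(list(chrT = d1), 10)
    t2 <- coverage_track(list(chrT = d2), 10)
    ts <- coverage_track(list(chrT = d1 + d2), 20)
    ws <- data.frame(chrom = "chrT", start = c(0, 100, 2000),
                     end = c(70, 700, 4999))
    expect_equal(window_counts(ts, ws),
                 window_counts(t1, ws) + window_counts(t2, ws))
  })
})

test_that("genome_layout and interval validation reject bad input", {
  expect_error(genome_layout(c("a", "a"), c(10, 10)), "unique")
  expect_error(genome_layout("a", 0), "> 0")
  expect_error(genomic_intervals("c1", 10, 10), "start < end")
  lay <- genome_layout("c1", 100)
  expect_error(genomic_intervals("c1", 0, 200, layout = lay), "past")
  expect_error(genomic_intervals("cX", 0, 10, layout = lay), "not in")
})

test_that("GMT reading yields named member lists", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg4"), f)
  gs <- read_gmt(f)
  expect_equal(gs, list(setA = c("g1", "g2", "g3"), setB = "g4"))
  writeLines("bad\tonlydesc", f)
  expect_error(read_gmt(f), "line 1")
})
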