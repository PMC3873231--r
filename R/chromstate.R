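# Feature annotation of peaks, presence thresholds for marks over 1 kb
# bins, TSS mark co-occurrence, pattern classification of bound bins, and
# CpG-island methylation binning.

#' Annotate peaks with genomic feature flags
#'
#' Each flag is independently true on >= 1 bp intersection: promoter
#' (TSS +/- 3 kb), TSS, TES, exon, intron, gene body (TSS to TES);
#' intergenic means not overlapping any gene body.  A single peak can
#' carry several flags.
#'
#' @param peaks peak interval data.frame.
#' @param transcripts deduplicated transcript data.frame (with exon
#'   lists where available).
#' @param promoter_flank promoter half-width (default 3000).
#' @return `peaks` with appended logical columns promoter/tss/tes/exon/
#'   intron/gene_body/intergenic.
#' @export
annotate_peak_features <- function(peaks, transcripts,
                                   promoter_flank = 3000) {
  tss_iv <- data.frame(chrom = transcripts$chrom,
                       start = transcripts$tss, end = transcripts$tss + 1)
  tes_iv <- data.frame(chrom = transcripts$chrom,
                       start = transcripts$tes, end = transcripts$tes + 1)
  prom <- data.frame(chrom = transcripts$chrom,
                     start = pmax(0, transcripts$tss - promoter_flank),
                     end = transcripts$tss + promoter_flank)
  body <- data.frame(chrom = transcripts$chrom,
                     start = pmin(transcripts$tss, transcripts$tes),
                     end = pmax(transcripts$tss, transcripts$tes))
  exons <- do.call(rbind, lapply(seq_len(nrow(transcripts)), function(i)
    transcript_exons(transcripts[i, , drop = FALSE])))
  introns <- if (!is.null(exons) && nrow(exons)) {
    # gene body minus exons, per the union over transcripts
    b <- as_granges(body); e <- as_granges(exons)
    from_granges(GenomicRanges::setdiff(GenomicRanges::reduce(b),
                                        GenomicRanges::reduce(e),
                                        ignore.strand = TRUE))
  } else body[0, ]
  peaks$promoter <- overlap_any(peaks, prom)
  peaks$tss <- overlap_any(peaks, tss_iv)
  peaks$tes <- overlap_any(peaks, tes_iv)
  peaks$exon <- if (!is.null(exons) && nrow(exons))
    overlap_any(peaks, exons) else rep(FALSE, nrow(peaks))
  peaks$intron <- if (nrow(introns)) overlap_any(peaks, introns)
    else rep(FALSE, nrow(peaks))
  peaks$gene_body <- overlap_any(peaks, body)
  peaks$intergenic <- !peaks$gene_body
  peaks
}

#' Rank-ordered elbow threshold (super-enhancer style)
#'
#' Values are sorted ascending and both rank and value are scaled to
#' `[0, 1]`.  The threshold is the value at the tangent point of the
#' scaled rank curve with a slope-1 line: the point farthest below the
#' unit diagonal, i.e. the point where the (convex) curve's tangent
#' passes slope 1 and beyond which values take off faster than rank.
#' Ties go to the highest qualifying index, so an exactly linear ramp
#' (slope identically 1 everywhere) thresholds at the final point.
#'
#' @param bin_values numeric vector with at least 2 distinct values.
#' @return the threshold value; "presence" downstream means strictly above
#'   it.
#' @export
rank_elbow_threshold <- function(bin_values) {
  y <- sort(bin_values)
  n <- length(y)
  if (length(unique(y)) < 2L) stop("need at least 2 distinct values")
  ys <- (y - y[1]) / (y[n] - y[1])
  xs <- (seq_len(n) - 1) / (n - 1)
  d <- ys - xs
  idx <- which(d <= min(d) + 1e-12)
  y[idx[length(idx)]]
}

#' Mark presence at TSSs via sliding 1 kb bins
#'
#' Present iff any 1 kb bin, slid at `step` bp across
#' `[TSS - flank, TSS + flank]`, has RPKM strictly above the threshold.
#'
#' @param transcripts transcript data.frame.
#' @param track `coverage_track` of the mark.
#' @param threshold RPKM threshold (from [rank_elbow_threshold()]).
#' @param flank half-width around the TSS (default 3000).
#' @param bin_size sliding bin size (default 1000).
#' @param step slide step (default 100).
#' @return logical vector, one flag per transcript.
#' @export
tss_mark_presence <- function(transcripts, track, threshold, flank = 3000,
                              bin_size = 1000, step = 100) {
  cums <- track_cumsums(track)
  vapply(seq_len(nrow(transcripts)), function(i) {
    ch <- transcripts$chrom[i]
    if (!ch %in% names(cums)) return(FALSE)
    L <- length(cums[[ch]]) - 1L
    starts <- seq(transcripts$tss[i] - flank,
                  transcripts$tss[i] + flank - bin_size, by = step)
    ends <- starts + bin_size
    sums <- window_depth_sums(cums[[ch]], pmax(0, starts),
                              pmin(L, ends))
    rpkm <- (sums / track$fragment_extension) * 1e9 /
      (bin_size * track$total_mapped)
    any(rpkm > threshold)
  }, logical(1))
}

#' Classify bound 1 kb bins into chromatin patterns
#'
#' Patterns, applied in precedence order to every bound bin:
#' 1 = H3K4me3 present and TSS overlap (active promoter);
#' 2 = H3K27me3 present and TSS overlap (inactive promoter);
#' 3 = H3K9me3 present; 4 = H3K27ac present without TSS overlap (putative
#' enhancer); 5 = no mark present; anything else falls into "other".
#'
#' @param presence data.frame (or list) of logical vectors `h3k4me3`,
#'   `h3k27me3`, `h3k9me3`, `h3k27ac` over the bound bins.
#' @param tss_overlap logical vector: bin overlaps a TSS.
#' @return list with `pattern` (character vector, "1".."5"/"other") and
#'   `percent` (named percentages over all bound bins, summing to 100).
#' @export
pattern_classify <- function(presence, tss_overlap) {
  k4 <- presence$h3k4me3; k27me <- presence$h3k27me3
  k9 <- presence$h3k9me3; k27ac <- presence$h3k27ac
  n <- length(tss_overlap)
  stopifnot(length(k4) == n, length(k27me) == n, length(k9) == n,
            length(k27ac) == n)
  pat <- rep("other", n)
  none <- !k4 & !k27me & !k9 & !k27ac
  pat[none] <- "5"
  pat[k27ac & !tss_overlap] <- "4"
  pat[k9] <- "3"
  pat[k27me & tss_overlap] <- "2"
  pat[k4 & tss_overlap] <- "1"
  lev <- c("1", "2", "3", "4", "5", "other")
  pct <- 100 * table(factor(pat, levels = lev)) / max(n, 1L)
  list(pattern = pat, percent = stats::setNames(as.numeric(pct), lev))
}

#' Methylation fraction of an island
#'
#' @param meth_reads methylated read count.
#' @param total_reads total sequenced reads (> 0; islands with 0 total
#'   should be dropped by the caller).
#' @return fraction in `[0, 1]`.
#' @export
methylation_fraction <- function(meth_reads, total_reads) {
  if (any(total_reads <= 0)) stop("total_reads must be positive")
  f <- meth_reads / total_reads
  if (any(f < 0 | f > 1)) stop("methylated reads exceed total reads")
  f
}

methylation_bin_edges <- function() {
  list(labels = c("x=0", "0<x<10", "10<=x<20", "20<=x<30", "30<=x<40",
                  "40<=x<50", "50<=x<60", "60<=x<70", "70<=x<80",
                  "80<=x<90", "90<=x<=100"))
}

# bin index (1..11) for methylation fractions in [0,1]
methylation_bin_index <- function(fraction) {
  idx <- ifelse(fraction == 0, 1L,
         ifelse(fraction < 0.1, 2L, pmin(2L + floor(fraction * 10), 11L)))
  as.integer(idx)
}

#' Build the methylation bin table from per-bin counts
#'
#' Computes percentages within the bound and total columns and a two-sided
#' two-sample proportion comparison per bin (bound column against the
#' total column).
#'
#' @param bound_counts,total_counts integer vectors of length 11, one per
#'   methylation bin (`x=0`, `0<x<10`, ten-point bins up to
#'   `90<=x<=100`).
#' @param test `"z"` for the pooled two-proportion z-test (default) or
#'   `"prop.test"` for the continuity-corrected chi-square version.
#' @return data.frame with bin, bound, bound_pct, total, total_pct, pval.
#' @export
methylation_bin_table <- function(bound_counts, total_counts,
                                  test = c("z", "prop.test")) {
  test <- match.arg(test)
  stopifnot(length(bound_counts) == 11L, length(total_counts) == 11L)
  if (any(bound_counts > total_counts))
    stop("bound counts cannot exceed total counts")
  nb <- sum(bound_counts); nt <- sum(total_counts)
  if (nt == 0L) stop("empty island set")
  pval <- vapply(seq_len(11L), function(i) {
    x <- c(bound_counts[i], total_counts[i])
    n <- c(nb, nt)
    if (test == "z") {
      p1 <- x[1] / n[1]; p2 <- x[2] / n[2]
      pp <- sum(x) / sum(n)
      se <- sqrt(pp * (1 - pp) * (1 / n[1] + 1 / n[2]))
      if (se == 0) return(1)
      2 * stats::pnorm(-abs((p1 - p2) / se))
    } else {
      stats::prop.test(x, n)$p.value
    }
  }, numeric(1))
  data.frame(bin = methylation_bin_edges()$labels,
             bound = bound_counts,
             bound_pct = round(100 * bound_counts / nb, 2),
             total = total_counts,
             total_pct = round(100 * total_counts / nt, 2),
             pval = pval,
             stringsAsFactors = FALSE)
}

#' Methylation decile table of CpG islands split by peak overlap
#'
#' Islands are flagged as bound iff they overlap a peak by at least 1 bp,
#' binned by methylation fraction (`x=0` separately, then ten-point bins,
#' the last closed at 100%), and tabulated with a per-bin two-sided
#' proportion comparison of the bound column against the total column.
#'
#' @param islands CpG-island interval data.frame.
#' @param methylation numeric methylation fractions in `[0, 1]`, parallel
#'   to `islands` (islands with undefined fractions should be dropped
#'   upstream).
#' @param peaks peak interval data.frame.
#' @param test see [methylation_bin_table()].
#' @return the [methylation_bin_table()] data.frame, with attribute
#'   `bound` (logical per island).
#' @export
methylation_decile_table <- function(islands, methylation, peaks,
                                     test = c("z", "prop.test")) {
  if (nrow(islands) == 0L) stop("empty island set")
  stopifnot(length(methylation) == nrow(islands))
  if (any(methylation < 0 | methylation > 1, na.rm = TRUE))
    stop("methylation fractions must lie in [0, 1]")
  keep <- !is.na(methylation)
  if (!all(keep)) {
    warning(sum(!keep), " island(s) without methylation dropped")
    islands <- islands[keep, , drop = FALSE]
    methylation <- methylation[keep]
  }
  bound <- overlap_any(islands, peaks)
  idx <- methylation_bin_index(methylation)
  total_counts <- tabulate(idx, nbins = 11L)
  bound_counts <- tabulate(idx[bound], nbins = 11L)
  out <- methylation_bin_table(bound_counts, total_counts,
                               test = match.arg(test))
  attr(out, "bound") <- bound
  out
}
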