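# Composite (metagene) profiles and heatmap matrices.
#
# All profile operations are linear in the track and strand-aware:
# transcript-relative windows on the minus strand are flipped so that
# "downstream" always means 5'->3'.  Composite averaging across
# transcripts is unweighted.

#' TSS-anchored composite profile
#'
#' Windows of `window` bases are tiled across `[TSS - flank, TSS + flank)`
#' (any remainder truncated), oriented 5'->3'; the window value is the
#' per-base mean depth; the profile is the unweighted mean over
#' transcripts with a Monte-Carlo standard error.
#'
#' @param track a `coverage_track`.
#' @param transcripts deduplicated transcript data.frame.
#' @param flank flank size in bases (default 5000).
#' @param window window size in bases (default 70).
#' @param rpm scale values per million mapped fragments.
#' @return data.frame with position (window center relative to TSS),
#'   value, se and n (transcripts contributing).
#' @export
tss_profile <- function(track, transcripts, flank = 5000, window = 70,
                        rpm = FALSE) {
  mat <- tss_window_matrix(track, transcripts, flank, window, rpm)
  n <- colSums(!is.na(mat))
  if (all(n == 0L)) stop("no transcript windows inside the genome")
  value <- colMeans(mat, na.rm = TRUE)
  se <- apply(mat, 2, function(col) {
    col <- col[!is.na(col)]
    if (length(col) > 1L) stats::sd(col) / sqrt(length(col)) else NA_real_
  })
  n_win <- ncol(mat)
  pos <- -flank + (seq_len(n_win) - 0.5) * window
  data.frame(position = pos, value = value, se = se, n = n)
}

# transcripts x windows matrix of per-base mean depth in TSS-anchored
# windows; windows leaving the chromosome are NA for that transcript.
tss_window_matrix <- function(track, transcripts, flank, window,
                              rpm = FALSE, anchor = "tss") {
  n_win <- floor(2 * flank / window)
  if (n_win < 1L) stop("flank smaller than window")
  cums <- track_cumsums(track)
  mat <- matrix(NA_real_, nrow(transcripts), n_win)
  span <- n_win * window
  for (i in seq_len(nrow(transcripts))) {
    ch <- transcripts$chrom[i]
    if (!ch %in% names(cums)) next
    L <- length(cums[[ch]]) - 1L
    a <- if (anchor == "tss") transcripts$tss[i] else transcripts$tes[i]
    # windows tile left-aligned from a - flank; any remainder past the
    # last full window (when 2*flank is not a multiple) is truncated
    left <- if (transcripts$strand[i] == "-") a + flank - span else a - flank
    starts <- left + (seq_len(n_win) - 1) * window
    ends <- starts + window
    ok <- starts >= 0 & ends <= L
    v <- rep(NA_real_, n_win)
    if (any(ok))
      v[ok] <- window_depth_sums(cums[[ch]], starts[ok], ends[ok]) / window
    if (transcripts$strand[i] == "-") v <- rev(v)
    mat[i, ] <- v
  }
  if (rpm) mat <- mat * 1e6 / track$total_mapped
  mat
}

#' Scaled gene-body composite profile
#'
#' Gene bodies strictly longer than `min_length` are divided into
#' `body_bins` equal bins (1% of gene length each by default); the per-bin
#' per-base mean depth is averaged across genes.  Flanks around TSS and
#' TES are profiled as in [tss_profile()].
#'
#' @param track a `coverage_track`.
#' @param transcripts transcript data.frame.
#' @param body_bins number of body bins (default 100).
#' @param flank flank size (default 5000); set 0 to skip flanks.
#' @param window flank window size (default 70).
#' @param min_length minimum gene length, strict (default 2000).
#' @return list with `body` (data.frame bin/value), `upstream` and
#'   `downstream` flank profiles (or NULL), and `n_genes`.
#' @export
genebody_profile <- function(track, transcripts, body_bins = 100L,
                             flank = 5000, window = 70,
                             min_length = 2000) {
  len <- abs(transcripts$tes - transcripts$tss)
  tx <- transcripts[len > min_length, , drop = FALSE]
  if (nrow(tx) == 0L) stop("no gene bodies longer than ", min_length)
  cums <- track_cumsums(track)
  acc <- matrix(NA_real_, nrow(tx), body_bins)
  for (i in seq_len(nrow(tx))) {
    ch <- tx$chrom[i]
    if (!ch %in% names(cums)) next
    bounds <- seq(tx$tss[i], tx$tes[i], length.out = body_bins + 1L)
    s <- pmin(bounds[-length(bounds)], bounds[-1])
    e <- pmax(bounds[-length(bounds)], bounds[-1])
    # bounds run TSS -> TES, so bin 1 is the 5' end on either strand
    v <- window_depth_sums(cums[[ch]], floor(s), ceiling(e)) /
      pmax(ceiling(e) - floor(s), 1)
    acc[i, ] <- v
  }
  body <- data.frame(bin = seq_len(body_bins),
                     value = colMeans(acc, na.rm = TRUE))
  up <- down <- NULL
  if (flank > 0) {
    up <- tss_profile(track, tx, flank = flank, window = window)
    tes_tx <- tx; tes_tx$tss <- tx$tes
    down <- tss_profile(track, tes_tx, flank = flank, window = window)
  }
  list(body = body, upstream = up, downstream = down, n_genes = nrow(tx))
}

#' Promoter heatmap matrices ranked by a signal track
#'
#' Bins the interval `[from, to)` relative to each TSS (strand-oriented)
#' into `n_bins` equal bins, ranks transcripts by descending total ranking
#' signal, and emits every passenger matrix (and any extra per-transcript
#' vectors) in the same row order.
#'
#' @param ranking_track `coverage_track` used for ranking (e.g. the
#'   factor's signal).
#' @param transcripts transcript data.frame.
#' @param passenger_tracks named list of `coverage_track`s profiled in the
#'   ranked order.
#' @param from,to interval relative to the TSS (defaults -7000, +3000;
#'   negative = upstream).
#' @param n_bins number of bins (default 20).
#' @param extra named list of per-transcript vectors (e.g. expression)
#'   reordered alongside.
#' @return list with `order` (transcript ids, ranked), `ranking` matrix,
#'   `passengers` (list of matrices) and `extra` (reordered vectors).
#' @export
promoter_matrix <- function(ranking_track, transcripts,
                            passenger_tracks = list(),
                            from = -7000, to = 3000, n_bins = 20L,
                            extra = list()) {
  rank_mat <- promoter_bin_matrix(ranking_track, transcripts, from, to,
                                  n_bins)
  total <- rowSums(rank_mat, na.rm = TRUE)
  ord <- order(-total, transcripts$id)
  pass <- lapply(passenger_tracks, function(tr)
    promoter_bin_matrix(tr, transcripts, from, to, n_bins)[ord, ,
                                                           drop = FALSE])
  list(order = transcripts$id[ord],
       ranking = rank_mat[ord, , drop = FALSE],
       passengers = pass,
       extra = lapply(extra, function(v) v[ord]))
}

promoter_bin_matrix <- function(track, transcripts, from, to, n_bins) {
  bin_w <- (to - from) / n_bins
  cums <- track_cumsums(track)
  mat <- matrix(NA_real_, nrow(transcripts), n_bins)
  rownames(mat) <- transcripts$id
  for (i in seq_len(nrow(transcripts))) {
    ch <- transcripts$chrom[i]
    if (!ch %in% names(cums)) next
    L <- length(cums[[ch]]) - 1L
    plus <- transcripts$strand[i] != "-"
    if (plus) {
      starts <- transcripts$tss[i] + from + (seq_len(n_bins) - 1) * bin_w
    } else {
      starts <- transcripts$tss[i] - to + (seq_len(n_bins) - 1) * bin_w
    }
    ends <- starts + bin_w
    v <- window_depth_sums(cums[[ch]], pmax(0, starts), pmin(L, ends)) /
      bin_w
    v[starts < 0 | ends > L] <- NA
    if (!plus) v <- rev(v)
    mat[i, ] <- v
  }
  mat
}

#' Iterative gene filter chain for DamID promoter heatmaps
#'
#' Applies, in order: (1) restriction to an allowed chromosome set;
#' (2) non-missing expression; (3) at least one probe in every TSS bin;
#' (4) unique TSS; (5) neighbor exclusion (no other TSS within
#' `up_exclude` upstream or `down_exclude` downstream, strand-oriented).
#' Reports the count after each step.
#'
#' @param transcripts transcript data.frame.
#' @param expression named numeric vector (NA = missing), names =
#'   transcript ids.
#' @param probes probe interval data.frame (array coverage).
#' @param chroms allowed chromosome names (default: all present).
#' @param from,to,n_bins TSS bin layout as in [promoter_matrix()].
#' @param up_exclude,down_exclude neighbor exclusion distances
#'   (defaults 7000 / 3000).
#' @return list with `ids` (retained transcript ids) and `counts` (named
#'   count after each step).
#' @export
damid_heatmap_gene_filter <- function(transcripts, expression, probes,
                                      chroms = unique(transcripts$chrom),
                                      from = -7000, to = 3000,
                                      n_bins = 20L, up_exclude = 7000,
                                      down_exclude = 3000) {
  counts <- c(input = nrow(transcripts))
  tx <- transcripts[transcripts$chrom %in% chroms, , drop = FALSE]
  counts["chromosomes"] <- nrow(tx)
  tx <- tx[!is.na(expression[tx$id]), , drop = FALSE]
  counts["expression"] <- nrow(tx)
  if (nrow(tx)) {
    probe_centers <- (probes$start + probes$end) / 2
    bin_w <- (to - from) / n_bins
    covered <- vapply(seq_len(nrow(tx)), function(i) {
      plus <- tx$strand[i] != "-"
      lo <- if (plus) tx$tss[i] + from else tx$tss[i] - to
      cen <- probe_centers[probes$chrom == tx$chrom[i]]
      if (!length(cen)) return(FALSE)
      b <- floor((cen - lo) / bin_w)
      all((seq_len(n_bins) - 1L) %in% b)
    }, logical(1))
    tx <- tx[covered, , drop = FALSE]
  }
  counts["probe_coverage"] <- nrow(tx)
  key <- paste(tx$chrom, tx$tss)
  tx <- tx[!(key %in% key[duplicated(key)]), , drop = FALSE]
  counts["unique_tss"] <- nrow(tx)
  if (nrow(tx)) {
    isolated <- vapply(seq_len(nrow(tx)), function(i) {
      plus <- tx$strand[i] != "-"
      lo <- if (plus) tx$tss[i] - up_exclude else tx$tss[i] - down_exclude
      hi <- if (plus) tx$tss[i] + down_exclude else tx$tss[i] + up_exclude
      others <- transcripts$tss[transcripts$chrom == tx$chrom[i] &
                                  transcripts$id != tx$id[i]]
      !any(others >= lo & others <= hi)
    }, logical(1))
    tx <- tx[isolated, , drop = FALSE]
  }
  counts["no_neighbors"] <- nrow(tx)
  list(ids = tx$id, counts = counts)
}

#' Filter matrix rows by mean absolute deviation
#'
#' A row is retained iff `mean(|x - mean(x)|)` strictly exceeds the
#' threshold, dropping transcripts whose binned signal barely varies.
#'
#' @param mat numeric matrix (rows = transcripts).
#' @param threshold MAD threshold (default 1.0, strict).
#' @return logical vector of retained rows.
#' @export
mad_row_filter <- function(mat, threshold = 1.0) {
  mad_v <- apply(as.matrix(mat), 1, function(x) mean(abs(x - mean(x))))
  mad_v > threshold
}

#' Signal profiles around peak centers, split by TSS overlap
#'
#' Peaks are stratified by whether they overlap any TSS +/- `tss_flank`
#' window (by at least 1 bp).  For each stratum and track, values are
#' per-window per-million-fragment means across peaks over
#' `[center - flank, center + flank)` in `window`-bp windows.  The peak
#' center is `start + floor(length/2)`.
#'
#' @param tracks named list of `coverage_track`s.
#' @param peaks peak interval data.frame.
#' @param transcripts transcript data.frame supplying TSSs.
#' @param flank flank around the peak center (default 3000).
#' @param window window size (default 60).
#' @param tss_flank TSS window half-width for stratification
#'   (default 3000).
#' @return data.frame with track, stratum ("tss"/"non_tss"), position,
#'   value, n_peaks; an empty stratum is omitted with a warning.
#' @export
peak_center_profile <- function(tracks, peaks, transcripts, flank = 3000,
                                window = 60, tss_flank = 3000) {
  tssw <- data.frame(chrom = transcripts$chrom,
                     start = pmax(0, transcripts$tss - tss_flank),
                     end = transcripts$tss + tss_flank)
  at_tss <- overlap_any(peaks, tssw)
  centers <- peaks$start + floor((peaks$end - peaks$start) / 2)
  anchors <- data.frame(id = seq_len(nrow(peaks)), chrom = peaks$chrom,
                        strand = "+", tss = centers, tes = centers + 1,
                        stringsAsFactors = FALSE)
  out <- list()
  for (stratum in c("tss", "non_tss")) {
    sel <- if (stratum == "tss") at_tss else !at_tss
    if (!any(sel)) {
      warning("empty ", stratum, " stratum; profile omitted")
      next
    }
    for (nm in names(tracks)) {
      prof <- tss_profile(tracks[[nm]], anchors[sel, , drop = FALSE],
                          flank = flank, window = window, rpm = TRUE)
      out[[length(out) + 1L]] <- data.frame(
        track = nm, stratum = stratum, position = prof$position,
        value = prof$value, n_peaks = sum(sel),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
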