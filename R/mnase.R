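# MNase-seq nucleosome occupancy: fragment size selection, midpoint
# conversion, seeded downsampling and TSS-aligned quartile metagenes.

#' MNase analysis parameters
#'
#' @param min_len,max_len retained fragment length range, inclusive
#'   (defaults 120-180, the mononucleosome size band).
#' @param smoothing_period moving-average width in positions (default 50).
#' @param norm_flank half-width of the normalization region around the TSS
#'   (default 5000).
#' @param quartile_flank half-width of the region used to rank transcripts
#'   by factor occupancy (default 3000).
#' @return parameter list.
#' @export
mnase_params <- function(min_len = 120L, max_len = 180L,
                         smoothing_period = 50L, norm_flank = 5000,
                         quartile_flank = 3000) {
  stopifnot(min_len < max_len, smoothing_period >= 1L)
  list(min_len = min_len, max_len = max_len,
       smoothing_period = smoothing_period, norm_flank = norm_flank,
       quartile_flank = quartile_flank)
}

#' Size-select fragments and convert to midpoints
#'
#' Retains fragments with `min_len <= length <= max_len` (inclusive at
#' both ends) and converts each to its midpoint,
#' `start + floor(length/2)`.
#'
#' @param fragments data.frame with chrom/start/end.
#' @param params [mnase_params()].
#' @return list with `midpoints` (data.frame chrom/pos) and
#'   `retained_fraction`.
#' @export
size_filter_midpoints <- function(fragments, params = mnase_params()) {
  validate_intervals(fragments)
  len <- fragments$end - fragments$start
  keep <- len >= params$min_len & len <= params$max_len
  f <- fragments[keep, , drop = FALSE]
  list(midpoints = data.frame(
         chrom = f$chrom,
         pos = f$start + floor((f$end - f$start) / 2),
         stringsAsFactors = FALSE),
       retained_fraction = if (nrow(fragments)) mean(keep) else NA_real_)
}

#' Downsample midpoint sets to a common count
#'
#' Uniform sampling without replacement, seeded; every condition ends with
#' exactly `target_n` midpoints.  If some condition holds fewer than
#' `target_n`, the minimum count is used instead with a warning.
#'
#' @param midpoints_by_condition named list of midpoint data.frames
#'   (chrom/pos).
#' @param target_n target count; default: the minimum count across
#'   conditions.
#' @param seed RNG seed.
#' @return named list of downsampled midpoint data.frames.
#' @export
downsample_midpoints <- function(midpoints_by_condition, target_n = NULL,
                                 seed = 1L) {
  ns <- vapply(midpoints_by_condition, nrow, integer(1))
  if (is.null(target_n)) target_n <- min(ns)
  if (any(ns < target_n)) {
    warning("condition(s) with fewer than target_n midpoints; ",
            "using the minimum count")
    target_n <- min(ns)
  }
  withr::with_seed(as.integer(seed), {
    lapply(midpoints_by_condition, function(df) {
      idx <- sort(sample.int(nrow(df), target_n, replace = FALSE))
      df[idx, , drop = FALSE]
    })
  })
}

# per-transcript factor occupancy used for quartile assignment: sum of
# track depth over TSS +/- flank
transcript_signal <- function(transcripts, track, flank) {
  cums <- track_cumsums(track)
  vapply(seq_len(nrow(transcripts)), function(i) {
    ch <- transcripts$chrom[i]
    if (!ch %in% names(cums)) return(0)
    L <- length(cums[[ch]]) - 1L
    window_depth_sums(cums[[ch]], max(0, transcripts$tss[i] - flank),
                      min(L, transcripts$tss[i] + flank))
  }, numeric(1))
}

#' Assign transcripts to occupancy quartiles
#'
#' Equal-size rank-based groups (1 = lowest signal, 4 = highest); ties
#' broken by transcript id so the partition is deterministic.  Sizes
#' differ by at most 1.
#'
#' @param transcripts transcript data.frame.
#' @param track ranking `coverage_track`.
#' @param flank TSS half-width for the ranking signal (default 3000).
#' @return integer quartile (1-4) per transcript.
#' @export
mbd_quartiles <- function(transcripts, track, flank = 3000) {
  if (nrow(transcripts) < 4L) stop("need at least 4 transcripts")
  sig <- transcript_signal(transcripts, track, flank)
  ord <- order(sig, transcripts$id)
  q <- integer(nrow(transcripts))
  q[ord] <- ceiling(seq_len(nrow(transcripts)) * 4 /
                      nrow(transcripts))
  q
}

#' TSS-aligned quartile metagenes of nucleosome occupancy
#'
#' Midpoint counts per base position are aligned to each TSS (minus-strand
#' transcripts flipped), transcripts are split into occupancy quartiles by
#' factor signal in TSS +/- `quartile_flank`, each quartile profile is
#' divided by its own mean over +/- `norm_flank` (so the pre-smoothing
#' mean is exactly 1) and then smoothed with a centered moving average of
#' width `smoothing_period`.
#'
#' @param midpoints midpoint data.frame (chrom/pos).
#' @param transcripts transcript data.frame (>= 4 rows).
#' @param mbd3_track `coverage_track` used for quartile ranking.
#' @param params [mnase_params()].
#' @return list with `position` (relative to TSS), `raw` and `smoothed`
#'   (position x quartile matrices, normalized), and `quartile`
#'   assignments.
#' @export
quartile_metagene <- function(midpoints, transcripts, mbd3_track,
                              params = mnase_params()) {
  flank <- params$norm_flank
  qq <- mbd_quartiles(transcripts, mbd3_track, params$quartile_flank)
  npos <- 2L * flank + 1L
  pos <- seq(-flank, flank)
  raw <- matrix(0, npos, 4L,
                dimnames = list(NULL, paste0("Q", 1:4)))
  mid_by_chrom <- split(midpoints$pos, midpoints$chrom)
  for (i in seq_len(nrow(transcripts))) {
    mp <- mid_by_chrom[[transcripts$chrom[i]]]
    if (is.null(mp)) next
    rel <- mp - transcripts$tss[i]
    if (transcripts$strand[i] == "-") rel <- -rel
    rel <- rel[rel >= -flank & rel <= flank]
    if (length(rel))
      raw[, qq[i]] <- raw[, qq[i]] +
        tabulate(rel + flank + 1L, nbins = npos)
  }
  means <- colMeans(raw)
  if (any(means == 0)) stop("a quartile has no midpoints in range")
  norm <- sweep(raw, 2, means, "/")
  sm <- apply(norm, 2, moving_average, period = params$smoothing_period)
  list(position = pos, raw = norm, smoothed = sm, quartile = qq)
}
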