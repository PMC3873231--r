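# Replicate-spooling sliding-window hypergeometric peak caller for tiling
# arrays.  For each probe a genomic window of w bases centered on the probe
# midpoint collects the normalized values of the k probes inside it across
# all r replicates; x of those k*r values exceed the global 100s-th
# percentile threshold.  The enrichment p-value is the upper tail of a
# hypergeometric draw of k*r values from the N*r pooled values of which M
# exceed the threshold.  Peaks are maximal runs of consecutive probes with
# p below the threshold, discarding runs shorter than `min_probes`.

#' Peak-calling parameters
#'
#' @param w window size in bases (default 2000).
#' @param s signal quantile defining the exceedance threshold
#'   (default 0.95).
#' @param p p-value threshold (default 0.001).
#' @param min_probes minimum probes per peak (default 6).
#' @param empirical_m count threshold exceedances empirically (default)
#'   rather than nominally as `ceiling((1-s) * N * r)`; the two differ
#'   under ties.
#' @return parameter list.
#' @export
acme_params <- function(w = 2000, s = 0.95, p = 0.001, min_probes = 6L,
                        empirical_m = TRUE) {
  stopifnot(w > 0, s > 0, s < 1, p > 0, p < 1, min_probes >= 1L)
  list(w = w, s = s, p = p, min_probes = min_probes,
       empirical_m = empirical_m)
}

#' Pooled percentile threshold
#'
#' The 100s-th percentile of the pooled signal vector, under the
#' linear-interpolation definition of the percentile (R quantile type 7).
#' Downstream comparisons are strict (values must exceed the threshold).
#'
#' @param signals numeric vector pooled over probes and replicates.
#' @param s quantile in (0, 1).
#' @return the threshold value.
#' @export
percentile_threshold <- function(signals, s) {
  if (length(signals) == 0L) stop("empty signal vector")
  stats::quantile(signals, probs = s, type = 7, names = FALSE)
}

#' Upper-tail hypergeometric probability
#'
#' P(X >= x) for X ~ Hypergeometric(population, successes, draws): the
#' probability of seeing at least x successes when `draws` values are drawn
#' without replacement from a population containing `successes` successes.
#' Computed exactly in log space.
#'
#' @param x observed successes (the tail is inclusive of x).
#' @param draws number of values drawn.
#' @param successes successes in the population.
#' @param population population size.
#' @return the tail probability; 0 when `x > min(draws, successes)`, 1 when
#'   `x <= 0`.
#' @export
hypergeom_tail <- function(x, draws, successes, population) {
  if (successes < 0 || successes > population || draws < 0 ||
      draws > population || x < 0)
    stop("inconsistent hypergeometric arguments")
  if (x <= 0) return(1)
  if (x > min(draws, successes)) return(0)
  stats::phyper(x - 1, successes, population - successes, draws,
                lower.tail = FALSE)
}

#' Per-probe windowed enrichment p-values
#'
#' @param probes probe data.frame with chrom/start/end (0-based half-open).
#' @param signal numeric matrix, probes x replicates, of normalized values
#'   (all replicate chips share the probe set).
#' @param params [acme_params()].
#' @return data.frame (row per probe, input order) with `k` probes in
#'   window, `x` exceedances, `pval`, plus the scalar attributes
#'   `threshold`, `M` and `N`.
#' @export
probe_enrichment_pvalues <- function(probes, signal,
                                     params = acme_params()) {
  signal <- as.matrix(signal)
  if (nrow(signal) != nrow(probes))
    stop("signal matrix and probe set do not match")
  r <- ncol(signal)
  N <- nrow(probes)
  thr <- percentile_threshold(as.vector(signal), params$s)
  exceed <- rowSums(signal > thr)
  M <- if (params$empirical_m) sum(exceed)
       else ceiling((1 - params$s) * N * r)
  out <- data.frame(k = integer(N), x = integer(N), pval = numeric(N))
  centers <- (probes$start + probes$end) / 2
  for (ch in unique(probes$chrom)) {
    idx <- which(probes$chrom == ch)
    ord <- idx[order(centers[idx])]
    cen <- centers[ord]
    # probes whose midpoint falls inside [center - w/2, center + w/2]
    lo <- findInterval(cen - params$w / 2, cen, left.open = TRUE) + 1L
    hi <- findInterval(cen + params$w / 2, cen)
    cs <- c(0, cumsum(exceed[ord]))
    k <- hi - lo + 1L
    x <- cs[hi + 1L] - cs[lo]
    pv <- stats::phyper(x - 1, M, N * r - M, k * r, lower.tail = FALSE)
    pv[x <= 0] <- 1
    out$k[ord] <- k; out$x[ord] <- x; out$pval[ord] <- pv
  }
  attr(out, "threshold") <- thr
  attr(out, "M") <- M
  attr(out, "N") <- N
  out
}

#' Call peaks as runs of significant probes
#'
#' Maximal runs of consecutive probes (in genomic order per chromosome)
#' with `pval < p` become peaks spanning the first probe's start to the
#' last probe's end; runs with fewer than `min_probes` probes are
#' discarded.
#'
#' @param probes probe data.frame (chrom/start/end).
#' @param window_stats result of [probe_enrichment_pvalues()] (parallel to
#'   `probes`).
#' @param params [acme_params()].
#' @return peak data.frame with chrom/start/end/n_probes/min_p/score
#'   (score = -log10(min p)).
#' @export
call_peaks <- function(probes, window_stats, params = acme_params()) {
  peaks <- list()
  for (ch in unique(probes$chrom)) {
    idx <- which(probes$chrom == ch)
    ord <- idx[order(probes$start[idx])]
    sig <- window_stats$pval[ord] < params$p
    rl <- rle(sig)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    for (j in which(rl$values & rl$lengths >= params$min_probes)) {
      run <- ord[starts[j]:ends[j]]
      peaks[[length(peaks) + 1L]] <- data.frame(
        chrom = ch,
        start = probes$start[run[1L]],
        end = probes$end[run[length(run)]],
        n_probes = length(run),
        min_p = min(window_stats$pval[run]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(peaks) == 0L)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_probes = integer(),
                      min_p = numeric(), score = numeric()))
  out <- do.call(rbind, peaks)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out$score <- -log10(pmax(out$min_p, 1e-300))
  out
}

#' Assign peak target genes by TSS proximity
#'
#' A gene is a target iff some peak overlaps (by at least 1 bp, half-open)
#' the window `[TSS - radius, TSS + radius)`.
#'
#' @param peaks peak data.frame.
#' @param transcripts deduplicated transcript data.frame.
#' @param radius distance from the TSS in bases (default 3000).
#' @return character vector of target gene ids (sorted, unique).
#' @export
assign_target_genes <- function(peaks, transcripts, radius = 3000) {
  if (nrow(peaks) == 0L || nrow(transcripts) == 0L) return(character(0))
  win <- data.frame(chrom = transcripts$chrom,
                    start = transcripts$tss - radius,
                    end = transcripts$tss + radius,
                    stringsAsFactors = FALSE)
  # clip in case a TSS sits near the chromosome origin
  win$start <- pmax(win$start, 0)
  hit <- overlap_any(win, peaks)
  sort(unique(transcripts$id[hit]))
}
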