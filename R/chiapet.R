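# ChIA-PET pair filtering at TSS anchors, signal scoring of both ends and
# rank-ordered grouping.

#' Filter PET pairs to those anchored at a TSS
#'
#' A pair is retained iff at least one end overlaps some TSS +/- `flank`
#' window by >= 1 bp.  The overlapping end is designated end 1 (the TSS
#' end); when both ends qualify the end whose center is closer to its
#' nearest TSS becomes end 1 (ties keep the ends as given).
#'
#' @param pets PET data.frame (chrom1/start1/end1/chrom2/start2/end2).
#' @param transcripts deduplicated transcript data.frame.
#' @param flank TSS window half-width (default 3000).
#' @return the retained pairs, ends swapped where needed, with a logical
#'   `swapped` column.
#' @export
filter_anchor_pets <- function(pets, transcripts, flank = 3000) {
  e1 <- data.frame(chrom = pets$chrom1, start = pets$start1,
                   end = pets$end1, stringsAsFactors = FALSE)
  e2 <- data.frame(chrom = pets$chrom2, start = pets$start2,
                   end = pets$end2, stringsAsFactors = FALSE)
  tssw <- data.frame(chrom = transcripts$chrom,
                     start = pmax(0, transcripts$tss - flank),
                     end = transcripts$tss + flank)
  hit1 <- overlap_any(e1, tssw)
  hit2 <- overlap_any(e2, tssw)
  keep <- hit1 | hit2
  d1 <- end_tss_distance(e1, transcripts)
  d2 <- end_tss_distance(e2, transcripts)
  # swap when only end 2 anchors, or both anchor and end 2 is closer
  swap <- keep & (!hit1 | (hit2 & d2 < d1))
  out <- pets[keep, , drop = FALSE]
  sw <- swap[keep]
  if (any(sw)) {
    tmp <- out[sw, c("chrom1", "start1", "end1")]
    out[sw, c("chrom1", "start1", "end1")] <-
      out[sw, c("chrom2", "start2", "end2")]
    out[sw, c("chrom2", "start2", "end2")] <- tmp
  }
  out$swapped <- sw
  rownames(out) <- NULL
  out
}

# distance from each end's center to the nearest TSS on its chromosome
end_tss_distance <- function(ends, transcripts) {
  vapply(seq_len(nrow(ends)), function(i) {
    tss <- transcripts$tss[transcripts$chrom == ends$chrom[i]]
    if (!length(tss)) return(Inf)
    cen <- ends$start[i] + floor((ends$end[i] - ends$start[i]) / 2)
    min(abs(tss - cen))
  }, numeric(1))
}

#' Score both PET ends by local signal and assign nearest genes
#'
#' For each end, fragments within `[center - half_width,
#' center + half_width)` are counted (as fragment equivalents from the
#' coverage track) and scaled per million mapped fragments.  A gene id is
#' attached only when the end overlaps a TSS +/- `flank` window; the
#' nearest such gene by TSS distance is chosen (ties broken
#' lexicographically by id).
#'
#' @param pairs filtered PET data.frame from [filter_anchor_pets()].
#' @param track `coverage_track` of the factor's signal.
#' @param transcripts transcript data.frame.
#' @param half_width half-width around the end center (default 500).
#' @param flank TSS window half-width for gene assignment (default 3000).
#' @return `pairs` with end1_score, end2_score, end1_gene, end2_gene.
#' @export
pet_end_scores <- function(pairs, track, transcripts, half_width = 500,
                           flank = 3000) {
  score_end <- function(chrom, start, end) {
    cums <- track_cumsums(track)
    vapply(seq_along(chrom), function(i) {
      if (!chrom[i] %in% names(cums)) return(0)
      cs <- cums[[chrom[i]]]
      L <- length(cs) - 1L
      cen <- start[i] + floor((end[i] - start[i]) / 2)
      s <- window_depth_sums(cs, max(0, cen - half_width),
                             min(L, cen + half_width))
      (s / track$fragment_extension) * 1e6 / track$total_mapped
    }, numeric(1))
  }
  gene_end <- function(chrom, start, end) {
    vapply(seq_along(chrom), function(i) {
      tx <- transcripts[transcripts$chrom == chrom[i], , drop = FALSE]
      if (!nrow(tx)) return(NA_character_)
      hit <- tx$tss - flank < end[i] & tx$tss + flank > start[i]
      if (!any(hit)) return(NA_character_)
      tx <- tx[hit, , drop = FALSE]
      cen <- start[i] + floor((end[i] - start[i]) / 2)
      d <- abs(tx$tss - cen)
      tx$id[order(d, tx$id)][1]
    }, character(1))
  }
  pairs$end1_score <- score_end(pairs$chrom1, pairs$start1, pairs$end1)
  pairs$end2_score <- score_end(pairs$chrom2, pairs$start2, pairs$end2)
  pairs$end1_gene <- gene_end(pairs$chrom1, pairs$start1, pairs$end1)
  pairs$end2_gene <- gene_end(pairs$chrom2, pairs$start2, pairs$end2)
  pairs
}

#' Rank pairs by TSS-end score and split into groups
#'
#' Pairs are sorted by end-1 score in descending order (stable: ties keep
#' input order) and divided into `n_groups` groups of near-equal size
#' (sizes differ by at most 1); end-2 scores are emitted in the same
#' order.
#'
#' @param scored_pairs data.frame from [pet_end_scores()].
#' @param n_groups number of groups (default 10).
#' @return `scored_pairs` reordered, with `rank` and `group` columns.
#' @export
rank_group_ends <- function(scored_pairs, n_groups = 10L) {
  n <- nrow(scored_pairs)
  if (n < n_groups) {
    warning("fewer pairs than groups; groups of size >= 1 formed")
    n_groups <- max(1L, n)
  }
  ord <- order(-scored_pairs$end1_score)  # stable radix/shell order
  out <- scored_pairs[ord, , drop = FALSE]
  out$rank <- seq_len(n)
  out$group <- ceiling(out$rank * n_groups / n)
  rownames(out) <- NULL
  out
}
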