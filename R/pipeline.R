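# End-to-end demonstration pipeline on synthetic data: simulate ->
# normalize -> call peaks -> assign targets -> permutation overlap vs the
# planted truth -> gene-set enrichment -> promoter classes -> profiles ->
# chromatin-state patterns -> methylation table -> ChIA-PET ranking ->
# MNase metagenes, with truth-recovery metrics collected into a
# machine-readable report.

#' Demo pipeline configuration
#'
#' @param seed root seed; every stochastic stage derives its stream from
#'   it.
#' @param params [sim_params()] (its own seed is overridden by `seed`).
#' @param n_perm permutations for the overlap test (default 2000 to keep
#'   the demo quick; the reference analysis convention is 20000).
#' @param acme [acme_params()].
#' @return configuration list.
#' @export
demo_config <- function(seed = 1L, params = NULL, n_perm = 2000L,
                        acme = acme_params()) {
  p <- params %||% sim_params()
  p$seed <- as.integer(seed)
  list(seed = as.integer(seed), params = p, n_perm = n_perm, acme = acme)
}

# Jaccard index between a truth region and the union of called peaks on
# its chromosome (computed against the single best-overlapping peak run).
region_jaccard <- function(region, peaks) {
  pk <- peaks[peaks$chrom == region$chrom, , drop = FALSE]
  if (nrow(pk) == 0L) return(0)
  inter <- pmax(0, pmin(pk$end, region$end) - pmax(pk$start, region$start))
  if (all(inter == 0)) return(0)
  best <- which.max(inter)
  union <- (pk$end[best] - pk$start[best]) +
    (region$end - region$start) - inter[best]
  inter[best] / union
}

#' Truth-recovery metrics for called peaks
#'
#' @param peaks called peak data.frame.
#' @param truth_regions planted region data.frame.
#' @param w window size used by the caller (neighborhood for the
#'   false-peak check).
#' @param jaccard_min recovery threshold (default 0.5).
#' @return list with per-region jaccard, recovered fraction and the count
#'   of peaks fully outside every truth region +/- w.
#' @export
peak_recovery <- function(peaks, truth_regions, w = 2000,
                          jaccard_min = 0.5) {
  jac <- vapply(seq_len(nrow(truth_regions)), function(i)
    region_jaccard(truth_regions[i, ], peaks), numeric(1))
  neigh <- truth_regions
  neigh$start <- pmax(0, neigh$start - w); neigh$end <- neigh$end + w
  outside <- if (nrow(peaks)) sum(!overlap_any(peaks, neigh)) else 0L
  list(jaccard = jac,
       recovered_fraction = if (length(jac)) mean(jac >= jaccard_min)
                            else NA_real_,
       false_peaks = outside)
}

#' Run the full demo pipeline on synthetic data
#'
#' @param config [demo_config()].
#' @return a report list (see the methods vignette for the fields); pass
#'   it to [jsonlite::toJSON] for a machine-readable record.
#' @export
run_demo <- function(config = demo_config()) {
  p <- config$params
  ann <- make_genome_annotation(p)
  tx <- dedup_transcripts(ann$transcripts)

  # DamID arrays -> normalization -> peaks -> targets
  probes <- simulate_damid_arrays(ann, p)
  min_bin <- min(500L, max(2L, nrow(probes) %/% 5L))
  norm <- damid_normalize(probes, normalization_params(min_bin_probes =
                                                         min_bin))
  sig <- as.matrix(norm[, grep("^normalized_", names(norm)), drop = FALSE])
  wstats <- probe_enrichment_pvalues(norm, sig, config$acme)
  peaks <- call_peaks(norm, wstats, config$acme)
  targets <- assign_target_genes(peaks, tx)
  recovery <- peak_recovery(peaks, ann$truth$enriched_regions,
                            w = config$acme$w)

  # circular permutation overlap of peaks vs planted regions over
  # disjoined probe units
  units <- disjoin_intervals(norm[, c("chrom", "start", "end")])
  overlap <- if (nrow(peaks)) {
    permutation_overlap_test(
      unit_membership(units, peaks),
      unit_membership(units, ann$truth$enriched_regions),
      units$chrom,
      overlap_test_params(n_perm = config$n_perm,
                          seed = stage_seed(p$seed, "overlap")))
  } else NULL

  # gene-set enrichment of targets
  gene_sets <- list(luminal_like = ann$truth$luminal_like_geneset)
  enrich <- gene_set_enrichment(targets, tx$id, gene_sets)

  # promoter classes from synthetic sequence
  seqs <- simulate_promoter_sequences(ann, p)
  classes <- classify_promoters(seqs)
  class_tab <- table(classes$class)
  class_counts <- stats::setNames(as.integer(class_tab), names(class_tab))

  # profiles: TSS composite of the factor track, gene bodies
  tracks <- simulate_chip_tracks(ann, p)
  tssprof <- tss_profile(tracks$mbd3, tx, flank = 3000, window = 70)
  # shape assessed on 500 bp windows (11 across +/-2750, one centered on
  # the TSS) so the dip test is not dominated by per-window noise
  tsscoarse <- tss_profile(tracks$mbd3, tx, flank = 2750, window = 500)
  body <- genebody_profile(tracks$mbd3, tx, flank = 0)

  # chromatin state over 1 kb bins
  chrom_state <- demo_chromatin_state(ann, tracks, tx)

  # methylation decile table against the called peaks
  meth <- simulate_methylation(ann$islands, p,
                               bound = ann$islands$gene %in%
                                 ann$truth$bound_genes)
  meth_table <- if (nrow(peaks))
    methylation_decile_table(meth, meth$fraction, peaks) else NULL

  # ChIA-PET anchors and ranking
  pets <- simulate_pets(ann, p)
  kept <- filter_anchor_pets(pets, tx)
  scored <- pet_end_scores(kept, tracks$mbd3, tx)
  ranked <- rank_group_ends(scored)
  pet_rho <- if (nrow(ranked) >= 4)
    stats::cor(ranked$end1_score, ranked$end2_score,
               method = "spearman") else NA_real_

  # MNase metagenes, control vs depleted
  mnase <- demo_mnase(ann, tracks, tx, p)

  list(
    seed = config$seed,
    n = list(transcripts = nrow(tx), probes = nrow(norm),
             peaks = nrow(peaks), targets = length(targets),
             planted_regions = nrow(ann$truth$enriched_regions),
             pets = nrow(pets), pets_kept = nrow(kept)),
    peaks = peaks,
    recovery = recovery,
    overlap = if (!is.null(overlap))
      overlap[c("observed", "expected", "odds_ratio", "pval", "ci")]
      else NULL,
    enrichment = enrich,
    promoter_classes = class_counts,
    tss_shape = tss_profile_shape(tsscoarse),
    chromatin = chrom_state,
    methylation = meth_table,
    pet_spearman = pet_rho,
    mnase = mnase)
}

#' Assess the bimodal shape of a TSS composite profile
#'
#' Reports the position of the maximum on each side of the TSS and
#' whether the TSS-containing window is a local minimum of the
#' inter-peak region (strictly below both flanking maxima and equal to
#' the minimum between them).
#'
#' @param profile data.frame from [tss_profile()].
#' @return list with left_max_pos, right_max_pos, tss_value and
#'   tss_is_local_min.
#' @export
tss_profile_shape <- function(profile) {
  left <- profile[profile$position < 0, ]
  right <- profile[profile$position > 0, ]
  lm_pos <- left$position[which.max(left$value)]
  rm_pos <- right$position[which.max(right$value)]
  mid <- profile[profile$position >= lm_pos & profile$position <= rm_pos, ]
  tss_idx <- which.min(abs(profile$position))
  tss_val <- profile$value[tss_idx]
  list(left_max_pos = lm_pos, right_max_pos = rm_pos,
       tss_value = tss_val,
       tss_is_local_min = isTRUE(tss_val <= min(mid$value) + 1e-12 &&
                                   tss_val < max(left$value) &&
                                   tss_val < max(right$value)))
}

# chromatin-state sub-pipeline: elbow thresholds over 1 kb bins, pattern
# classification of factor-bound bins, recovery of planted patterns
demo_chromatin_state <- function(ann, tracks, tx) {
  bins <- genome_bins(ann$layout, 1000)
  rpkm <- lapply(tracks[c("mbd3", "h3k4me3", "h3k27ac", "h3k27me3",
                          "h3k9me3")], bin_rpkm, bins = bins)
  thr <- lapply(rpkm, rank_elbow_threshold)
  present <- Map(function(v, t) v > t, rpkm, thr)
  tss_iv <- data.frame(chrom = tx$chrom, start = tx$tss,
                       end = tx$tss + 1)
  tss_ov <- overlap_any(bins, tss_iv)
  bound_bins <- present$mbd3
  cls <- pattern_classify(
    list(h3k4me3 = present$h3k4me3[bound_bins],
         h3k27me3 = present$h3k27me3[bound_bins],
         h3k9me3 = present$h3k9me3[bound_bins],
         h3k27ac = present$h3k27ac[bound_bins]),
    tss_ov[bound_bins])
  # planted evaluation sets: TSS bins of bound genes; enhancer bins
  bound_tss <- tx[tx$id %in% ann$truth$bound_genes, , drop = FALSE]
  tssbin_idx <- which(overlap_any(
    bins, data.frame(chrom = bound_tss$chrom, start = bound_tss$tss,
                     end = bound_tss$tss + 1)))
  enh_centers <- with(ann$truth$enhancer_links,
                      data.frame(chrom = chrom,
                                 start = (start + end) / 2,
                                 end = (start + end) / 2 + 1))
  enhbin_idx <- if (nrow(enh_centers))
    which(overlap_any(bins, enh_centers)) else integer(0)
  all_pat <- rep(NA_character_, nrow(bins))
  all_pat[bound_bins] <- cls$pattern
  list(thresholds = unlist(thr),
       n_bound_bins = sum(bound_bins),
       percent = cls$percent,
       promoter_pattern1_rate = mean(all_pat[tssbin_idx] == "1",
                                     na.rm = FALSE),
       enhancer_pattern4_rate = if (length(enhbin_idx))
         mean(all_pat[enhbin_idx] == "4") else NA_real_)
}

# MNase sub-pipeline: simulate both conditions, size-filter, downsample,
# quartile metagenes and quartile-specific occupancy change at the
# planted -1/+2/+3/+4 positions
demo_mnase <- function(ann, tracks, tx, p) {
  ctrl <- simulate_mnase(ann, p, depleted = FALSE)
  depl <- simulate_mnase(ann, p, depleted = TRUE)
  mp <- mnase_params()
  f_ctrl <- size_filter_midpoints(ctrl, mp)
  f_depl <- size_filter_midpoints(depl, mp)
  ds <- downsample_midpoints(list(control = f_ctrl$midpoints,
                                  depleted = f_depl$midpoints),
                             seed = stage_seed(p$seed, "downsample"))
  mg_ctrl <- quartile_metagene(ds$control, tx, tracks$mbd3, mp)
  mg_depl <- quartile_metagene(ds$depleted, tx, tracks$mbd3, mp)
  # occupancy around the planted depleted nucleosome positions
  pos_idx <- planted_nucleosome_index(mg_ctrl$position, p)
  occ <- function(mg, q) mean(mg$smoothed[pos_idx, q])
  list(retained_fraction = c(control = f_ctrl$retained_fraction,
                             depleted = f_depl$retained_fraction),
       occupancy_change_q4 = occ(mg_depl, 4) - occ(mg_ctrl, 4),
       occupancy_change_q1 = occ(mg_depl, 1) - occ(mg_ctrl, 1),
       control = mg_ctrl, depleted = mg_depl)
}

# profile indices within +/-60 bp of the -1/+2/+3/+4 nucleosome centers
planted_nucleosome_index <- function(position, p) {
  centers <- c(-180, 120 + p$phasing_period * (1:3))
  which(vapply(position, function(x) any(abs(x - centers) <= 60),
               logical(1)))
}
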