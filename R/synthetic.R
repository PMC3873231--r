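# Seeded synthetic-data generators.
#
# The generators emulate the statistical structure the downstream stages
# assume: two-color promoter arrays with GC-dependent dye bias on one
# channel and planted log2 enrichment at bound promoters; extended-
# fragment coverage tracks with a bimodal promoter shape dipping at the
# TSS, 5'->3' gene-body decay, a TES bump and co-planted enhancer marks;
# bimodal CpG-island methylation biased low at bound promoters; PET pairs
# linking enhancers to TSSs plus TSS-free decoys; and phased nucleosomes
# flanking an NDR, with optional depletion of the -1/+2/+3/+4 nucleosomes
# at high-occupancy promoters.  Every generator derives an independent
# RNG stream from (seed, stage name), so adding a stage never perturbs
# another stage's draws.

#' Simulation parameters
#'
#' Defaults define the package's reference study conditions; see the
#' methods vignette for the rationale behind each value.
#'
#' @param seed root seed; every stage derives its own stream from it.
#' @param n_chrom,chrom_length genome shape (2 x 1 Mb).
#' @param n_transcripts total transcripts (60).
#' @param probe_spacing,probe_width,promoter_tile_flank array design:
#'   probes of `probe_width` bp every `probe_spacing` bp across
#'   TSS +/- `promoter_tile_flank`.
#' @param replicate_count r, number of replicate chips (>= 2).
#' @param enrichment_effect planted log2 enrichment at bound promoters.
#' @param gc_bias_amplitude slope of the linear GC dye bias added to the
#'   cy5 channel (log2 units per unit GC).
#' @param noise_sd per-channel Gaussian noise sd (log2 units).
#' @param frac_bound fraction of transcripts with a planted bound
#'   promoter (drawn among active ones).
#' @param frac_active fraction of transcripts that are "active" (CpG
#'   island, H3K4me3, expression).
#' @param meth_low_mean,meth_high_mean,meth_mix_weight two-mode
#'   methylation mixture: mode means and the low-mode weight for islands
#'   away from bound promoters (bound-promoter islands use weight 0.9).
#' @param ndr_depth_factor multiplier (< 1) applied to the -1/+2/+3/+4
#'   nucleosomes of high-occupancy promoters under depletion.
#' @param phasing_period nucleosome repeat length in bp.
#' @param phasing_amplitude fraction of non-background nucleosomal
#'   fragments that are phased (0 = flat density).
#' @param pet_decoy_rate decoy PET pairs per link-derived pair.
#' @param fragment_extension ChIP fragment extension (bases).
#' @param mnase_frags_per_tx MNase fragments simulated per transcript and
#'   condition.
#' @return parameter list of class `sim_params`.
#' @export
sim_params <- function(seed = 1L, n_chrom = 2L, chrom_length = 1e6,
                       n_transcripts = 60L, probe_spacing = 250L,
                       probe_width = 50L, promoter_tile_flank = 5000L,
                       replicate_count = 2L, enrichment_effect = 2.5,
                       gc_bias_amplitude = 2, noise_sd = 0.4,
                       frac_bound = 0.12, frac_active = 0.5,
                       meth_low_mean = 0.04, meth_high_mean = 0.96,
                       meth_mix_weight = 0.55, ndr_depth_factor = 0.5,
                       phasing_period = 190L, phasing_amplitude = 0.75,
                       pet_decoy_rate = 0.5, fragment_extension = 300L,
                       mnase_frags_per_tx = 1500L) {
  stopifnot(replicate_count >= 2L, enrichment_effect >= 0,
            meth_mix_weight >= 0, meth_mix_weight <= 1,
            frac_bound <= frac_active)
  structure(as.list(environment()), class = "sim_params")
}

#' Generate a genome layout, transcript annotation and ground truth
#'
#' Deterministic for a fixed seed.  Transcripts are placed with a mixture
#' of short and long inter-TSS gaps (so a realistic share of genes has
#' close neighbors), assigned strands, lengths, exons, activity classes
#' (active / H3K27me3 / H3K9me3 / silent), CpG islands at active
#' promoters and at a minority of inactive ones, a replicate expression
#' matrix (with a few missing values), and planted truth: bound-promoter
#' enrichment regions, enhancer-TSS links co-planted with H3K27ac, and a
#' "luminal-like" gene set concentrated in the bound genes.
#'
#' @param params [sim_params()].
#' @return list with layout, transcripts, islands, expression, genes
#'   (per-gene classes and levels) and truth (enriched_regions,
#'   enhancer_links, luminal_like_geneset, bound_genes).
#' @export
make_genome_annotation <- function(params = sim_params()) {
  p <- params
  layout <- genome_layout(paste0("chr", seq_len(p$n_chrom)),
                          rep(p$chrom_length, p$n_chrom))
  with_stage_seed(p$seed, "annotation", {
    per <- diff(round(seq(0, p$n_transcripts,
                          length.out = p$n_chrom + 1L)))
    tx_list <- list()
    for (ci in seq_len(p$n_chrom)) {
      n <- per[ci]
      if (n == 0L) next
      # inter-TSS gaps: half clustered (2-8 kb), half isolated (12-18 kb)
      close_gap <- stats::runif(n) < 0.5
      gaps <- ifelse(close_gap, stats::runif(n, 2000, 8000),
                     stats::runif(n, 12000, 18000))
      tss <- 15000 + cumsum(gaps)
      if (max(tss) > p$chrom_length - 15000)
        stop("requested transcripts denser than chromosome allows")
      strand <- sample(c("+", "-"), n, replace = TRUE)
      len <- round(stats::runif(n, 2500, 9000))
      tes <- ifelse(strand == "+", tss + len, tss - len)
      tx_list[[ci]] <- data.frame(
        id = sprintf("gene_%d_%02d", ci, seq_len(n)),
        chrom = layout$chrom_names[ci], strand = strand,
        tss = round(tss), tes = round(tes),
        stringsAsFactors = FALSE)
    }
    tx <- do.call(rbind, tx_list)
    if (is.null(tx))
      tx <- data.frame(id = character(), chrom = character(),
                       strand = character(), tss = numeric(),
                       tes = numeric(), stringsAsFactors = FALSE)
    # exons: 2-4 per gene, 5' -> 3'
    exon_cols <- t(vapply(seq_len(nrow(tx)), function(i) {
      lo <- min(tx$tss[i], tx$tes[i]); hi <- max(tx$tss[i], tx$tes[i])
      k <- sample(2:4, 1)
      cuts <- sort(c(lo, hi, round(stats::runif(2 * k - 2, lo, hi))))
      s <- cuts[seq(1, length(cuts) - 1, by = 2)]
      e <- pmax(cuts[seq(2, length(cuts), by = 2)], s + 1)
      c(paste(s, collapse = ","), paste(e, collapse = ","))
    }, character(2)))
    if (nrow(tx)) {
      tx$exon_starts <- exon_cols[, 1]; tx$exon_ends <- exon_cols[, 2]
    } else {
      tx$exon_starts <- character(0); tx$exon_ends <- character(0)
    }
    n <- nrow(tx)
    # activity classes
    cls <- rep("silent", n)
    if (n) {
      active <- sample(n, round(p$frac_active * n))
      cls[active] <- "active"
      rest <- setdiff(seq_len(n), active)
      k27 <- sample(rest, round(0.3 * length(rest)))
      cls[k27] <- "h3k27me3"
      k9 <- sample(setdiff(rest, k27), round(0.2 * length(rest)))
      cls[k9] <- "h3k9me3"
      # bound promoters drawn among active genes, with TSSs separated by
      # more than the caller window plus the planted region so every
      # planted region is resolvable as its own peak
      bound <- integer(0)
      for (g in sample(active)) {
        if (length(bound) >= round(p$frac_bound * n)) break
        near <- bound[tx$chrom[bound] == tx$chrom[g]]
        if (!length(near) || min(abs(tx$tss[near] - tx$tss[g])) > 6500)
          bound <- c(bound, g)
      }
    } else bound <- integer(0)
    mbd3_level <- numeric(n)
    mbd3_level[cls == "active"] <- stats::runif(sum(cls == "active"),
                                                0.1, 0.4)
    mbd3_level[bound] <- stats::runif(length(bound), 0.6, 1)
    genes <- data.frame(id = tx$id, class = cls, bound = logical(n),
                        mbd3_level = mbd3_level,
                        stringsAsFactors = FALSE)
    genes$bound[bound] <- TRUE
    # CpG islands: all active promoters + 30% of the rest
    isl_idx <- sort(c(which(cls == "active"),
                      sample(which(cls != "active"),
                             round(0.3 * sum(cls != "active")))))
    islands <- data.frame(chrom = tx$chrom[isl_idx],
                          start = pmax(0, tx$tss[isl_idx] - 400),
                          end = tx$tss[isl_idx] + 400,
                          gene = tx$id[isl_idx],
                          stringsAsFactors = FALSE)
    # expression: two replicates, active genes high; ~5% missing
    base <- ifelse(cls == "active",
                   stats::rnorm(n, 6, 1), stats::rnorm(n, 1, 0.5))
    expr <- cbind(rep1 = base + stats::rnorm(n, 0, 0.3),
                  rep2 = base + stats::rnorm(n, 0, 0.3))
    rownames(expr) <- tx$id
    if (n > 4) expr[sample(n, max(1, round(0.05 * n))), ] <- NA
    # truth: planted enrichment at bound promoters
    enriched <- data.frame(chrom = tx$chrom[bound],
                           start = pmax(0, tx$tss[bound] - 1500),
                           end = tx$tss[bound] + 1500,
                           gene = tx$id[bound],
                           stringsAsFactors = FALSE)
    enriched <- enriched[order(enriched$chrom, enriched$start), ,
                         drop = FALSE]
    truth <- list(enriched_regions = enriched,
                  bound_genes = tx$id[bound])
    truth$enhancer_links <- place_enhancers(tx, genes, layout, p)
    lum_n <- min(15L, length(bound))
    truth$luminal_like_geneset <-
      sort(c(sample(tx$id[bound], lum_n),
             if (n - length(bound) >= 3)
               sample(setdiff(tx$id, tx$id[bound]), 3) else character(0)))
    list(layout = layout, transcripts = tx, islands = islands,
         expression = expr, genes = genes, truth = truth)
  })
}

# enhancer intervals in open space (no TSS within 3.5 kb), linked to
# bound/active genes with strength proportional to the gene's level
place_enhancers <- function(tx, genes, layout, p, n_enhancers = 12L) {
  if (nrow(tx) == 0L || !any(genes$bound)) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), target = character(),
                      strength = numeric()))
  }
  out <- list(); tries <- 0L
  while (length(out) < n_enhancers && tries < 2000L) {
    tries <- tries + 1L
    ch <- sample(layout$chrom_names, 1)
    pos <- round(stats::runif(1, 5000, layout$chrom_lengths[[ch]] - 5000))
    tss <- tx$tss[tx$chrom == ch]
    if (length(tss) && min(abs(tss - pos)) < 3500) next
    # keep planted enhancers in open intergenic chromatin, clear of the
    # broad gene-body-anchored marks
    on_ch <- tx$chrom == ch
    if (any(on_ch)) {
      lo <- pmin(tx$tss[on_ch], tx$tes[on_ch]) - 8000
      hi <- pmax(tx$tss[on_ch], tx$tes[on_ch]) + 8000
      if (any(pos >= lo & pos <= hi)) next
    }
    cand <- which(genes$bound & tx$chrom == ch)
    if (!length(cand)) cand <- which(genes$class == "active" &
                                       tx$chrom == ch)
    if (!length(cand)) next
    g <- cand[sample.int(length(cand), 1)]
    out[[length(out) + 1L]] <- data.frame(
      chrom = ch, start = pos - 500, end = pos + 500,
      target = tx$id[g],
      strength = 0.3 + 0.7 * genes$mbd3_level[g],
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  df[order(df$chrom, df$start), , drop = FALSE]
}

#' Simulate replicated two-color DamID promoter arrays
#'
#' Probes tile every promoter (TSS +/- tile flank) at the configured
#' spacing.  Per replicate chip, log2 channel intensities are
#' `baseline + noise` for the Dam-only (cy3) channel and
#' `baseline + gc_bias + effect * planted + noise` for the fusion (cy5)
#' channel, where the GC dye bias is a linear function of probe GC applied
#' to the cy5 channel only and the planted effect applies inside truth
#' enriched regions.
#'
#' @param annotation output of [make_genome_annotation()].
#' @param params [sim_params()].
#' @return probe data.frame with probe_id/chrom/start/end/gc, channel
#'   columns `log_cy3_<i>`/`log_cy5_<i>`, and a ground-truth `planted`
#'   flag.
#' @export
simulate_damid_arrays <- function(annotation, params = sim_params()) {
  p <- params
  tx <- annotation$transcripts
  with_stage_seed(p$seed, "damid", {
    probe_list <- lapply(seq_len(nrow(tx)), function(i) {
      lo <- max(0, tx$tss[i] - p$promoter_tile_flank)
      hi <- min(annotation$layout$chrom_lengths[[tx$chrom[i]]],
                tx$tss[i] + p$promoter_tile_flank) - p$probe_width
      # probes sit on a genome-wide lattice (as on a fixed array design),
      # so overlapping promoter tiles share probes instead of doubling
      # the local probe density
      s <- seq(ceiling(lo / p$probe_spacing) * p$probe_spacing, hi,
               by = p$probe_spacing)
      data.frame(chrom = tx$chrom[i], start = s, end = s + p$probe_width,
                 stringsAsFactors = FALSE)
    })
    probes <- unique(do.call(rbind, probe_list))
    probes <- probes[order(probes$chrom, probes$start), , drop = FALSE]
    n <- nrow(probes)
    probes$probe_id <- sprintf("probe_%05d", seq_len(n))
    # GC: centered at 0.5, independent of planting so the dye-bias
    # correction and the planted effect are identifiable separately
    gc <- 0.5 + 0.10 * stats::rnorm(n)
    probes$gc <- pmin(0.85, pmax(0.15, gc))
    probes$planted <- overlap_any(probes,
                                  annotation$truth$enriched_regions)
    baseline <- stats::rnorm(n, 10, 1)
    bias <- p$gc_bias_amplitude * (probes$gc - mean(probes$gc))
    for (i in seq_len(p$replicate_count)) {
      probes[[paste0("log_cy3_", i)]] <-
        baseline + stats::rnorm(n, 0, p$noise_sd)
      probes[[paste0("log_cy5_", i)]] <-
        baseline + bias + p$enrichment_effect * probes$planted +
        stats::rnorm(n, 0, p$noise_sd)
    }
    probes[, c("probe_id", "chrom", "start", "end", "gc", "planted",
               grep("^log_", names(probes), value = TRUE))]
  })
}

# draw fragment intervals of length `ext` centered at the given midpoints
frags_at <- function(chrom, mids, ext) {
  data.frame(chrom = chrom, start = round(mids - ext / 2),
             end = round(mids - ext / 2) + ext, stringsAsFactors = FALSE)
}

#' Simulate extended-fragment ChIP coverage tracks
#'
#' Produces coverage tracks for the factor (mbd3), four histone marks and
#' an input control.  The factor's promoter component is bimodal with
#' modes 1.5 kb either side of the TSS (hence a dip at the TSS), plus a
#' 5'->3' decaying gene-body component, a TES component and an enhancer
#' component co-planted with H3K27ac at the truth enhancers.
#'
#' @param annotation output of [make_genome_annotation()].
#' @param params [sim_params()].
#' @return named list of `coverage_track`s: mbd3, h3k4me3, h3k27ac,
#'   h3k27me3, h3k9me3, input.
#' @export
simulate_chip_tracks <- function(annotation, params = sim_params()) {
  p <- params
  tx <- annotation$transcripts
  genes <- annotation$genes
  layout <- annotation$layout
  enh <- annotation$truth$enhancer_links
  glen <- sum(layout$chrom_lengths)
  with_stage_seed(p$seed, "chip", {
    uniform_mids <- function(n) {
      ch <- sample(layout$chrom_names, n, replace = TRUE,
                   prob = layout$chrom_lengths)
      data.frame(chrom = ch,
                 mid = stats::runif(n, 200,
                                    layout$chrom_lengths[ch] - 200))
    }
    promoter_mids <- function(i, n, bimodal = TRUE, sd = 500) {
      if (bimodal) {
        # flanking modes 1.5 kb either side of the TSS plus a promoter-
        # core component, so the TSS dips without emptying its bin
        n_core <- round(0.3 * n)
        side <- sample(c(-1, 1), n - n_core, replace = TRUE)
        off <- c(side * 1500 + stats::rnorm(n - n_core, 0, sd),
                 stats::runif(n_core, -1000, 1000))
      } else {
        off <- stats::rnorm(n, 0, sd)
      }
      data.frame(chrom = tx$chrom[i], mid = tx$tss[i] + off)
    }
    mk_track <- function(mids) {
      f <- frags_at(mids$chrom, mids$mid, p$fragment_extension)
      f$start <- pmax(0, f$start)
      f$end <- pmin(layout$chrom_lengths[f$chrom], f$end)
      f <- f[f$end > f$start, , drop = FALSE]
      track_from_fragments(f, layout,
                           fragment_extension = p$fragment_extension)
    }
    mbd3 <- list(); k4 <- list(); k27ac <- list(); k27me <- list()
    k9 <- list()
    for (i in seq_len(nrow(tx))) {
      lv <- genes$mbd3_level[i]
      if (genes$class[i] == "active") {
        act <- stats::runif(1, 0.5, 1)
        k4[[length(k4) + 1L]] <-
          promoter_mids(i, round(450 * act), bimodal = FALSE, sd = 500)
        k27ac[[length(k27ac) + 1L]] <-
          promoter_mids(i, round(250 * act), bimodal = FALSE, sd = 600)
        if (lv > 0) {
          n_prom <- round(500 * lv)
          mbd3[[length(mbd3) + 1L]] <- promoter_mids(i, n_prom)
          # 5'->3' decaying gene-body component and a TES bump
          nb <- round(150 * lv)
          u <- stats::rbeta(nb, 1, 3)
          sgn_i <- sign(tx$tes[i] - tx$tss[i])
          blen <- abs(tx$tes[i] - tx$tss[i]) - 500
          mbd3[[length(mbd3) + 1L]] <- data.frame(
            chrom = tx$chrom[i],
            mid = tx$tss[i] + sgn_i * (500 + u * blen))
          mbd3[[length(mbd3) + 1L]] <- data.frame(
            chrom = tx$chrom[i],
            mid = tx$tes[i] + stats::rnorm(round(60 * lv), 0, 200))
        }
      } else if (genes$class[i] == "h3k27me3") {
        k27me[[length(k27me) + 1L]] <-
          promoter_mids(i, 350, bimodal = FALSE, sd = 1500)
        mbd3[[length(mbd3) + 1L]] <-
          promoter_mids(i, 60, bimodal = TRUE, sd = 700)
      } else if (genes$class[i] == "h3k9me3") {
        body_mid <- (tx$tss[i] + tx$tes[i]) / 2
        k9[[length(k9) + 1L]] <- data.frame(
          chrom = tx$chrom[i],
          mid = body_mid + stats::rnorm(350, 0, 2000))
      }
    }
    for (j in seq_len(nrow(enh))) {
      cen <- (enh$start[j] + enh$end[j]) / 2
      nfe <- round(300 * enh$strength[j])
      mbd3[[length(mbd3) + 1L]] <- data.frame(
        chrom = enh$chrom[j], mid = cen + stats::rnorm(nfe, 0, 250))
      k27ac[[length(k27ac) + 1L]] <- data.frame(
        chrom = enh$chrom[j],
        mid = cen + stats::rnorm(round(350 * enh$strength[j]), 0, 250))
    }
    assemble <- function(lst, bg_frac = 0.05) {
      sig <- do.call(rbind, lst)
      n_sig <- if (is.null(sig)) 0L else nrow(sig)
      bg <- uniform_mids(max(200L, round(bg_frac * n_sig)))
      mk_track(rbind(sig, bg))
    }
    list(mbd3 = assemble(mbd3), h3k4me3 = assemble(k4),
         h3k27ac = assemble(k27ac), h3k27me3 = assemble(k27me),
         h3k9me3 = assemble(k9), input = mk_track(uniform_mids(20000L)))
  })
}

#' Simulate CpG-island methylation fractions
#'
#' Fractions are drawn from a two-mode mixture (hypomethylated mode mean
#' < 0.1, hypermethylated mode mean > 0.9, plus a point mass at exactly
#' 0); islands at bound promoters use a strongly hypomethylated mixing
#' weight.  Read counts consistent with the fractions are attached so
#' the fraction formula can be exercised on counts.
#'
#' @param islands island data.frame (with a `gene` column).
#' @param params [sim_params()].
#' @param bound logical per island; default: island's gene is in the
#'   truth bound set (requires `attr(islands, "bound_genes")` or an
#'   explicit vector).
#' @return `islands` with meth_reads/total_reads/fraction columns.
#' @export
simulate_methylation <- function(islands, params = sim_params(),
                                 bound = NULL) {
  p <- params
  if (is.null(bound)) bound <- rep(FALSE, nrow(islands))
  stopifnot(length(bound) == nrow(islands))
  with_stage_seed(p$seed, "methylation", {
    n <- nrow(islands)
    w_low <- ifelse(bound, 0.90, p$meth_mix_weight)
    in_low <- stats::runif(n) < w_low
    # a slice of the hypomethylated mode is exactly 0 (fully unmethylated)
    zero <- in_low & stats::runif(n) < 0.09
    low <- in_low & !zero
    high <- !in_low
    frac <- numeric(n)
    b_lo <- 1.5 * (1 - p$meth_low_mean) / p$meth_low_mean
    frac[low] <- stats::rbeta(sum(low), 1.5, b_lo)
    b_hi <- 1.5 * p$meth_high_mean / (1 - p$meth_high_mean)
    frac[high] <- stats::rbeta(sum(high), b_hi, 1.5)
    total <- 20L + stats::rpois(n, 60)
    meth <- round(frac * total)
    islands$meth_reads <- meth
    islands$total_reads <- total
    islands$fraction <- meth / total
    islands
  })
}

#' Simulate PET pairs from enhancer-TSS links plus decoys
#'
#' Every link yields at least one pair with end 1 near the target TSS and
#' end 2 at the enhancer; decoy pairs with neither end within the TSS
#' anchor windows are added at `pet_decoy_rate` per link pair.
#'
#' @param annotation output of [make_genome_annotation()].
#' @param params [sim_params()].
#' @return PET data.frame (chrom1/start1/end1/chrom2/start2/end2,
#'   from_link flag).
#' @export
simulate_pets <- function(annotation, params = sim_params()) {
  p <- params
  tx <- annotation$transcripts
  links <- annotation$truth$enhancer_links
  layout <- annotation$layout
  with_stage_seed(p$seed, "pets", {
    rows <- list()
    for (j in seq_len(nrow(links))) {
      g <- match(links$target[j], tx$id)
      npair <- 2L + stats::rpois(1, 2)
      for (k in seq_len(npair)) {
        c1 <- tx$tss[g] +
          sample(c(-1, 1), 1) * (800 + stats::runif(1, 0, 700))
        c2 <- (links$start[j] + links$end[j]) / 2 + stats::rnorm(1, 0, 150)
        rows[[length(rows) + 1L]] <- data.frame(
          chrom1 = tx$chrom[g], start1 = round(c1 - 200),
          end1 = round(c1 + 200),
          chrom2 = links$chrom[j], start2 = round(c2 - 200),
          end2 = round(c2 + 200), from_link = TRUE,
          stringsAsFactors = FALSE)
      }
    }
    n_link <- length(rows)
    n_decoy <- round(p$pet_decoy_rate * n_link)
    made <- 0L; tries <- 0L
    while (made < n_decoy && tries < 5000L) {
      tries <- tries + 1L
      ch <- sample(layout$chrom_names, 2, replace = TRUE)
      pos <- stats::runif(2, 1000, layout$chrom_lengths[ch] - 1000)
      ok <- vapply(1:2, function(m) {
        tss <- tx$tss[tx$chrom == ch[m]]
        !length(tss) || min(abs(tss - pos[m])) > 3300
      }, logical(1))
      if (!all(ok)) next
      made <- made + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        chrom1 = ch[1], start1 = round(pos[1] - 200),
        end1 = round(pos[1] + 200),
        chrom2 = ch[2], start2 = round(pos[2] - 200),
        end2 = round(pos[2] + 200), from_link = FALSE,
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    if (is.null(out))
      out <- data.frame(chrom1 = character(), start1 = numeric(),
                        end1 = numeric(), chrom2 = character(),
                        start2 = numeric(), end2 = numeric(),
                        from_link = logical(), stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  })
}

#' Simulate paired-end MNase fragments
#'
#' Fragment lengths follow N(147, 15) truncated to `[100, 200]`.
#' Midpoints are drawn per promoter from a mixture of a uniform
#' background and phased nucleosome positions flanking an NDR at the TSS
#' (downstream +1 at +120, upstream -1 at -180, then one per
#' `phasing_period`).  With `depleted = TRUE`, the -1/+2/+3/+4
#' nucleosomes of the highest-occupancy quarter of promoters (by planted
#' factor level) are down-weighted by `ndr_depth_factor`.
#'
#' @param annotation output of [make_genome_annotation()].
#' @param params [sim_params()].
#' @param depleted simulate the factor-depleted condition.
#' @return fragment data.frame (chrom/start/end).
#' @export
simulate_mnase <- function(annotation, params = sim_params(),
                           depleted = FALSE) {
  p <- params
  tx <- annotation$transcripts
  genes <- annotation$genes
  layout <- annotation$layout
  stage <- if (depleted) "mnase_depleted" else "mnase_control"
  top_q <- genes$mbd3_level >=
    stats::quantile(genes$mbd3_level, 0.75, type = 7)
  with_stage_seed(p$seed, stage, {
    span <- p$phasing_period * (seq_len(25L) - 1L)
    off_down <- 120 + span            # +1, +2, ...
    off_up <- -180 - span             # -1, -2, ...
    offsets <- c(off_up, off_down)
    labels <- c(paste0("-", seq_len(25L)), paste0("+", seq_len(25L)))
    decay <- exp(-abs(offsets) / 4000)
    rows <- list()
    for (i in seq_len(nrow(tx))) {
      w <- decay
      if (depleted && top_q[i]) {
        hit <- labels %in% c("-1", "+2", "+3", "+4")
        w[hit] <- w[hit] * p$ndr_depth_factor
      }
      n <- p$mnase_frags_per_tx
      n_bg <- round(0.25 * n)
      n_ph <- round(p$phasing_amplitude * (n - n_bg))
      n_un <- n - n_bg - n_ph
      sgn <- if (tx$strand[i] == "-") -1 else 1
      mids_bg <- tx$tss[i] + stats::runif(n_bg, -6000, 6000)
      mids_un <- tx$tss[i] + stats::runif(n_un, -6000, 6000)
      pick <- sample.int(length(offsets), n_ph, replace = TRUE, prob = w)
      mids_ph <- tx$tss[i] + sgn * (offsets[pick] +
                                      stats::rnorm(n_ph, 0, 30))
      mids <- c(mids_bg, mids_un, mids_ph)
      len <- round(pmin(200, pmax(100, stats::rnorm(length(mids),
                                                    147, 15))))
      start <- round(mids) - floor(len / 2)
      rows[[i]] <- data.frame(chrom = tx$chrom[i], start = start,
                              end = start + len, stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    out <- out[out$start >= 0 &
                 out$end <= layout$chrom_lengths[out$chrom], ,
               drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Simulate promoter sequences matched to promoter classes
#'
#' Active (CpG-island) genes receive CpG-rich GC-rich sequence; a third of
#' the remaining genes receive intermediate sequence; the rest receive
#' CpG-depleted sequence.  Window length follows the classifier default
#' (1001 bp).
#'
#' @param annotation output of [make_genome_annotation()].
#' @param params [sim_params()].
#' @param window sequence length (default 1001).
#' @return named character vector of sequences (names = transcript ids).
#' @export
simulate_promoter_sequences <- function(annotation,
                                        params = sim_params(),
                                        window = 1001L) {
  p <- params
  tx <- annotation$transcripts
  genes <- annotation$genes
  with_stage_seed(p$seed, "promoter_seq", {
    n <- nrow(tx)
    kind <- ifelse(genes$class == "active", "hcp",
                   ifelse(stats::runif(n) < 1 / 3, "icp", "lcp"))
    seqs <- vapply(kind, function(k) {
      if (k == "hcp") {
        # heavy CG dinucleotide content, GC ~ 0.65
        tokens <- sample(c("CG", "G", "C", "A", "T"), window,
                         replace = TRUE,
                         prob = c(0.22, 0.20, 0.20, 0.19, 0.19))
      } else if (k == "icp") {
        tokens <- sample(c("CG", "G", "C", "A", "T"), window,
                         replace = TRUE,
                         prob = c(0.05, 0.22, 0.22, 0.255, 0.255))
      } else {
        tokens <- sample(c("G", "C", "A", "T"), window, replace = TRUE,
                         prob = c(0.19, 0.19, 0.31, 0.31))
        # break almost every CpG to emulate CpG depletion
        s <- paste(tokens, collapse = "")
        s <- gsub("CG", "CA", s, fixed = TRUE)
        return(substr(s, 1, window))
      }
      substr(paste(tokens, collapse = ""), 1, window)
    }, character(1))
    stats::setNames(seqs, tx$id)
  })
}
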