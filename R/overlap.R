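# Chromosome-bound circular permutation test for interval-set overlap, and
# Fisher/BH gene-set enrichment.
#
# The permutation test works on "disjoined units" (e.g. disjoined array
# probes): each unit carries a membership flag for set A and for set B.
# One set's membership vector is rotated within each chromosome by an
# independent uniform offset, wrapping around at the chromosome end, so
# per-chromosome marked-unit counts are conserved by construction.  The
# overlap statistic is the number of units marked in both sets.

#' Permutation-test parameters
#'
#' @param n_perm number of permutations (default 20000).
#' @param seed RNG seed for the permutation stream.
#' @param ci_level confidence level for the ratio percentile interval
#'   (default 0.95).
#' @return parameter list.
#' @export
overlap_test_params <- function(n_perm = 20000L, seed = 1L,
                                ci_level = 0.95) {
  stopifnot(n_perm >= 1L, ci_level > 0, ci_level < 1)
  list(n_perm = as.integer(n_perm), seed = as.integer(seed),
       ci_level = ci_level)
}

#' Rotate a membership vector with wrap-around
#'
#' Element i of the result is element `i - offset` (mod n) of the input:
#' the membership status of every unit is shifted forward by `offset`,
#' resuming at the beginning when the shift passes the last unit.  The
#' marked-unit count is conserved.
#'
#' @param membership logical (or 0/1) vector, units ordered by position.
#' @param offset integer shift.
#' @return rotated vector.
#' @export
circular_shift <- function(membership, offset) {
  n <- length(membership)
  if (n == 0L) return(membership)
  k <- ((offset %% n) + n) %% n
  if (k == 0L) return(membership)
  c(membership[(n - k + 1L):n], membership[seq_len(n - k)])
}

# Overlap counts of a with b rotated by every offset 0..n-1 on one
# chromosome: cross-correlation by direct loop (n is at most a few
# thousand units per chromosome).
rotation_overlap_curve <- function(a, b) {
  n <- length(a)
  vapply(0:(n - 1L), function(d) sum(a & circular_shift(b, d)), numeric(1))
}

#' Chromosome-bound circular permutation overlap test
#'
#' @param a,b logical membership vectors over the same disjoined units.
#' @param chrom chromosome of each unit (units ordered by position within
#'   chromosome).
#' @param params [overlap_test_params()].
#' @return list of class `overlap_test` with observed, expected (the
#'   permutation mean), odds_ratio = observed/expected, two-sided empirical
#'   pval, ci (percentile interval on the ratio), and the permutation
#'   overlap vector.
#' @export
permutation_overlap_test <- function(a, b, chrom,
                                     params = overlap_test_params()) {
  stopifnot(length(a) == length(b), length(chrom) == length(a))
  if (!any(a) || !any(b)) stop("all-zero membership in one set")
  chroms <- unique(chrom)
  observed <- sum(a & b)
  # precompute, per chromosome, overlap as a function of rotation offset;
  # each permutation then just indexes these curves at a random offset
  curves <- lapply(chroms, function(ch) {
    idx <- chrom == ch
    if (!sum(idx)) return(NULL)
    rotation_overlap_curve(a[idx], b[idx])
  })
  sizes <- vapply(curves, length, integer(1))
  keep <- sizes > 0L
  curves <- curves[keep]; sizes <- sizes[keep]
  perm <- withr::with_seed(params$seed, {
    draws <- vapply(seq_along(curves), function(i)
      curves[[i]][sample.int(sizes[i], params$n_perm, replace = TRUE)],
      numeric(params$n_perm))
    if (is.null(dim(draws))) sum(draws) else rowSums(draws)
  })
  expected <- mean(perm)
  n_perm <- params$n_perm
  p_enrich <- (1 + sum(perm >= observed)) / (1 + n_perm)
  p_deplete <- (1 + sum(perm <= observed)) / (1 + n_perm)
  pval <- min(1, 2 * min(p_enrich, p_deplete))
  alpha <- 1 - params$ci_level
  qs <- stats::quantile(perm, c(1 - alpha / 2, alpha / 2), names = FALSE)
  ci <- c(low = if (qs[1] > 0) observed / qs[1] else Inf,
          high = if (qs[2] > 0) observed / qs[2] else Inf)
  structure(list(observed = observed, expected = expected,
                 odds_ratio = if (expected > 0) observed / expected else NA,
                 pval = pval, ci = ci, perm = perm,
                 n_perm = n_perm),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf(
    "<overlap_test> observed %d, expected %.2f, odds ratio %.3f, p = %.4g\n",
    x$observed, x$expected, x$odds_ratio, x$pval))
  cat(sprintf("  %s CI on ratio: [%.3f, %.3f] (%d permutations)\n",
              "95%", x$ci[1], x$ci[2], x$n_perm))
  invisible(x)
}

#' Map intervals onto disjoined units as membership flags
#'
#' A unit is "in" an interval set iff it overlaps it by at least 1 bp.
#'
#' @param units disjoined unit data.frame (chrom/start/end, ordered).
#' @param intervals interval data.frame.
#' @return logical membership per unit.
#' @export
unit_membership <- function(units, intervals) {
  overlap_any(units, intervals)
}

#' Gene-set enrichment by Fisher's exact test with BH correction
#'
#' For every gene set a 2x2 table (target in set / target not in set /
#' non-target in set / non-target not in set) is tested two-sided; BH
#' adjustment is applied across all sets tested.
#'
#' @param target_genes character vector of target gene ids.
#' @param universe character vector of all gene ids considered.
#' @param gene_sets named list of character vectors (subsets of the
#'   universe).
#' @return data.frame with set, n_set, n_overlap, odds_ratio, pval, qval.
#' @export
gene_set_enrichment <- function(target_genes, universe, gene_sets) {
  if (length(universe) == 0L) stop("empty universe")
  universe <- unique(universe)
  targets <- intersect(unique(target_genes), universe)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(gene_sets[[nm]], universe)
    a <- length(intersect(targets, set))
    b <- length(targets) - a
    c_ <- length(set) - a
    d <- length(universe) - a - b - c_
    ft <- stats::fisher.test(matrix(c(a, b, c_, d), nrow = 2))
    data.frame(set = nm, n_set = length(set), n_overlap = a,
               odds_ratio = unname(ft$estimate), pval = ft$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$qval <- stats::p.adjust(out$pval, method = "BH")
  out
}
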