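# Two-step DamID array normalization.
#
# Step one (within chip): probes are binned by GC content with bin widths
# from the normal-scale zero-stage rule, bins merged until each holds at
# least `min_bin_probes` probes; within each bin a robust lowess of
# log(cy5) on log(cy3) is fit and the residuals, scaled by the bin's median
# absolute residual, become the normalized signal.  This removes dye bias
# and GC-dependent structure without touching genuine local enrichment
# (which survives as residual outliers).
#
# Step two (between chips): quantile normalization across chips so every
# chip shares the same value distribution.

#' Normalization parameters
#'
#' @param min_bin_probes minimum probes per GC bin (default 500).
#' @param lowess_span lowess smoother span as a fraction of points
#'   (default 2/3).
#' @param lowess_iterations robustifying iterations (default 3).
#' @return a list of parameters.
#' @export
normalization_params <- function(min_bin_probes = 500L, lowess_span = 2/3,
                                 lowess_iterations = 3L) {
  stopifnot(min_bin_probes >= 2L, lowess_span > 0, lowess_span <= 1)
  list(min_bin_probes = min_bin_probes, lowess_span = lowess_span,
       lowess_iterations = lowess_iterations)
}

#' Assign probes to GC bins by the zero-stage rule
#'
#' Initial bin width h = 3.49 * sigma * n^(-1/3) with
#' sigma = min(sd, IQR/1.349) (the robust normal-scale estimate); bins are
#' contiguous in GC after sorting and adjacent bins with fewer than
#' `min_bin_probes` probes are merged left-to-right (smallest GC first)
#' until every bin reaches the minimum.  Identical GC values always share a
#' bin.
#'
#' @param gc numeric GC fractions in `[0, 1]`.
#' @param min_bin_probes minimum probes per bin.
#' @return integer bin label per probe (1-based, increasing with GC).
#' @export
gc_bin_assign <- function(gc, min_bin_probes = 500L) {
  n <- length(gc)
  if (n == 0L) stop("no probes")
  if (n < min_bin_probes) {
    warning("fewer than min_bin_probes probes in total; using a single bin")
    return(rep(1L, n))
  }
  sigma <- min(stats::sd(gc), stats::IQR(gc) / 1.349)
  if (!is.finite(sigma) || sigma == 0) return(rep(1L, n))
  h <- 3.49 * sigma * n^(-1/3)
  raw <- pmin(floor((gc - min(gc)) / h), ceiling(diff(range(gc)) / h) - 1)
  # merge left-to-right on occupied raw bins until all bins hold enough
  counts <- table(factor(raw, levels = sort(unique(raw))))
  labels <- integer(length(counts))
  lab <- 1L; acc <- 0L
  for (i in seq_along(counts)) {
    labels[i] <- lab
    acc <- acc + counts[[i]]
    if (acc >= min_bin_probes) { lab <- lab + 1L; acc <- 0L }
  }
  if (acc > 0L && lab > 1L)  # trailing underfull bin joins its left neighbor
    labels[labels == lab] <- lab - 1L
  bin <- labels[match(raw, sort(unique(raw)))]
  as.integer(factor(bin))
}

# Scale residuals by the median absolute residual (a robust spread unit);
# a zero median leaves residuals unscaled with a warning.
scale_by_median_abs <- function(res) {
  m <- stats::median(abs(res))
  # a numerically zero spread (e.g. an exact fit) cannot serve as a
  # scale unit; 1e-10 log2 units is far below any real dye variation
  if (m < 1e-10) {
    warning("median absolute residual is zero; residuals left unscaled")
    return(res)
  }
  res / m
}

#' Within-chip lowess residual normalization
#'
#' Within each GC bin, a robust lowess predicts log(cy5) as a smooth
#' function of log(cy3); the normalized signal is the residual divided by
#' the bin's median absolute residual.
#'
#' @param log_cy3,log_cy5 log-transformed channel intensities (log2;
#'   cy3 carries the Dam-only control, cy5 the fusion sample).
#' @param bins integer bin labels from [gc_bin_assign()].
#' @param params [normalization_params()].
#' @return numeric normalized signal per probe.
#' @export
lowess_residual_normalize <- function(log_cy3, log_cy5, bins,
                                      params = normalization_params()) {
  stopifnot(length(log_cy3) == length(log_cy5),
            length(bins) == length(log_cy3))
  out <- numeric(length(log_cy3))
  for (b in unique(bins)) {
    idx <- which(bins == b)
    x <- log_cy3[idx]; y <- log_cy5[idx]
    if (length(idx) < 4L || stats::sd(x) == 0) {
      fit_at <- rep(stats::median(y), length(idx))
    } else {
      fit <- stats::lowess(x, y, f = params$lowess_span,
                           iter = params$lowess_iterations)
      fit_at <- stats::approx(fit$x, fit$y, xout = x, rule = 2,
                              ties = mean)$y
    }
    out[idx] <- scale_by_median_abs(y - fit_at)
  }
  out
}

#' Quantile normalization across chips
#'
#' After transformation every chip's sorted value vector equals the
#' rank-wise mean of the sorted input chips; within-chip ranks are
#' preserved and ties receive the mean of their tied rank values.
#'
#' @param mat numeric matrix, probes x chips, no missing values.
#' @return matrix of the same shape.
#' @export
quantile_normalize <- function(mat) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("missing values are not supported")
  n <- nrow(mat)
  sorted_means <- rowMeans(apply(mat, 2, sort))
  out <- vapply(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    vals <- numeric(n)
    vals[order(col)] <- sorted_means
    # tied entries share the mean of the values their ranks map to
    stats::ave(vals, match(col, col), FUN = mean)
  }, numeric(n))
  dimnames(out) <- dimnames(mat)
  out
}

#' Full two-step DamID normalization of a replicated chip set
#'
#' Applies within-chip GC-binned lowess residual normalization to every
#' chip, then quantile normalization across the chip set.
#'
#' @param probes probe data.frame with `gc` plus paired channel columns
#'   `log_cy3_<i>`/`log_cy5_<i>` for replicates i = 1..r.
#' @param params [normalization_params()].
#' @return `probes` with appended `normalized_<i>` columns.
#' @export
damid_normalize <- function(probes, params = normalization_params()) {
  reps <- grep("^log_cy5_", names(probes), value = TRUE)
  if (length(reps) == 0L) stop("no log_cy5_<i> channel columns found")
  bins <- gc_bin_assign(probes$gc, params$min_bin_probes)
  mat <- sapply(reps, function(cy5col) {
    i <- sub("^log_cy5_", "", cy5col)
    cy3col <- paste0("log_cy3_", i)
    if (!cy3col %in% names(probes)) stop("missing channel column ", cy3col)
    lowess_residual_normalize(probes[[cy3col]], probes[[cy5col]], bins,
                              params)
  })
  mat <- quantile_normalize(mat)
  for (j in seq_along(reps)) {
    i <- sub("^log_cy5_", "", reps[j])
    probes[[paste0("normalized_", i)]] <- mat[, j]
  }
  probes
}
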