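# HCP/ICP/LCP promoter classification from sequence around the TSS.
#
# A 1001 bp window centered on the TSS is scanned with 500 bp subwindows.
# A promoter is HCP if any subwindow has CpG observed/expected ratio above
# 0.75 and GC content above 0.55; LCP if no subwindow has ratio above
# 0.48; ICP otherwise.  Subwindow starts are placed symmetrically around
# the sequence midpoint (the forward grid plus its mirror image), so the
# classification is exactly invariant under reverse complement at any step
# size; at step 1 this is simply every start position.

#' Promoter classification parameters
#'
#' @param window full window length centered on the TSS (default 1001 bp).
#' @param subwindow scanned area length (default 500 bp).
#' @param step subwindow step in bases (default 5).
#' @param hcp_ratio,hcp_gc,lcp_ratio class thresholds (strict
#'   inequalities, defaults 0.75 / 0.55 / 0.48).
#' @return parameter list.
#' @export
promoter_class_params <- function(window = 1001L, subwindow = 500L,
                                  step = 5L, hcp_ratio = 0.75,
                                  hcp_gc = 0.55, lcp_ratio = 0.48) {
  stopifnot(subwindow <= window, step >= 1L)
  list(window = window, subwindow = subwindow, step = step,
       hcp_ratio = hcp_ratio, hcp_gc = hcp_gc, lcp_ratio = lcp_ratio)
}

#' CpG statistics of a sequence
#'
#' GC content and CpG observed/expected ratio.  N bases are excluded from
#' both numerator and denominator counts; `expected = (#C * #G) / L` with L
#' the number of called bases; `ratio = observed / expected`, defined 0
#' when the expectation is 0.
#'
#' @param sequence character string over A/C/G/T/N, case-insensitive.
#' @return list with gc_content, cpg_observed, cpg_expected, ratio.
#' @export
cpg_stats <- function(sequence) {
  if (!nzchar(sequence)) stop("empty sequence")
  s <- toupper(sequence)
  counts <- cpg_window_counts(s, 1L, nchar(s))
  L <- counts$called
  if (L == 0) stop("sequence contains no called bases")
  expected <- counts$c * counts$g / L
  list(gc_content = (counts$c + counts$g) / L,
       cpg_observed = counts$cg,
       cpg_expected = expected,
       ratio = if (expected > 0) counts$cg / expected else 0)
}

# counts of C, G, CG dinucleotides and called bases in s[from..to]
cpg_window_counts <- function(s, from, to) {
  sub <- substr(s, from, to)
  chars <- strsplit(sub, "", fixed = TRUE)[[1]]
  nc <- sum(chars == "C"); ng <- sum(chars == "G")
  called <- sum(chars %in% c("A", "C", "G", "T"))
  cg <- sum(chars[-length(chars)] == "C" & chars[-1] == "G")
  list(c = nc, g = ng, cg = cg, called = called)
}

# symmetric subwindow start grid (1-based) for a sequence of length L
subwindow_starts <- function(L, subwindow, step) {
  last <- L - subwindow + 1L
  if (last < 1L) stop("sequence shorter than subwindow")
  fwd <- seq(1L, last, by = step)
  sort(unique(c(fwd, (last + 1L) - fwd)))
}

#' Classify a promoter sequence as HCP, ICP or LCP
#'
#' @param sequence the promoter sequence (window length centered on the
#'   TSS; shorter sequences at chromosome edges should be padded with N,
#'   which is excluded from all counts).
#' @param params [promoter_class_params()].
#' @return a list with `class` ("HCP"/"ICP"/"LCP"), `max_ratio` and
#'   `max_gc` over subwindows.
#' @export
classify_promoter <- function(sequence, params = promoter_class_params()) {
  s <- toupper(sequence)
  L <- nchar(s)
  if (L < params$subwindow) stop("sequence shorter than subwindow")
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  isC <- chars == "C"; isG <- chars == "G"
  called <- chars %in% c("A", "C", "G", "T")
  if (!any(called)) stop("classification undefined for an all-N sequence")
  isCG <- c(isC[-L] & isG[-1], FALSE)
  cumC <- c(0, cumsum(isC)); cumG <- c(0, cumsum(isG))
  cumN <- c(0, cumsum(called)); cumCG <- c(0, cumsum(isCG))
  w <- params$subwindow
  starts <- subwindow_starts(L, w, params$step)
  hcp <- FALSE; any_mid <- FALSE
  max_ratio <- 0; max_gc <- 0
  for (st in starts) {
    en <- st + w - 1L
    ncall <- cumN[en + 1L] - cumN[st]
    if (ncall < w / 2) next  # subwindow mostly N: skipped
    nc <- cumC[en + 1L] - cumC[st]
    ng <- cumG[en + 1L] - cumG[st]
    # CG dinucleotides fully inside the subwindow (start in [st, en-1])
    ncg <- cumCG[en] - cumCG[st]
    gc <- (nc + ng) / ncall
    expected <- nc * ng / ncall
    ratio <- if (expected > 0) ncg / expected else 0
    max_ratio <- max(max_ratio, ratio)
    max_gc <- max(max_gc, gc)
    if (ratio > params$hcp_ratio && gc > params$hcp_gc) hcp <- TRUE
    if (ratio > params$lcp_ratio) any_mid <- TRUE
  }
  cls <- if (hcp) "HCP" else if (!any_mid) "LCP" else "ICP"
  list(class = cls, max_ratio = max_ratio, max_gc = max_gc)
}

#' Classify many promoter sequences
#'
#' @param sequences named character vector (names = transcript ids).
#' @param params [promoter_class_params()].
#' @return data.frame with id, class, max_ratio, max_gc.
#' @export
classify_promoters <- function(sequences,
                               params = promoter_class_params()) {
  res <- lapply(sequences, classify_promoter, params = params)
  data.frame(id = names(sequences) %||% as.character(seq_along(sequences)),
             class = vapply(res, `[[`, "", "class"),
             max_ratio = vapply(res, `[[`, 0, "max_ratio"),
             max_gc = vapply(res, `[[`, 0, "max_gc"),
             row.names = NULL, stringsAsFactors = FALSE)
}
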