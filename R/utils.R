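# internal helpers shared across modules

#' Derive a reproducible per-stage seed from a root seed
#'
#' Each stochastic stage draws from an independent stream keyed by
#' (seed, stage name), so adding or reordering stages never perturbs the
#' draws of another stage.  The result is always a valid 32-bit seed.
#'
#' @param seed integer root seed.
#' @param stage character stage name.
#' @return an integer seed.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  # polynomial rolling hash of the stage name, folded with the root seed;
  # doubles hold every intermediate exactly below 2^53
  h <- 0
  for (c in utf8ToInt(stage)) h <- (h * 131 + c) %% 2147483629
  as.integer((h + abs(seed) * 7919) %% 2147483629)
}

with_stage_seed <- function(seed, stage, code) {
  withr::with_seed(stage_seed(seed, stage), code)
}

#' Centered moving average with symmetric edge truncation
#'
#' @param x numeric vector.
#' @param period window width in positions; at the edges the window is
#'   truncated symmetrically so the average always uses the positions that
#'   exist.
#' @return smoothed numeric vector of the same length.
#' @export
moving_average <- function(x, period = 50L) {
  stopifnot(period >= 1L)
  n <- length(x)
  half_lo <- (period - 1L) %/% 2L
  half_hi <- period - 1L - half_lo
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(1L, i - half_lo)
  hi <- pmin(n, i + half_hi)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
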