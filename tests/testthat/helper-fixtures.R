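# Shared fixtures, memoised per test session (the generators are seeded,
# so every test sees identical objects).

.fx <- new.env(parent = emptyenv())

fx_params <- function() sim_params(seed = 42L)

fx_annotation <- function() {
  if (is.null(.fx$ann)) .fx$ann <- make_genome_annotation(fx_params())
  .fx$ann
}

fx_probes <- function() {
  if (is.null(.fx$probes))
    .fx$probes <- simulate_damid_arrays(fx_annotation(), fx_params())
  .fx$probes
}

fx_norm <- function() {
  if (is.null(.fx$norm)) {
    pr <- fx_probes()
    .fx$norm <- damid_normalize(
      pr, normalization_params(min_bin_probes =
                                 min(500L, nrow(pr) %/% 5L)))
  }
  .fx$norm
}

fx_peaks <- function() {
  if (is.null(.fx$peaks)) {
    norm <- fx_norm()
    sig <- as.matrix(norm[, grep("^normalized_", names(norm))])
    ws <- probe_enrichment_pvalues(norm, sig)
    .fx$wstats <- ws
    .fx$peaks <- call_peaks(norm, ws)
  }
  .fx$peaks
}

fx_tracks <- function() {
  if (is.null(.fx$tracks))
    .fx$tracks <- simulate_chip_tracks(fx_annotation(), fx_params())
  .fx$tracks
}

# small uniform-depth track on a toy genome
toy_track <- function(depth = 2, len = 20000, total = 1000,
                      chroms = "chrT") {
  coverage_track(stats::setNames(lapply(chroms, function(.)
    rep(depth, len)), chroms), total_mapped = total)
}

toy_layout <- function(len = 20000, chroms = "chrT")
  genome_layout(chroms, rep(len, length(chroms)))

rand_intervals <- function(n, len = 1000, chroms = c("c1", "c2")) {
  s <- sample.int(len - 50, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = s, end = s + sample.int(40, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# exact hypergeometric upper tail by summing choose() products
hyper_tail_oracle <- function(x, draws, successes, population) {
  if (x <= 0) return(1)
  hi <- min(draws, successes)
  if (x > hi) return(0)
  j <- x:hi
  sum(choose(successes, j) * choose(population - successes, draws - j)) /
    choose(population, draws)
}
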