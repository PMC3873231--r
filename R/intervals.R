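# Interval arithmetic and the annotation model.  All coordinates are
# 0-based, half-open [start, end), i.e. BED-native; any 1-based display is
# labeled as such.  Intervals live in plain data.frames with columns
# chrom/start/end (+ optional name/score/strand); transcripts additionally
# carry id/strand/tss/tes and refFlat-like exon lists.

#' Describe a genome as an ordered set of chromosomes
#'
#' @param chrom_names character vector of unique chromosome names.
#' @param chrom_lengths integer vector of lengths (> 0), parallel to
#'   `chrom_names`.
#' @return a `genome_layout` object (list with `chrom_names`,
#'   `chrom_lengths` named by chromosome).
#' @export
genome_layout <- function(chrom_names, chrom_lengths) {
  if (anyDuplicated(chrom_names)) stop("chromosome names must be unique")
  if (length(chrom_names) != length(chrom_lengths))
    stop("names and lengths differ in length")
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be > 0")
  structure(
    list(chrom_names = as.character(chrom_names),
         chrom_lengths = stats::setNames(as.numeric(chrom_lengths),
                                         chrom_names)),
    class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("<genome_layout> ", length(x$chrom_names), " chromosome(s), ",
      format(sum(x$chrom_lengths), big.mark = ","), " bp total\n", sep = "")
  invisible(x)
}

#' Construct/validate a set of genomic intervals
#'
#' @param chrom,start,end,strand,name,score parallel vectors; `start`/`end`
#'   are 0-based half-open.  `strand` in `+`, `-`, `.`.
#' @param layout optional [genome_layout()]; when given, intervals must lie
#'   within chromosome bounds.
#' @return a data.frame of intervals.
#' @export
genomic_intervals <- function(chrom, start, end, strand = NULL, name = NULL,
                              score = NULL, layout = NULL) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), stringsAsFactors = FALSE)
  if (!is.null(name)) df$name <- as.character(name)
  if (!is.null(score)) df$score <- as.numeric(score)
  if (!is.null(strand)) {
    if (!all(strand %in% c("+", "-", "."))) stop("strand must be +, - or .")
    df$strand <- as.character(strand)
  }
  validate_intervals(df, layout)
  df
}

validate_intervals <- function(df, layout = NULL) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  bad <- which(!(df$start >= 0 & df$start < df$end))
  if (length(bad))
    stop("invalid interval(s) at row(s) ", paste(utils::head(bad, 5), collapse = ", "),
         ": need 0 <= start < end")
  if (!is.null(layout)) {
    if (!all(df$chrom %in% layout$chrom_names))
      stop("interval chromosome not in genome layout")
    if (any(df$end > layout$chrom_lengths[df$chrom]))
      stop("interval extends past chromosome end")
  }
  invisible(df)
}

# Convert half-open interval data.frame to GRanges (1-based closed) for
# IRanges machinery; inverse conversion keeps the package 0-based.
as_granges <- function(df) {
  strand <- if ("strand" %in% names(df)) {
    s <- df$strand; s[s == "."] <- "*"; s
  } else "*"
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$start + 1, df$end),
                         strand = strand)
}

from_granges <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Flag intervals in `a` overlapping any interval in `b`
#'
#' @param a,b interval data.frames.
#' @param min_bp minimum shared bases (default 1).
#' @return logical vector, one flag per row of `a`.
#' @export
overlap_any <- function(a, b, min_bp = 1L) {
  validate_intervals(a); validate_intervals(b)
  if (nrow(a) == 0L) return(logical(0))
  if (nrow(b) == 0L) return(rep(FALSE, nrow(a)))
  ga <- as_granges(a); gb <- as_granges(b)
  lv <- union(GenomeInfoDb::seqlevels(ga), GenomeInfoDb::seqlevels(gb))
  GenomeInfoDb::seqlevels(ga) <- lv
  GenomeInfoDb::seqlevels(gb) <- lv
  IRanges::overlapsAny(ga, gb, minoverlap = min_bp, ignore.strand = TRUE)
}

#' Disjoin intervals into non-overlapping atomic units
#'
#' The units are pairwise disjoint, their union equals the union of the
#' inputs, and every input interval is an exact union of units.
#'
#' @param df interval data.frame.
#' @return data.frame of disjoint units, sorted by chromosome and start.
#' @export
disjoin_intervals <- function(df) {
  validate_intervals(df)
  if (nrow(df) == 0L) return(df[, c("chrom", "start", "end")])
  gr <- GenomicRanges::disjoin(as_granges(df), ignore.strand = TRUE)
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  from_granges(gr)
}

#' Remove transcripts duplicating an already-seen genomic locus
#'
#' Among transcripts sharing an identical (chrom, TSS, TES) triple exactly
#' one is retained: the first in `id` order.  Transcripts agreeing on the
#' TSS but not the TES (or vice versa) are all retained.
#'
#' @param transcripts transcript data.frame with columns `id`, `chrom`,
#'   `strand`, `tss`, `tes`.
#' @return the filtered transcript data.frame.
#' @export
dedup_transcripts <- function(transcripts) {
  if (nrow(transcripts) == 0L) return(transcripts)
  ord <- order(transcripts$id)
  tx <- transcripts[ord, , drop = FALSE]
  key <- paste(tx$chrom, tx$tss, tx$tes, sep = "\r")
  tx <- tx[!duplicated(key), , drop = FALSE]
  tx[order(match(tx$id, transcripts$id)), , drop = FALSE]
}

# Strand-aware promoter window [tss - up, tss + down) in genomic coords.
# On the minus strand "upstream" is to the right.
promoter_windows <- function(transcripts, up = 3000, down = 3000) {
  plus <- transcripts$strand != "-"
  start <- ifelse(plus, transcripts$tss - up, transcripts$tss - down)
  end <- ifelse(plus, transcripts$tss + down, transcripts$tss + up)
  data.frame(chrom = transcripts$chrom, start = start, end = end,
             name = transcripts$id, stringsAsFactors = FALSE)
}
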