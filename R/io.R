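# Readers/writers for the plain-text formats the pipeline touches: BED3/6,
# bedGraph, refFlat-like transcript tables, GMT gene sets, probe/PET/
# fragment TSVs, FASTA (via Biostrings).

#' Read a BED3/BED6 file
#'
#' @param path file path.
#' @return interval data.frame with chrom/start/end and, for BED6,
#'   name/score/strand.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
  if (length(lines) == 0L)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 3L & nf < 6L))
    stop("malformed BED line ", which(nf != 3L & nf < 6L)[1],
         ": expected 3 or >= 6 tab-separated fields")
  starts <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  ends <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (anyNA(starts) || anyNA(ends))
    stop("malformed BED line ", which(is.na(starts) | is.na(ends))[1],
         ": non-numeric coordinates")
  bad <- which(starts >= ends)
  if (length(bad))
    stop("invalid BED line ", bad[1], ": start >= end")
  df <- data.frame(chrom = vapply(fields, `[[`, "", 1L),
                   start = starts, end = ends, stringsAsFactors = FALSE)
  if (all(nf >= 6L)) {
    df$name <- vapply(fields, `[[`, "", 4L)
    df$score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
    df$strand <- vapply(fields, `[[`, "", 6L)
  }
  validate_intervals(df)
  df
}

#' Write intervals as BED3 or BED6
#'
#' BED6 is written when name/score/strand columns are present; round-trip
#' through [read_bed()] is lossless for chrom/start/end/name/score/strand.
#'
#' @param df interval data.frame.
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  validate_intervals(df)
  bed6 <- all(c("name", "score", "strand") %in% names(df))
  cols <- if (bed6) df[, c("chrom", "start", "end", "name", "score", "strand")]
          else df[, c("chrom", "start", "end")]
  utils::write.table(format(cols, scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a binned signal as bedGraph
#'
#' @param df data.frame with chrom/start/end/value.
#' @param path output path.
#' @param track_header write a "track type=bedGraph" header line.
#' @export
write_bedgraph <- function(df, path, track_header = FALSE) {
  con <- file(path, "w"); on.exit(close(con))
  if (track_header) writeLines("track type=bedGraph", con)
  utils::write.table(format(df[, c("chrom", "start", "end", "value")],
                            scientific = FALSE, trim = TRUE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a refFlat-like transcript table
#'
#' Tab-separated with header columns id, chrom, strand, txStart, txEnd,
#' exonStarts, exonEnds (comma-separated exon lists).  TSS/TES are derived
#' from the strand: on `-` the TSS is txEnd.
#'
#' @param path file path.
#' @return transcript data.frame with id/chrom/strand/tss/tes/
#'   exon_starts/exon_ends (comma strings).
#' @export
read_transcripts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "chrom", "strand", "txStart", "txEnd")
  if (!all(need %in% names(df)))
    stop("transcript table must have columns ", paste(need, collapse = ", "))
  transcripts_from_tx(df)
}

transcripts_from_tx <- function(df) {
  stopifnot(all(df$strand %in% c("+", "-")))
  minus <- df$strand == "-"
  data.frame(id = as.character(df$id), chrom = as.character(df$chrom),
             strand = df$strand,
             tss = ifelse(minus, df$txEnd, df$txStart),
             tes = ifelse(minus, df$txStart, df$txEnd),
             exon_starts = df$exonStarts %||% NA_character_,
             exon_ends = df$exonEnds %||% NA_character_,
             stringsAsFactors = FALSE)
}

#' Write a transcript table in refFlat-like TSV form
#' @param transcripts transcript data.frame.
#' @param path output path.
#' @export
write_transcripts <- function(transcripts, path) {
  minus <- transcripts$strand == "-"
  out <- data.frame(id = transcripts$id, chrom = transcripts$chrom,
                    strand = transcripts$strand,
                    txStart = ifelse(minus, transcripts$tes, transcripts$tss),
                    txEnd = ifelse(minus, transcripts$tss, transcripts$tes),
                    exonStarts = transcripts$exon_starts,
                    exonEnds = transcripts$exon_ends)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Exon interval data.frame for one transcript row (0-based half-open).
transcript_exons <- function(tx_row) {
  if (is.na(tx_row$exon_starts) || !nzchar(tx_row$exon_starts))
    return(data.frame(chrom = character(), start = numeric(), end = numeric()))
  s <- as.numeric(strsplit(tx_row$exon_starts, ",")[[1]])
  e <- as.numeric(strsplit(tx_row$exon_ends, ",")[[1]])
  data.frame(chrom = tx_row$chrom, start = s, end = e,
             stringsAsFactors = FALSE)
}

#' Read gene sets in GMT format
#'
#' One set per line: set name, description, then member gene ids, all
#' tab-separated.
#'
#' @param path file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) stop("malformed GMT line ", bad[1])
  stats::setNames(lapply(fields, function(f) f[-c(1, 2)]),
                  vapply(fields, `[[`, "", 1L))
}

#' Read/write the probe TSV used by the array stages
#'
#' Columns: probe_id, chrom, start, end, gc, then one column per
#' channel/replicate (e.g. log_cy3_1, log_cy5_1, ...), plus `normalized_*`
#' columns once normalization has run.
#'
#' @param path file path.
#' @return probe data.frame.
#' @export
read_probes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("probe_id", "chrom", "start", "end", "gc")
  if (!all(need %in% names(df)))
    stop("probe table must have columns ", paste(need, collapse = ", "))
  df
}

#' @rdname read_probes
#' @param probes probe data.frame to write.
#' @export
write_probes <- function(probes, path) {
  utils::write.table(probes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read paired-end tag (PET) pairs
#'
#' TSV with columns chrom1,start1,end1,chrom2,start2,end2 and optional
#' count.
#'
#' @param path file path.
#' @return PET data.frame.
#' @export
read_pets <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  if (!all(need %in% names(df)))
    stop("PET table must have columns ", paste(need, collapse = ", "))
  df
}

#' Read fragment records (chrom, start, end)
#' @param path file path.
#' @return fragment data.frame.
#' @export
read_fragments <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("chrom", "start", "end") %in% names(df)))
    stop("fragment table must have columns chrom, start, end")
  validate_intervals(df)
  df
}

#' Read promoter sequences from FASTA
#' @param path file path.
#' @return named character vector of sequences (names = transcript ids).
#' @export
read_promoter_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write promoter sequences to FASTA
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
write_promoter_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
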