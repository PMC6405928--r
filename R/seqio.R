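# Sequence I/O and the single coordinate convention.
#
# A sequence collection is a named character vector (names = unique ids,
# values = upper-case sequences over A/C/G/T/U/N).  All internal coordinates
# are 0-based half-open; conversion to 1-based happens only in the writers.

VALID_DNA <- "ACGTUN"

premirscan_error <- function(msg, class) {
  stop(structure(class = c(class, "premirscan_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

format_error <- function(msg) premirscan_error(msg, "premirscan_format_error")
data_error   <- function(msg) premirscan_error(msg, "premirscan_data_error")
config_error <- function(msg) premirscan_error(msg, "premirscan_config_error")

#' Read a FASTA file into a named character vector
#'
#' Sequences are upper-cased and, by default, U is normalised to T so that
#' all internal work happens in DNA space.  Ids must be unique; malformed
#' records raise a format error naming the offending line.
#'
#' @param path file path; gzip-compressed input is read transparently.
#' @param to_dna convert U to T (default `TRUE`).
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path, to_dna = TRUE) {
  if (!file.exists(path)) data_error(sprintf("FASTA file not found: %s", path))
  lines <- readLines(con <- gzfile(path)); close(con)
  lines <- sub("\r$", "", lines)
  hdr <- grepl("^>", lines)
  nonempty <- nzchar(trimws(lines))
  if (!any(hdr & nonempty))
    format_error(sprintf("%s: no FASTA header found", path))
  first_hdr <- which(hdr)[1]
  if (any(nonempty[seq_len(first_hdr - 1)]))
    format_error(sprintf("%s: sequence data before first header at line %d",
                         path, which(nonempty)[1]))
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  if (any(!nzchar(ids))) {
    ln <- which(hdr)[!nzchar(ids)][1]
    format_error(sprintf("%s: empty FASTA header at line %d", path, ln))
  }
  grp <- cumsum(hdr)
  body <- lines[!hdr & nonempty]
  bgrp <- grp[!hdr & nonempty]
  seqs <- vapply(seq_along(ids), function(i)
    paste(body[bgrp == i], collapse = ""), character(1))
  seqs <- toupper(gsub("\\s", "", seqs))
  if (any(!nzchar(seqs))) {
    ln <- which(hdr)[!nzchar(seqs)][1]
    format_error(sprintf("%s: empty sequence for record '%s' (line %d)",
                         path, ids[!nzchar(seqs)][1], ln))
  }
  bad <- grepl(sprintf("[^%s]", VALID_DNA), seqs)
  if (any(bad))
    format_error(sprintf("%s: invalid residues in record '%s'",
                         path, ids[bad][1]))
  if (anyDuplicated(ids))
    format_error(sprintf("%s: duplicate sequence id(s): %s", path,
                         paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  if (to_dna) seqs <- chartr("U", "T", seqs)
  stats::setNames(seqs, ids)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line-wrap width (default 70).
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a FASTQ file (sequences only)
#'
#' Qualities are parsed for record framing but discarded; the result is a
#' named character vector like [read_fasta()].
#'
#' @param path file path (gzip transparent).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) data_error(sprintf("FASTQ file not found: %s", path))
  lines <- readLines(con <- gzfile(path)); close(con)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) %% 4L != 0L)
    format_error(sprintf("%s: FASTQ record count not a multiple of 4", path))
  ids <- lines[seq(1L, length(lines), by = 4L)]
  if (any(!grepl("^@", ids)))
    format_error(sprintf("%s: malformed FASTQ header at line %d",
                         path, (which(!grepl("^@", ids))[1] - 1L) * 4L + 1L))
  ids <- sub("\\s.*$", "", sub("^@", "", ids))
  seqs <- toupper(lines[seq(2L, length(lines), by = 4L)])
  stats::setNames(chartr("U", "T", seqs), ids)
}

#' Reverse complement (DNA space)
#' @param x character vector of sequences.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

#' T -> U (RNA space) and back
#' @param x character vector.
#' @export
to_rna <- function(x) chartr("T", "U", x)

#' @rdname to_rna
#' @export
to_dna <- function(x) chartr("U", "T", x)

#' Construct a genomic interval (0-based, half-open)
#'
#' @param seq_id reference sequence id.
#' @param start,end 0-based half-open bounds, `end > start`.
#' @param strand `"+"` or `"-"`.
#' @return one-row data.frame with columns seq_id, start, end, strand.
#' @export
genomic_interval <- function(seq_id, start, end, strand = "+") {
  if (!strand %in% c("+", "-")) config_error("strand must be '+' or '-'")
  if (end <= start) config_error("interval end must exceed start")
  if (start < 0) config_error("interval start must be >= 0")
  data.frame(seq_id = seq_id, start = as.integer(start),
             end = as.integer(end), strand = strand,
             stringsAsFactors = FALSE)
}

#' Extract the sequence of an interval
#'
#' Returns the reverse complement for minus-strand intervals.
#'
#' @param interval one-row data.frame as from [genomic_interval()].
#' @param records named character vector of reference sequences.
#' @export
extract_interval <- function(interval, records) {
  sid <- interval$seq_id
  if (!sid %in% names(records))
    data_error(sprintf("unknown seq_id '%s'", sid))
  L <- nchar(records[[sid]])
  if (interval$start < 0 || interval$end > L)
    data_error(sprintf("interval [%d,%d) out of range for '%s' (length %d)",
                       interval$start, interval$end, sid, L))
  s <- substr(records[[sid]], interval$start + 1L, interval$end)
  if (interval$strand == "-") revcomp(s) else s
}

#' Write predictions as GFF3 (1-based inclusive)
#'
#' @param predictions data.frame with columns seq_id, start, end, strand
#'   (0-based half-open) and optionally id, score.
#' @param path output path.
#' @export
write_gff3 <- function(predictions, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(predictions)) {
    ids <- if ("id" %in% names(predictions)) predictions$id
           else sprintf("premir_%d", seq_len(nrow(predictions)))
    score <- if ("score" %in% names(predictions))
      sprintf("%.6g", predictions$score) else "."
    writeLines(sprintf("%s\tpremirscan\tpre_miRNA\t%d\t%d\t%s\t%s\t.\tID=%s",
                       predictions$seq_id, predictions$start + 1L,
                       predictions$end, score, predictions$strand, ids), con)
  }
  invisible(path)
}

#' Write predictions as BED (0-based half-open)
#' @inheritParams write_gff3
#' @export
write_bed <- function(predictions, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(predictions)) {
    ids <- if ("id" %in% names(predictions)) predictions$id
           else sprintf("premir_%d", seq_len(nrow(predictions)))
    score <- if ("score" %in% names(predictions))
      sprintf("%.6g", predictions$score) else "0"
    writeLines(sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                       predictions$seq_id, predictions$start, predictions$end,
                       ids, score, predictions$strand), con)
  }
  invisible(path)
}
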