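# Computational validation operators: star-sequence detection in the
# precursor duplex, exact matching against small-RNA read sets, and
# homology lookup against a reference mature-miRNA collection.

#' Find the miRNA* (star) sequence of a mature interval in a folded precursor
#'
#' The star is the set of precursor positions paired with the mature region
#' in the dot-bracket structure, extended by `overhang` nt at its 3' end
#' (Dicer leaves a 2-nt 3' overhang on each duplex strand).  The call is
#' reported only when the number of unpaired positions inside the duplex
#' (gaps on either strand between the first and last paired duplex
#' positions) is at most `max_unpaired`.
#'
#' @param precursor_seq precursor sequence.
#' @param fold `fold_result` or dot-bracket string for the precursor.
#' @param mature_start,mature_end 0-based half-open mature interval within
#'   the precursor.
#' @param max_unpaired maximum tolerated unpaired/gap positions in the
#'   duplex (default 4).
#' @param overhang 3' overhang in nt (default 2).
#' @return list (star_start, star_end, n_paired, n_gaps, offset_3p) or
#'   `NULL` when the mature region is unpaired or the duplex is too gapped.
#' @export
find_star <- function(precursor_seq, fold, mature_start, mature_end,
                      max_unpaired = 4L, overhang = 2L) {
  n <- nchar(precursor_seq)
  if (mature_start < 0 || mature_end > n || mature_end <= mature_start)
    config_error("mature interval must lie inside the precursor")
  pairs <- if (is.character(fold)) pairs_from_dotbracket(fold) else fold$pairs
  mpos <- (mature_start + 1L):mature_end # 1-based
  partners <- pairs[mpos]
  paired <- !is.na(partners)
  if (!any(paired)) return(NULL)
  # gaps within the paired part of the mature arm
  span <- range(which(paired))
  gaps_mature <- sum(!paired[span[1]:span[2]])
  p <- partners[paired]
  star_lo <- min(p); star_hi <- max(p)
  # unpaired positions on the star strand inside its span
  gaps_star <- sum(is.na(pairs[star_lo:star_hi]))
  n_gaps <- gaps_mature + gaps_star
  if (n_gaps > max_unpaired) return(NULL)
  # 2-nt 3' overhang: the star's 3' end (its genomically rightmost position,
  # pairing the mature 5' end) extends beyond the duplex
  star_start <- star_lo - 1L                     # 0-based
  star_end <- min(n, star_hi + as.integer(overhang)) # half-open
  if (max(p) > mature_end) {
    # star downstream of mature: extend right end (already done)
  } else {
    # star upstream: its 3' end still is its right edge; same extension rule
    star_end <- min(mature_start, star_hi + as.integer(overhang))
  }
  list(star_start = star_start, star_end = star_end,
       n_paired = sum(paired), n_gaps = n_gaps,
       offset_3p = as.integer(overhang))
}

#' Exact matching of a query against a small-RNA read set
#'
#' Reports reads equal to the query, or containing it as an exact substring
#' (`mode = "substring"`), on the forward strand and optionally the reverse
#' complement.  By construction this enforces the published stringency:
#' identity 100%, query coverage 100%, 0 mismatches, 0 gaps.
#'
#' @param query_seq query sequence (DNA/RNA space).
#' @param read_set named character vector (see [read_fasta()] /
#'   [read_fastq()]).
#' @param mode "substring" (default) or "equal".
#' @param both_strands also match the reverse complement (default TRUE).
#' @return character vector of matching read ids.
#' @export
match_exact <- function(query_seq, read_set, mode = c("substring", "equal"),
                        both_strands = TRUE) {
  mode <- match.arg(mode)
  q <- to_dna(toupper(query_seq))
  reads <- to_dna(toupper(read_set))
  queries <- if (both_strands) c(q, revcomp(q)) else q
  hit <- rep(FALSE, length(reads))
  for (qq in unique(queries)) {
    hit <- hit | if (mode == "equal") reads == qq
                 else grepl(qq, reads, fixed = TRUE)
  }
  names(read_set)[hit]
}

#' Homology lookup of mature candidates against a reference collection
#'
#' Runs the seeded homology engine with each reference entry as the subject;
#' queries with at least one hit within the mismatch budget are labelled
#' "known" (candidate miRNAs conserved in other species), the rest "novel".
#'
#' @param queries named character vector of mature sequences.
#' @param reference named character vector (user-supplied reference set; no
#'   download is performed).
#' @param max_mismatches mismatch budget (default 4).
#' @param word_len seed length (default 7).
#' @return data.frame: query_id, status, best_ref, best_mismatches.
#' @export
homology_lookup <- function(queries, reference, max_mismatches = 4L,
                            word_len = 7L) {
  index <- build_word_index(reference, word_len)
  rows <- lapply(names(queries), function(qid) {
    h <- seed_and_extend(queries[[qid]], index, reference, max_mismatches)
    if (nrow(h))
      data.frame(query_id = qid, status = "known", best_ref = h$seq_id[1],
                 best_mismatches = h$mismatches[1], stringsAsFactors = FALSE)
    else
      data.frame(query_id = qid, status = "novel", best_ref = NA_character_,
                 best_mismatches = NA_integer_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
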