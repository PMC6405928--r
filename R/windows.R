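# From homology hits to precursor-scale candidate windows.

#' Extract the flanked locus around a homology hit
#'
#' Takes `up` nt of 5' flank and `down` nt of 3' flank around the hit *on the
#' hit's strand* (for a minus-strand hit, upstream is genomically rightward),
#' clipping silently at sequence bounds.
#'
#' @param hit one-row data.frame with seq_id, start, end, strand.
#' @param genome named character vector.
#' @param up,down flank sizes in nt (defaults 500/500).
#' @return list with `interval` (plus-strand genomic coordinates of the
#'   locus), `seq` (locus sequence in hit-strand orientation) and
#'   `hit_offset` (0-based offset of the hit inside `seq`).
#' @export
extract_flanked_locus <- function(hit, genome, up = 500L, down = 500L) {
  stopifnot(up >= 0, down >= 0)
  L <- nchar(genome[[hit$seq_id]])
  if (hit$strand == "+") {
    s <- max(0L, hit$start - up); e <- min(L, hit$end + down)
    off <- hit$start - s
  } else {
    s <- max(0L, hit$start - down); e <- min(L, hit$end + up)
    off <- e - hit$end
  }
  iv <- genomic_interval(hit$seq_id, s, e, hit$strand)
  list(interval = iv, seq = extract_interval(iv, genome), hit_offset = off)
}

#' Fragment a locus into multi-size sliding windows
#'
#' For each window size w, windows start at offsets 0, step, 2*step, ... while
#' offset + w <= locus length.  Windows carry genomic coordinates derived
#' from the locus interval; positional windows with byte-identical sequences
#' are collapsed to the first occurrence.  When `hit_offset`/`hit_len` are
#' given, each window records the intersection of the seeding mature hit with
#' the window (the mature anchor).
#'
#' @param locus list as returned by [extract_flanked_locus()], or a bare
#'   list(interval=, seq=).
#' @param sizes window sizes (default c(90, 100, 110, 120)).
#' @param step step in nt (default 10).
#' @param hit_len length of the seeding hit, for anchor bookkeeping.
#' @return data.frame: seq_id, start, end, strand, size, offset, seq,
#'   anchor_start, anchor_end (window-local, NA when absent).
#' @export
fragment_locus <- function(locus, sizes = c(90L, 100L, 110L, 120L),
                           step = 10L, hit_len = NA_integer_) {
  seq <- locus$seq
  iv <- locus$interval
  L <- nchar(seq)
  out <- list()
  for (w in as.integer(sizes)) {
    if (L < w) next
    offs <- seq(0L, L - w, by = as.integer(step))
    # genomic coordinates: locus seq is oriented along iv$strand
    if (iv$strand == "+") {
      gs <- iv$start + offs
    } else {
      gs <- iv$end - offs - w
    }
    win <- data.frame(seq_id = iv$seq_id, start = gs, end = gs + w,
                      strand = iv$strand, size = w, offset = offs,
                      seq = substring(seq, offs + 1L, offs + w),
                      stringsAsFactors = FALSE)
    if (!is.na(hit_len) && !is.null(locus$hit_offset)) {
      a0 <- pmax(locus$hit_offset, offs)
      a1 <- pmin(locus$hit_offset + hit_len, offs + w)
      has <- a1 > a0
      win$anchor_start <- ifelse(has, a0 - offs, NA_integer_)
      win$anchor_end <- ifelse(has, a1 - offs, NA_integer_)
    } else {
      win$anchor_start <- NA_integer_
      win$anchor_end <- NA_integer_
    }
    out[[length(out) + 1L]] <- win
  }
  if (!length(out))
    return(data.frame(seq_id = character(), start = integer(),
                      end = integer(), strand = character(), size = integer(),
                      offset = integer(), seq = character(),
                      anchor_start = integer(), anchor_end = integer(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[!duplicated(res$seq), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# global identity = matches / longer length, via Biostrings global alignment
global_identity <- function(a, b) {
  if (a == b) return(1.0)
  al <- Biostrings::pairwiseAlignment(a, b, type = "global")
  Biostrings::nmatch(al) / max(nchar(a), nchar(b))
}

#' Greedy redundancy removal (CD-HIT-style)
#'
#' Clusters greedily in decreasing-length order: a sequence joins the first
#' existing representative whose global identity (matches / longer length)
#' meets the threshold, otherwise it founds a new cluster.  Representatives
#' are returned in order of first occurrence in the input.
#'
#' @param seqs character vector (names optional).
#' @param identity_threshold in (0.5, 1]; default 1 (exact duplicates only).
#' @return list with `representatives` (character vector) and `cluster`
#'   (integer vector mapping each input to its representative's cluster).
#' @export
dedupe_sequences <- function(seqs, identity_threshold = 1.0) {
  if (identity_threshold <= 0.5 || identity_threshold > 1.0)
    config_error("identity_threshold must be in (0.5, 1]")
  n <- length(seqs)
  if (!n) return(list(representatives = character(), cluster = integer()))
  ord <- order(-nchar(seqs), seq_len(n)) # length-descending, stable
  cluster <- integer(n)
  reps_idx <- integer(0)
  for (i in ord) {
    assigned <- FALSE
    for (ci in seq_along(reps_idx)) {
      r <- seqs[[reps_idx[ci]]]
      if (identity_threshold == 1.0) {
        ok <- identical(seqs[[i]], r)
      } else {
        ok <- global_identity(seqs[[i]], r) >= identity_threshold
      }
      if (ok) { cluster[i] <- ci; assigned <- TRUE; break }
    }
    if (!assigned) {
      reps_idx <- c(reps_idx, i)
      cluster[i] <- length(reps_idx)
    }
  }
  # representatives in input order of first occurrence
  ord2 <- order(reps_idx)
  remap <- integer(length(reps_idx))
  remap[ord2] <- seq_along(reps_idx)
  list(representatives = seqs[sort(reps_idx)], cluster = remap[cluster])
}
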