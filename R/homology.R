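# Seeded homology search of short mature-miRNA queries against a genome.
#
# Model: ungapped, full-query-coverage placements with at most
# `max_mismatches` substitutions, seeded by exact words of length `word_len`
# (default 7) on both strands.  Sensitivity caveat: a placement with >= 3
# mismatches in a 21-mer can, in principle, destroy every 7-mer seed; the
# exhaustive mode scans every offset and strand instead.  E-values are not
# computed: the permissive published cutoff (10) is honoured by construction.

#' Build an exact-word index over a genome
#'
#' Indexes every `word_len`-mer of every sequence (forward strand only; minus
#' strand is handled by searching the reverse-complemented query).
#'
#' @param genome named character vector of sequences.
#' @param word_len word (seed) length, >= 4; default 7.
#' @return object of class `word_index`.
#' @export
build_word_index <- function(genome, word_len = 7L) {
  word_len <- as.integer(word_len)
  if (word_len < 4L) config_error("word_len must be >= 4")
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (sid in names(genome)) {
    s <- genome[[sid]]
    L <- nchar(s)
    if (L < word_len) next
    starts <- seq_len(L - word_len + 1L)
    words <- substring(s, starts, starts + word_len - 1L)
    sp <- split(starts - 1L, words) # 0-based offsets
    for (w in names(sp)) {
      cur <- get0(w, envir = env)
      entry <- list(list(seq_id = sid, pos = sp[[w]]))
      assign(w, if (is.null(cur)) entry else c(cur, entry), envir = env)
    }
  }
  structure(list(env = env, word_len = word_len,
                 seq_len = vapply(genome, nchar, integer(1))),
            class = "word_index")
}

#' Look up all forward-strand positions of a word
#' @param index a `word_index`.
#' @param word exact word of length `index$word_len`.
#' @return data.frame (seq_id, pos), 0-based.
#' @export
lookup_word <- function(index, word) {
  if (nchar(word) != index$word_len)
    config_error("word length does not match index word_len")
  hits <- get0(word, envir = index$env)
  if (is.null(hits))
    return(data.frame(seq_id = character(), pos = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(hits, function(h)
    data.frame(seq_id = h$seq_id, pos = h$pos, stringsAsFactors = FALSE)))
}

empty_hits <- function() {
  data.frame(query_id = character(), seq_id = character(), start = integer(),
             end = integer(), strand = character(), mismatches = integer(),
             aligned_len = integer(), score = double(), rank = integer(),
             stringsAsFactors = FALSE)
}

# candidate offsets (0-based) on one oriented query, via the seed index
seeded_offsets <- function(index, genome, q) {
  m <- nchar(q)
  w <- index$word_len
  starts <- seq_len(m - w + 1L)
  words <- unique(substring(q, starts, starts + w - 1L))
  out <- list()
  for (word in words) {
    hits <- get0(word, envir = index$env)
    if (is.null(hits)) next
    qpos <- starts[substring(q, starts, starts + w - 1L) == word] - 1L
    for (h in hits) {
      for (qp in qpos) {
        off <- h$pos - qp
        out[[length(out) + 1L]] <-
          data.frame(seq_id = h$seq_id, off = off, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(NULL)
  unique(do.call(rbind, out))
}

#' Seeded homology search of one query against an indexed genome
#'
#' Reports every full-length ungapped placement with at most `max_mismatches`
#' substitutions that shares at least one exact `word_len`-mer with the
#' genome, on either strand, exactly once.  Score = matches - mismatches.
#' Hits are sorted by (mismatches, -score, seq_id, start, strand).
#'
#' @param query unambiguous DNA string, typically 17-30 nt.
#' @param index a [build_word_index()] result.
#' @param genome the same named character vector the index was built from.
#' @param max_mismatches maximum substitutions (default 4).
#' @return data.frame of hits (0-based half-open intervals).
#' @export
seed_and_extend <- function(query, index, genome, max_mismatches = 4L) {
  query <- toupper(to_dna(query))
  if (grepl("[^ACGT]", query))
    data_error("query must be unambiguous DNA (A/C/G/T only)")
  m <- nchar(query)
  if (m < index$word_len)
    config_error("query shorter than index word_len")
  res <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") query else revcomp(query)
    cand <- seeded_offsets(index, genome, q)
    if (is.null(cand)) next
    for (sid in unique(cand$seq_id)) {
      offs <- sort(unique(cand$off[cand$seq_id == sid]))
      L <- nchar(genome[[sid]])
      offs <- offs[offs >= 0L & offs + m <= L]
      if (!length(offs)) next
      mm <- vapply(offs, function(o) {
        sum(strsplit(substr(genome[[sid]], o + 1L, o + m), "")[[1]] !=
              strsplit(q, "")[[1]])
      }, integer(1))
      keep <- mm <= max_mismatches
      if (!any(keep)) next
      res[[length(res) + 1L]] <- data.frame(
        seq_id = sid, start = offs[keep], end = offs[keep] + m,
        strand = strand, mismatches = mm[keep],
        aligned_len = m, score = (m - mm[keep]) - mm[keep],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) return(empty_hits()[, -1L])
  hits <- do.call(rbind, res)
  hits <- hits[order(hits$mismatches, -hits$score, hits$seq_id,
                     hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Exhaustive homology scan (every offset, both strands)
#'
#' Brute-force counterpart of [seed_and_extend()]; guaranteed-complete for
#' any mismatch budget, intended for small genomes or the `exhaustive`
#' config switch.
#'
#' @inheritParams seed_and_extend
#' @export
exhaustive_scan <- function(query, genome, max_mismatches = 4L) {
  query <- toupper(to_dna(query))
  m <- nchar(query)
  res <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") query else revcomp(query)
    for (sid in names(genome)) {
      if (nchar(genome[[sid]]) < m) next
      mm <- .hamming_offsets(genome[[sid]], q)
      keep <- which(mm <= max_mismatches)
      if (!length(keep)) next
      res[[length(res) + 1L]] <- data.frame(
        seq_id = sid, start = keep - 1L, end = keep - 1L + m,
        strand = strand, mismatches = mm[keep],
        aligned_len = m, score = (m - mm[keep]) - mm[keep],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) return(empty_hits()[, -1L])
  hits <- do.call(rbind, res)
  hits <- hits[order(hits$mismatches, -hits$score, hits$seq_id,
                     hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Per-query hit selection: mismatch cutoff then top-k
#'
#' Keeps, within each query, hits with `mismatches < max_mismatches_exclusive`
#' (published rule: "< 5 mismatches") and then the first `top_k` in sort
#' order (published rule: top 10), re-ranking 1..k.
#'
#' @param hits data.frame with a `query_id` column, sorted as produced by
#'   [scan_homology()].
#' @param top_k hits retained per query (default 10).
#' @param max_mismatches_exclusive exclusive mismatch bound (default 5).
#' @export
select_hits <- function(hits, top_k = 10L, max_mismatches_exclusive = 5L) {
  if (!nrow(hits)) return(hits)
  out <- do.call(rbind, lapply(split(hits, hits$query_id), function(h) {
    h <- h[h$mismatches < max_mismatches_exclusive, , drop = FALSE]
    h <- head(h, top_k)
    if (nrow(h)) h$rank <- seq_len(nrow(h))
    h
  }))
  if (is.null(out)) return(hits[0, , drop = FALSE])
  out <- out[order(out$query_id, out$rank), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Homology scan of many queries with selection
#'
#' Convenience wrapper: seed-and-extend (or exhaustive scan) every query,
#' attach query ids, and apply the mismatch/top-k selection.
#'
#' @param genome named character vector.
#' @param queries named character vector of mature miRNA sequences.
#' @param word_len seed length (default 7).
#' @param max_mismatches inclusive mismatch budget for the engine (default 4).
#' @param top_k per-query cap (default 10).
#' @param exhaustive use the brute-force scan instead of seeding.
#' @export
scan_homology <- function(genome, queries, word_len = 7L, max_mismatches = 4L,
                          top_k = 10L, exhaustive = FALSE) {
  index <- if (exhaustive) NULL else build_word_index(genome, word_len)
  res <- lapply(names(queries), function(qid) {
    h <- if (exhaustive) exhaustive_scan(queries[[qid]], genome, max_mismatches)
         else seed_and_extend(queries[[qid]], index, genome, max_mismatches)
    if (nrow(h)) cbind(query_id = qid, h, stringsAsFactors = FALSE)
    else empty_hits()
  })
  hits <- do.call(rbind, res)
  if (!nrow(hits)) return(empty_hits())
  hits$rank <- NA_integer_
  select_hits(hits, top_k = top_k,
              max_mismatches_exclusive = max_mismatches + 1L)
}

#' Import hits from BLAST tabular output (outfmt 6)
#'
#' Adapter for an external `blastn -word_size 7 -evalue 10` run: parses the
#' standard 12-column tabular format and converts records to the package's
#' hit model.  Only full-query-coverage, gap-free alignments are retained
#' (the ungapped model the downstream mismatch rule is defined on);
#' coordinates are converted to 0-based half-open, minus-strand hits are
#' recognised by reversed subject coordinates.
#'
#' @param path BLAST outfmt-6 file (qseqid sseqid pident length mismatch
#'   gapopen qstart qend sstart send evalue bitscore).
#' @param query_lengths named integer vector of query lengths, for the
#'   full-coverage check.
#' @return hit data.frame as from [scan_homology()] (rank unset).
#' @export
read_blast_tab <- function(path, query_lengths) {
  if (!file.exists(path)) data_error(sprintf("BLAST file not found: %s", path))
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  tab <- tryCatch(read.delim(path, header = FALSE, col.names = cols,
                             stringsAsFactors = FALSE),
                  error = function(e) format_error(
                    sprintf("%s: not BLAST outfmt 6 (%s)", path,
                            conditionMessage(e))))
  keep <- tab$gapopen == 0 &
    tab$qseqid %in% names(query_lengths) &
    tab$length == query_lengths[tab$qseqid] &
    tab$qstart == 1 & tab$qend == query_lengths[tab$qseqid]
  tab <- tab[keep, , drop = FALSE]
  if (!nrow(tab)) return(empty_hits())
  minus <- tab$sstart > tab$send
  start0 <- ifelse(minus, tab$send, tab$sstart) - 1L
  end0 <- ifelse(minus, tab$sstart, tab$send)
  hits <- data.frame(
    query_id = tab$qseqid, seq_id = tab$sseqid, start = as.integer(start0),
    end = as.integer(end0), strand = ifelse(minus, "-", "+"),
    mismatches = as.integer(tab$mismatch), aligned_len = as.integer(tab$length),
    score = (tab$length - tab$mismatch) - tab$mismatch, rank = NA_integer_,
    stringsAsFactors = FALSE)
  hits <- hits[order(hits$query_id, hits$mismatches, -hits$score,
                     hits$seq_id, hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}
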