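# Folding, hairpin topology metrics and the pseudo-miRNA filters.

#' Fold an RNA/DNA sequence
#'
#' Backends:
#' \describe{
#'   \item{`reference`}{bundled DP minimising a simple stacking energy
#'     (GC 1.8, AU 1.0, GU 0.6 kcal/mol per stacked pair, averaged over the
#'     two pairs of a stack); no lonely pairs, hairpin loops >= 3 nt.
#'     Default, deterministic, dependency-free.}
#'   \item{`maxpair`}{same DP maximising the raw base-pair count (Nussinov);
#'     retained as the classical oracle surface.}
#'   \item{`rnafold`}{shells out to an external `RNAfold` binary if present
#'     on the PATH; errors with instructions otherwise.}
#'   \item{`fixture`}{looks the sequence up in a recorded (id, seq,
#'     dotbracket, mfe) TSV supplied via `fixture_table`.}
#' }
#'
#' @param seq nucleotide string (T or U space), length >= 10.
#' @param backend one of "reference", "maxpair", "rnafold", "fixture".
#' @param fixture_table data.frame with columns seq, dotbracket, mfe
#'   (required for the fixture backend).
#' @return list of class `fold_result`: dotbracket, mfe, pairs (1-based
#'   partner index or NA), backend.
#' @export
fold_rna <- function(seq, backend = c("reference", "maxpair", "rnafold",
                                      "fixture"),
                     fixture_table = NULL) {
  backend <- match.arg(backend)
  if (nchar(seq) < 10L) config_error("fold_rna requires length >= 10")
  rna <- to_rna(toupper(seq))
  if (backend %in% c("reference", "maxpair")) {
    r <- .fold_engine(rna, if (backend == "maxpair") 0L else 1L)
    out <- list(dotbracket = r$dotbracket, mfe = r$mfe, pairs = r$pairs,
                backend = backend)
  } else if (backend == "rnafold") {
    bin <- Sys.which("RNAfold")
    if (!nzchar(bin))
      config_error(paste("RNAfold binary not found on PATH; install ViennaRNA",
                         "or use backend='fixture' with a recorded fold table",
                         "(see ?fold_rna)"))
    res <- system2(bin, args = c("--noPS"), input = rna, stdout = TRUE)
    line <- res[2]
    db <- sub("\\s.*$", "", line)
    mfe <- as.numeric(gsub("[()\\s]", "", sub("^\\S+\\s+", "", line)))
    out <- list(dotbracket = db, mfe = mfe, pairs = pairs_from_dotbracket(db),
                backend = "rnafold")
  } else {
    if (is.null(fixture_table))
      config_error("fixture backend requires fixture_table")
    if (is.character(fixture_table)) # path to a recorded TSV
      fixture_table <- read.delim(fixture_table, stringsAsFactors = FALSE)
    i <- match(to_rna(toupper(seq)), to_rna(toupper(fixture_table$seq)))
    if (is.na(i)) data_error("sequence not present in fixture table")
    db <- fixture_table$dotbracket[i]
    out <- list(dotbracket = db, mfe = fixture_table$mfe[i],
                pairs = pairs_from_dotbracket(db), backend = "fixture")
  }
  class(out) <- "fold_result"
  out
}

#' Pair table from a dot-bracket string
#' @param db dot-bracket string over `(`, `)`, `.`.
#' @return integer vector; position i holds the 1-based partner or NA.
#' @export
pairs_from_dotbracket <- function(db) {
  ch <- strsplit(db, "", fixed = TRUE)[[1]]
  if (any(!ch %in% c("(", ")", ".")))
    format_error("dot-bracket may contain only '(', ')' and '.'")
  n <- length(ch)
  pairs <- rep(NA_integer_, n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      if (!length(stack)) format_error("unbalanced dot-bracket string")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pairs[i] <- j; pairs[j] <- i
    }
  }
  if (length(stack)) format_error("unbalanced dot-bracket string")
  pairs
}

#' Serialise a pair table back to dot-bracket
#' @param pairs integer partner vector as from [pairs_from_dotbracket()].
#' @export
dotbracket_from_pairs <- function(pairs) {
  out <- rep(".", length(pairs))
  has <- !is.na(pairs)
  out[has & pairs > seq_along(pairs)] <- "("
  out[has & pairs < seq_along(pairs)] <- ")"
  paste(out, collapse = "")
}

#' GC content in percent
#'
#' 100 * (G + C) / length; N counts in the denominator only.
#' @param seq nucleotide string.
#' @export
gc_percent <- function(seq) {
  if (!nchar(seq)) config_error("gc_percent of empty sequence")
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  100 * sum(ch %in% c("G", "C")) / length(ch)
}

#' Hairpin topology metrics of a folded sequence
#'
#' A *helix* is a maximal run of stacked pairs (`n_stems` counts helices).
#' For `stem_len`, helices are chained into stems when consecutive helices
#' are separated by at most 3 unpaired nt on either strand (bulges and small
#' internal loops bridged); `stem_len` counts base pairs in the longest
#' such chain.  A *hairpin loop*
#' is an unpaired stretch closed directly by a pair; `terminal_loop_len` is
#' the loop of the hairpin owning the longest stem.
#'
#' @param seq sequence (only its length and GC content are used).
#' @param fold `fold_result` or dot-bracket string.
#' @return named list: n_bp, n_stems, n_hairpin_loops, stem_len,
#'   terminal_loop_len, gc_percent, mfe, length.
#' @export
hairpin_metrics <- function(seq, fold) {
  if (is.character(fold)) fold <- list(dotbracket = fold, mfe = NA_real_)
  db <- fold$dotbracket
  if (nchar(db) != nchar(seq))
    config_error("fold length does not match sequence length")
  pairs <- pairs_from_dotbracket(db)
  n <- length(pairs)
  n_bp <- sum(!is.na(pairs)) / 2
  # helices: maximal runs where pair(i+1) == pair(i) - 1
  opens <- which(!is.na(pairs) & pairs > seq_len(n))
  helices <- list() # each: (i_start, i_end, j_start, j_end, n pairs)
  if (length(opens)) {
    run_start <- opens[1]
    prev <- opens[1]
    for (i in opens[-1]) {
      if (i == prev + 1L && pairs[i] == pairs[prev] - 1L) {
        prev <- i
      } else {
        helices[[length(helices) + 1L]] <-
          c(run_start, prev, pairs[prev], pairs[run_start],
            prev - run_start + 1L)
        run_start <- i; prev <- i
      }
    }
    helices[[length(helices) + 1L]] <-
      c(run_start, prev, pairs[prev], pairs[run_start],
        prev - run_start + 1L)
  }
  n_helices <- length(helices)
  # chain helices into stems: helix b continues helix a when the gaps
  # between a's inner end and b's outer end are <= 3 nt on both strands
  stems <- list()
  if (n_helices) {
    cur <- helices[[1]]
    cur_bp <- cur[5]
    cur_inner <- c(cur[2], cur[3]) # innermost open pos, innermost close pos
    cur_outer <- c(cur[1], cur[4])
    for (h in seq_len(n_helices - 1L) + 1L) {
      b <- helices[[h]]
      gap5 <- b[1] - cur_inner[1] - 1L
      gap3 <- cur_inner[2] - b[4] - 1L
      if (gap5 >= 0L && gap3 >= 0L && gap5 <= 3L && gap3 <= 3L) {
        cur_bp <- cur_bp + b[5]
        cur_inner <- c(b[2], b[3])
      } else {
        stems[[length(stems) + 1L]] <- list(bp = cur_bp, inner = cur_inner,
                                            outer = cur_outer)
        cur_bp <- b[5]
        cur_inner <- c(b[2], b[3])
        cur_outer <- c(b[1], b[4])
      }
    }
    stems[[length(stems) + 1L]] <- list(bp = cur_bp, inner = cur_inner,
                                        outer = cur_outer)
  }
  n_stems <- n_helices # "stems" reported = maximal contiguous helices
  # hairpin loops: innermost pairs enclosing no other pair
  hp_loops <- Filter(function(h) {
    i <- h[2]; j <- h[3]
    j > i + 1L && all(is.na(pairs[(i + 1L):(j - 1L)]))
  }, helices)
  n_hairpin_loops <- length(hp_loops)
  stem_len <- if (length(stems)) max(vapply(stems, `[[`, numeric(1), "bp")) else 0
  # terminal loop of the longest stem (the hairpin its innermost helix closes)
  terminal_loop_len <- 0L
  if (length(stems)) {
    best <- stems[[which.max(vapply(stems, `[[`, numeric(1), "bp"))]]
    i <- best$inner[1]; j <- best$inner[2]
    inside <- if (j > i + 1L) pairs[(i + 1L):(j - 1L)] else integer(0)
    if (length(inside) && all(is.na(inside)))
      terminal_loop_len <- length(inside)
  }
  list(n_bp = as.integer(n_bp), n_stems = n_stems,
       n_hairpin_loops = n_hairpin_loops, stem_len = as.integer(stem_len),
       terminal_loop_len = as.integer(terminal_loop_len),
       gc_percent = gc_percent(seq),
       mfe = if (is.null(fold$mfe)) NA_real_ else fold$mfe,
       length = nchar(seq))
}

#' Pseudo-miRNA filter configuration
#'
#' Defaults are the published screening ranges: stem length 20-50 bp, GC
#' content 24-82 percent, MFE -60 to -20 kcal/mol (all inclusive), plus a
#' single-hairpin requirement.
#'
#' @param stem_min,stem_max stem length bounds in base pairs.
#' @param gc_min,gc_max GC bounds in percent.
#' @param mfe_min,mfe_max MFE bounds in kcal/mol (min is the more negative).
#' @param require_single_hairpin demand exactly one hairpin loop.
#' @export
filter_config <- function(stem_min = 20, stem_max = 50,
                          gc_min = 24, gc_max = 82,
                          mfe_min = -60, mfe_max = -20,
                          require_single_hairpin = TRUE) {
  if (stem_min > stem_max || gc_min > gc_max || mfe_min > mfe_max)
    config_error("filter bounds must satisfy min <= max")
  list(stem_min = stem_min, stem_max = stem_max, gc_min = gc_min,
       gc_max = gc_max, mfe_min = mfe_min, mfe_max = mfe_max,
       require_single_hairpin = isTRUE(require_single_hairpin))
}

#' Apply the pseudo-miRNA filters
#'
#' @param metrics list from [hairpin_metrics()].
#' @param cfg list from [filter_config()].
#' @return list(pass = logical, failed = character vector of criteria among
#'   "stem", "gc", "mfe", "single_hairpin").
#' @export
passes_filter <- function(metrics, cfg = filter_config()) {
  failed <- character(0)
  if (metrics$stem_len < cfg$stem_min || metrics$stem_len > cfg$stem_max)
    failed <- c(failed, "stem")
  if (metrics$gc_percent < cfg$gc_min || metrics$gc_percent > cfg$gc_max)
    failed <- c(failed, "gc")
  if (is.na(metrics$mfe) || metrics$mfe < cfg$mfe_min ||
      metrics$mfe > cfg$mfe_max)
    failed <- c(failed, "mfe")
  if (cfg$require_single_hairpin && metrics$n_hairpin_loops != 1L)
    failed <- c(failed, "single_hairpin")
  list(pass = !length(failed), failed = failed)
}
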