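# Synthetic fixtures with planted ground truth.  The generator states the
# world the tests live in: hairpin precursors with 20-40 bp arms, 20-24 nt
# matures on the 5' arm, ~50% GC, planted in uniform background; decoys are
# dinucleotide-shuffled hairpins and ORF-like coding stretches; pseudo-
# hairpins (imperfect inverted repeats) supply the CDS negative class.

rand_base <- function(n, gc = 0.5) {
  # exact composition: round(n*gc) G/C bases, rest A/T, shuffled
  ngc <- round(n * gc)
  b <- c(sample(c("G", "C"), ngc, replace = TRUE),
         sample(c("A", "T"), n - ngc, replace = TRUE))
  paste(sample(b), collapse = "")
}

#' Generate a hairpin precursor sequence
#'
#' sequence = arm + loop + reverse complement of arm, with `bulges` random
#' unpaired single-nucleotide insertions in the 3' arm.  Realised GC lands
#' within ~5 percentage points of `gc_target` by construction.  The
#' maximum-pairing structure contains a stem of at least `arm_len - bulges`
#' pairs.
#'
#' @param seed RNG seed.
#' @param arm_len arm length in bp, 15-60.
#' @param loop_len loop length in nt, 3-20.
#' @param gc_target target GC fraction (default 0.5).
#' @param bulges number of unpaired insertions (default 0).
#' @return list: seq, arm_len, loop_len, mature_start, mature_end (0-based
#'   half-open 21-nt mature on the 5' arm, clipped to the arm).
#' @export
make_hairpin <- function(seed, arm_len = 25L, loop_len = 6L, gc_target = 0.5,
                         bulges = 0L) {
  if (arm_len < 15L || arm_len > 60L) config_error("arm_len must be in [15,60]")
  if (loop_len < 3L || loop_len > 20L) config_error("loop_len must be in [3,20]")
  set.seed(as.integer(seed))
  arm <- rand_base(arm_len, gc_target)
  loop <- rand_base(loop_len, gc_target)
  right <- revcomp(arm)
  if (bulges > 0L) {
    for (b in seq_len(bulges)) {
      pos <- sample.int(nchar(right) - 1L, 1L)
      ins <- sample(c("A", "C", "G", "T"), 1L)
      right <- paste0(substr(right, 1L, pos), ins,
                      substr(right, pos + 1L, nchar(right)))
    }
  }
  seq <- paste0(arm, loop, right)
  mlen <- min(21L, arm_len)
  list(seq = seq, arm_len = arm_len, loop_len = loop_len,
       mature_start = 0L, mature_end = mlen)
}

#' Exact dinucleotide shuffle (Altschul-Erickson style)
#'
#' Returns a sequence with exactly the same dinucleotide counts, via a
#' random Eulerian walk on the dinucleotide multigraph.
#'
#' @param seq input sequence.
#' @param seed RNG seed.
#' @export
dinucleotide_shuffle <- function(seq, seed = 1L) {
  set.seed(as.integer(seed))
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  if (n < 3L) return(seq)
  # edge lists: successors of each residue, in input order
  succ <- split(ch[-1L], ch[-n])
  for (attempt in 1:1000) {
    sh <- lapply(succ, function(v) v[sample.int(length(v))])
    # walk from the original start
    cur <- ch[1L]
    idx <- stats::setNames(rep(1L, length(sh)), names(sh))
    out <- character(n)
    out[1L] <- cur
    ok <- TRUE
    for (i in 2:n) {
      v <- sh[[cur]]
      if (is.null(v) || idx[[cur]] > length(v)) { ok <- FALSE; break }
      nxt <- v[idx[[cur]]]
      idx[[cur]] <- idx[[cur]] + 1L
      out[i] <- nxt
      cur <- nxt
    }
    if (ok) return(paste(out, collapse = ""))
  }
  # fallback: plain shuffle (preserves mononucleotide counts only)
  paste(sample(ch), collapse = "")
}

#' Generate an ORF-like coding stretch
#'
#' ATG followed by random sense codons (no stops), used as CDS-like decoy
#' and negative-set background.
#' @param len approximate length in nt.
#' @param gc target GC fraction.
#' @export
make_orf <- function(len, gc = 0.5) {
  stops <- c("TAA", "TAG", "TGA")
  ncod <- max(1L, (len - 3L) %/% 3L)
  cods <- character(ncod)
  i <- 1L
  while (i <= ncod) {
    c3 <- rand_base(3L, gc)
    if (!c3 %in% stops) { cods[i] <- c3; i <- i + 1L }
  }
  paste0("ATG", paste(cods, collapse = ""))
}

# imperfect inverted repeat: hairpin with scattered arm substitutions
make_pseudo_hairpin <- function(seed, arm_len = 28L, loop_len = 8L,
                                gc_target = 0.5, mismatch_rate = 0.12) {
  hp <- make_hairpin(seed, arm_len, loop_len, gc_target)
  ch <- strsplit(hp$seq, "", fixed = TRUE)[[1]]
  n_mut <- max(1L, round(arm_len * mismatch_rate))
  # scatter substitutions over the 3' arm only, spaced >= 4 nt so single
  # mismatches stay bridgeable in the stem-length sense
  arm3 <- (arm_len + loop_len + 1L):length(ch)
  cand <- arm3[seq(2L, length(arm3) - 1L)]
  pos <- sort(sample(cand, n_mut))
  for (try in 1:200) {
    if (length(pos) < 2L || min(diff(pos)) >= 5L) break
    pos <- sort(sample(cand, n_mut))
  }
  for (p in pos) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  }
  list(seq = paste(ch, collapse = ""), arm_len = arm_len,
       loop_len = loop_len, n_mut = n_mut)
}

#' Generate a genome with planted precursors and decoys
#'
#' Plants `n_precursors` filter-passing hairpins (arms 20-40 bp, loops 4-15
#' nt, GC 40-60%) and `n_decoys` decoys (alternating dinucleotide-shuffled
#' hairpins and ORF-like stretches) at disjoint positions in uniform
#' background.  Each precursor's 21-nt mature (5' arm) is emitted as a
#' companion known-miRNA set.
#'
#' @param n_precursors number of planted precursors (default 20).
#' @param n_decoys number of decoys (default 10).
#' @param bg_len genome length in nt (default 50000).
#' @param seed RNG seed.
#' @param bulges unpaired insertions per precursor (default 0: perfect
#'   duplexes).
#' @return list of class `planted_truth`: genome (named character vector),
#'   truth (data.frame seq_id, start, end, strand, arm_len, loop_len,
#'   mature_start, mature_end), mature (named character vector), decoys
#'   (data.frame), seed.
#' @export
make_genome <- function(n_precursors = 20L, n_decoys = 10L, bg_len = 50000L,
                        seed = 1L, bulges = 0L) {
  set.seed(as.integer(seed))
  sid <- "synth_chr1"
  bg <- strsplit(rand_base(bg_len, 0.5), "", fixed = TRUE)[[1]]
  # inserts
  inserts <- list()
  for (i in seq_len(n_precursors)) {
    hp <- make_hairpin(seed = seed * 1000L + i,
                       arm_len = sample(20:40, 1L),
                       loop_len = sample(4:15, 1L),
                       gc_target = runif(1, 0.40, 0.60),
                       bulges = bulges)
    inserts[[length(inserts) + 1L]] <- c(hp, list(kind = "precursor"))
  }
  for (i in seq_len(n_decoys)) {
    if (i %% 2L == 1L) {
      hp <- make_hairpin(seed = seed * 2000L + i,
                         arm_len = sample(20:40, 1L),
                         loop_len = sample(4:15, 1L),
                         gc_target = runif(1, 0.40, 0.60))
      s <- dinucleotide_shuffle(hp$seq, seed = seed * 2000L + i)
      inserts[[length(inserts) + 1L]] <- list(seq = s, kind = "decoy_shuffle")
    } else {
      inserts[[length(inserts) + 1L]] <-
        list(seq = make_orf(sample(60:120, 1L), gc = runif(1, 0.4, 0.6)),
             kind = "decoy_orf")
    }
  }
  # disjoint placement with 150-nt clearance, bounded retries
  set.seed(as.integer(seed) + 7L)
  taken <- matrix(numeric(0), ncol = 2)
  truth <- list(); decoys <- list(); mature <- character(0)
  for (k in seq_along(inserts)) {
    ins <- inserts[[k]]
    L <- nchar(ins$seq)
    placed <- FALSE
    for (try in 1:200) {
      s <- sample.int(bg_len - L - 600L, 1L) + 300L
      e <- s + L
      if (!nrow(taken) ||
          all(e + 150L <= taken[, 1] | s - 150L >= taken[, 2])) {
        taken <- rbind(taken, c(s, e))
        bg[(s + 1L):e] <- strsplit(ins$seq, "", fixed = TRUE)[[1]]
        placed <- TRUE
        break
      }
    }
    if (!placed) data_error("could not place insert after bounded retries")
    if (identical(ins$kind, "precursor")) {
      i <- length(truth) + 1L
      truth[[i]] <- data.frame(
        seq_id = sid, start = s, end = e, strand = "+",
        arm_len = ins$arm_len, loop_len = ins$loop_len,
        mature_start = s + ins$mature_start, mature_end = s + ins$mature_end,
        stringsAsFactors = FALSE)
      mature[sprintf("mir_%03d", i)] <-
        substr(ins$seq, ins$mature_start + 1L, ins$mature_end)
    } else {
      decoys[[length(decoys) + 1L]] <-
        data.frame(seq_id = sid, start = s, end = e, strand = "+",
                   kind = ins$kind, stringsAsFactors = FALSE)
    }
  }
  structure(list(genome = stats::setNames(paste(bg, collapse = ""), sid),
                 truth = do.call(rbind, truth),
                 mature = mature,
                 decoys = if (length(decoys)) do.call(rbind, decoys)
                          else NULL,
                 seed = as.integer(seed)),
            class = "planted_truth")
}

#' Two-class Gaussian feature clouds
#'
#' Class means sit at +/- shift/2 on each of the first `n_informative`
#' dimensions (unit variance everywhere), so the centroid separation is
#' shift * sqrt(n_informative) sigma.
#'
#' @param n_per_class samples per class.
#' @param dim dimensionality (default 10).
#' @param shift per-dimension mean separation in sigma units.
#' @param n_informative dims carrying signal (default all).
#' @param seed RNG seed.
#' @return list: X (matrix), y (+1/-1 labels).
#' @export
make_feature_cloud <- function(n_per_class, dim = 10L, shift = 4,
                               n_informative = dim, seed = 1L) {
  set.seed(as.integer(seed))
  n <- 2L * n_per_class
  X <- matrix(rnorm(n * dim), nrow = n)
  y <- rep(c(1, -1), each = n_per_class)
  for (j in seq_len(n_informative))
    X[, j] <- X[, j] + ifelse(y > 0, shift / 2, -shift / 2)
  list(X = X, y = y)
}

#' Simulated training set for the classifier
#'
#' Positives: hairpins (arms 20-40 bp, perfect duplexes) embedded in random
#' flanks to a sampled window size (90-120 nt).  Negatives: windows from
#' synthetic ORF-like coding sequence with planted pseudo-hairpins, passing
#' the pseudo-miRNA filters (the published CDS negative construction).
#'
#' @param n_pos,n_neg class sizes (defaults 150/150).
#' @param seed RNG seed.
#' @param filter_cfg a [filter_config()] applied to the negatives.
#' @param backend folding backend.
#' @return list: seqs, y (+1/-1), folds.
#' @export
simulate_training_set <- function(n_pos = 150L, n_neg = 150L, seed = 1L,
                                  filter_cfg = filter_config(),
                                  backend = "reference") {
  # positives: hairpin windows that themselves satisfy the filters (both
  # training classes pass the screening step, as in the published design)
  pos <- character(0)
  set.seed(as.integer(seed) + 31L)
  i <- 0L
  while (length(pos) < n_pos && i < n_pos * 30L) {
    i <- i + 1L
    hp <- make_hairpin(seed = seed * 4000L + i,
                       arm_len = sample(20:40, 1L),
                       loop_len = sample(4:15, 1L),
                       gc_target = runif(1, 0.40, 0.60))
    w <- sample(c(90L, 100L, 110L, 120L), 1L)
    pad <- max(0L, w - nchar(hp$seq))
    left <- sample.int(pad + 1L, 1L) - 1L
    s <- substr(paste0(rand_base(left, 0.5), hp$seq,
                       rand_base(pad - left, 0.5)), 1L, w)
    f <- fold_rna(s, backend = backend)
    if (passes_filter(hairpin_metrics(s, f), filter_cfg)$pass)
      pos[sprintf("pos_%04d", length(pos) + 1L)] <- s
  }
  if (length(pos) < n_pos)
    data_error("could not generate enough filter-passing positive windows")
  # negatives: synthetic CDS with embedded pseudo-hairpins
  set.seed(as.integer(seed) + 77L)
  n_cds <- max(4L, ceiling(n_neg / 8L))
  cds <- character(0)
  for (i in seq_len(n_cds)) {
    parts <- character(0)
    for (j in 1:10) {
      parts <- c(parts, make_orf(sample(60:100, 1L), gc = runif(1, 0.4, 0.6)))
      ph <- make_pseudo_hairpin(seed = seed * 5000L + i * 97L + j,
                                arm_len = sample(22:38, 1L),
                                loop_len = sample(4:15, 1L),
                                gc_target = runif(1, 0.40, 0.60))
      parts <- c(parts, ph$seq)
    }
    cds[sprintf("cds_%02d", i)] <- paste(parts, collapse = "")
  }
  neg <- build_negative_set(cds, n_required = n_neg,
                            filter_cfg = filter_cfg, seed = seed,
                            backend = backend)
  seqs <- c(pos, neg$seqs)
  y <- c(rep(1, length(pos)), rep(-1, length(neg$seqs)))
  list(seqs = seqs, y = y)
}
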