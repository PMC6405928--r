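# Independent oracles used across the suite.  These deliberately share no
# code with the package implementations they check.

# random DNA of length n
rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

oracle_revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N", U = "A")
  paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
}

# brute-force Hamming scan of a query over all offsets and both strands
oracle_hamming_scan <- function(query, genome, max_mismatches) {
  out <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") query else oracle_revcomp(query)
    qc <- strsplit(q, "")[[1]]
    m <- length(qc)
    for (sid in names(genome)) {
      gc <- strsplit(genome[[sid]], "")[[1]]
      L <- length(gc)
      if (L < m) next
      for (off in 0:(L - m)) {
        mm <- sum(gc[(off + 1):(off + m)] != qc)
        if (mm <= max_mismatches)
          out[[length(out) + 1L]] <- data.frame(
            seq_id = sid, start = off, end = off + m, strand = strand,
            mismatches = mm, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(seq_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# independent Nussinov-style DP (memoised recursion, R implementation):
# maximum number of pairs under min hairpin loop 3 and helix length >= 2
oracle_maxpair <- function(seq) {
  s <- strsplit(chartr("T", "U", toupper(seq)), "")[[1]]
  n <- length(s)
  can <- function(i, j) {
    p <- paste0(s[i], s[j])
    p %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  }
  memoW <- new.env(); memoH <- new.env()
  H <- function(i, j) { # best with helix of >=2 pairs closing (i,j)
    key <- paste(i, j)
    if (!is.null(v <- get0(key, memoH))) return(v)
    best <- -Inf
    hmax <- (j - i - 2) %/% 2
    if (hmax >= 2 && can(i, j)) {
      ok <- TRUE
      for (h in 2:hmax) {
        for (d in 0:(h - 1)) if (!can(i + d, j - d)) { ok <- FALSE; break }
        if (!ok) break
        best <- max(best, h + W(i + h, j - h))
      }
    }
    assign(key, best, memoH)
    best
  }
  W <- function(i, j) {
    if (j - i + 1 < 7) return(0)
    key <- paste(i, j)
    if (!is.null(v <- get0(key, memoW))) return(v)
    best <- W(i + 1, j)
    for (k in (i + 6):j) {
      hk <- H(i, k)
      if (is.finite(hk)) best <- max(best, hk + W(k + 1, j))
    }
    assign(key, best, memoW)
    best
  }
  if (n < 7) return(0)
  W(1, n)
}

# independent stacking-energy optimum (same recursion, energy objective,
# +3 hairpin-loop initiation penalty)
oracle_min_energy <- function(seq) {
  s <- strsplit(chartr("T", "U", toupper(seq)), "")[[1]]
  n <- length(s)
  wt <- function(i, j) {
    p <- paste0(s[i], s[j])
    if (p %in% c("GC", "CG")) return(1.8)
    if (p %in% c("AU", "UA")) return(1.0)
    if (p %in% c("GU", "UG")) return(0.6)
    0
  }
  can <- function(i, j) wt(i, j) > 0
  memoW <- new.env(); memoH <- new.env()
  H <- function(i, j) {
    key <- paste(i, j)
    if (!is.null(v <- get0(key, memoH))) return(v)
    best <- -Inf
    hmax <- (j - i - 2) %/% 2
    if (hmax >= 2 && can(i, j)) {
      ok <- TRUE
      for (h in 2:hmax) {
        for (d in 0:(h - 1)) if (!can(i + d, j - d)) { ok <- FALSE; break }
        if (!ok) break
        sc <- 0
        for (d in 0:(h - 2))
          sc <- sc + (wt(i + d, j - d) + wt(i + d + 1, j - d - 1)) / 2
        inner <- W(i + h, j - h)
        best <- max(best, sc + if (inner > 0) inner else -3)
      }
    }
    assign(key, best, memoH)
    best
  }
  W <- function(i, j) {
    if (j - i + 1 < 7) return(0)
    key <- paste(i, j)
    if (!is.null(v <- get0(key, memoW))) return(v)
    best <- W(i + 1, j)
    for (k in (i + 6):j) {
      hk <- H(i, k)
      if (is.finite(hk)) best <- max(best, hk + W(k + 1, j))
    }
    assign(key, best, memoW)
    best
  }
  if (n < 7) return(0)
  -W(1, n)
}

# AUC by the rank-statistic (Mann-Whitney with mid-ranks)
oracle_auc_rank <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == -1]
  r <- rank(c(pos, neg))
  u <- sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2
  u / (length(pos) * length(neg))
}

# naive substring scan
oracle_substring_ids <- function(query, reads, both = TRUE) {
  qs <- if (both) c(query, oracle_revcomp(query)) else query
  hit <- vapply(reads, function(r) {
    any(vapply(qs, function(q) {
      m <- nchar(q); L <- nchar(r)
      if (m > L) return(FALSE)
      any(vapply(0:(L - m), function(o)
        substr(r, o + 1, o + m) == q, logical(1)))
    }, logical(1)))
  }, logical(1))
  names(reads)[hit]
}

# small deterministic XOR data set
make_xor <- function(n_per_arm = 30, noise = 0.15, seed = 3) {
  set.seed(seed)
  centers <- rbind(c(1, 1), c(-1, -1), c(1, -1), c(-1, 1))
  X <- do.call(rbind, lapply(1:4, function(k)
    cbind(rnorm(n_per_arm, centers[k, 1], noise),
          rnorm(n_per_arm, centers[k, 2], noise))))
  y <- rep(c(1, 1, -1, -1), each = n_per_arm)
  list(X = X, y = y)
}

write_tmp_fasta <- function(seqs, dir = tempdir()) {
  path <- tempfile(fileext = ".fa", tmpdir = dir)
  con <- file(path, "w")
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    writeLines(seqs[[i]], con)
  }
  close(con)
  path
}
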