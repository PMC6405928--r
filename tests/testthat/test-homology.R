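test_that("word index finds exact word positions on the forward strand", {
  g <- c(chr = "ACGTACGT")
  idx <- build_word_index(g, word_len = 4)
  hits <- lookup_word(idx, "ACGT")
  expect_equal(sort(hits$pos), c(0L, 4L))
  expect_equal(nrow(lookup_word(idx, "TTTT")), 0L)
  expect_error(build_word_index(g, 3), class = "premirscan_config_error")
})

test_that("palindrome-aware strand handling matches brute force", {
  g <- c(chr = "ACGTACGT")
  idx <- build_word_index(g, 4)
  hits <- seed_and_extend("ACGT", idx, g, max_mismatches = 0)
  oracle <- oracle_hamming_scan("ACGT", g, 0)
  expect_equal(nrow(hits), nrow(oracle))
  expect_equal(sum(hits$strand == "-"), sum(oracle$strand == "-"))
})

test_that("planted exact and mutated copies are found with correct counts", {
  set.seed(7)
  bg <- rand_dna(2000)
  q <- rand_dna(21)
  g <- c(chr = paste0(substr(bg, 1, 1000), q, substr(bg, 1001, 2000)))
  idx <- build_word_index(g, 7)
  hits <- seed_and_extend(q, idx, g, 4)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$mismatches, 0L)
  expect_equal(hits$start, 1000L)
  expect_equal(hits$score, 21)
  # 3 scattered substitutions leaving a 7-mer intact
  qc <- strsplit(q, "")[[1]]
  for (p in c(2, 10, 18)) qc[p] <- setdiff(c("A","C","G","T"), qc[p])[1]
  q3 <- paste(qc, collapse = "")
  hits3 <- seed_and_extend(q3, idx, g, 4)
  ora <- oracle_hamming_scan(q3, g, 4)
  expect_equal(nrow(hits3), nrow(ora))
  expect_true(any(hits3$start == 1000 & hits3$mismatches == 3))
  # 6 substitutions: outside the published budget, not reported
  for (p in c(4, 7, 13, 21, 15, 11)) qc[p] <- setdiff(c("A","C","G","T"), qc[p])[1]
  q6 <- paste(qc, collapse = "")
  hits6 <- seed_and_extend(q6, idx, g, 4)
  expect_false(any(hits6$start == 1000))
})

test_that("seed-and-extend equals exhaustive Hamming scan (oracle property)", {
  set.seed(11)
  for (rep in 1:12) {
    g <- c(chr = rand_dna(sample(2000:4000, 1)))
    q <- rand_dna(21)
    idx <- build_word_index(g, 7)
    got <- seed_and_extend(q, idx, g, 2) # <=2 mismatches: pigeonhole-complete
    ora <- oracle_hamming_scan(q, g, 2)
    key <- function(d) if (nrow(d)) sort(paste(d$seq_id, d$start, d$strand,
                                               d$mismatches)) else character(0)
    expect_identical(key(got), key(ora))
    # exhaustive mode agrees at any budget
    ex <- exhaustive_scan(q, g, 4)
    ora4 <- oracle_hamming_scan(q, g, 4)
    expect_identical(key(ex), key(ora4))
  }
})

test_that("hits never cross boundaries and minus hits revcomp-verify", {
  set.seed(5)
  g <- c(a = rand_dna(500), b = rand_dna(300))
  q <- substr(revcomp(substr(g[["b"]], 101, 121)), 1, 21)
  idx <- build_word_index(g, 7)
  hits <- seed_and_extend(q, idx, g, 2)
  expect_true(all(hits$start >= 0))
  for (i in seq_len(nrow(hits))) {
    L <- nchar(g[[hits$seq_id[i]]])
    expect_lte(hits$end[i], L)
    sub <- substr(g[[hits$seq_id[i]]], hits$start[i] + 1, hits$end[i])
    qq <- if (hits$strand[i] == "+") q else revcomp(q)
    mm <- sum(strsplit(sub, "")[[1]] != strsplit(qq, "")[[1]])
    expect_equal(mm, hits$mismatches[i])
  }
})

test_that("select_hits applies the <5-mismatch and top-10 rules", {
  mk <- function(mms) data.frame(
    query_id = "q", seq_id = "c", start = seq_along(mms) * 30L,
    end = seq_along(mms) * 30L + 21L, strand = "+", mismatches = mms,
    aligned_len = 21L, score = 21 - 2 * mms, rank = NA_integer_,
    stringsAsFactors = FALSE)
  h12 <- mk(c(0, 0, 1, 1, 2, 2, 2, 3, 3, 4, 4, 4))
  kept <- select_hits(h12, top_k = 10, max_mismatches_exclusive = 5)
  expect_equal(nrow(kept), 10L)
  expect_equal(kept$rank, 1:10)
  h5 <- mk(rep(5, 4))
  expect_equal(nrow(select_hits(h5)), 0L)
  h3 <- mk(c(0, 1, 2))
  expect_equal(nrow(select_hits(h3)), 3L)
})

test_that("scan_homology ranks per query without gaps", {
  set.seed(13)
  g <- c(chr = rand_dna(3000))
  q1 <- substr(g[["chr"]], 501, 521)
  qs <- c(mirA = q1, mirB = rand_dna(21))
  hits <- scan_homology(g, qs)
  for (qid in unique(hits$query_id)) {
    r <- hits$rank[hits$query_id == qid]
    expect_equal(r, seq_along(r))
  }
  expect_true(any(hits$query_id == "mirA" & hits$start == 500 &
                    hits$mismatches == 0))
})

test_that("BLAST outfmt-6 adapter maps records to the ungapped hit model", {
  p <- tempfile()
  # qseqid sseqid pident length mismatch gapopen qstart qend sstart send e bit
  writeLines(c(
    "q1\tchr1\t100.00\t21\t0\t0\t1\t21\t101\t121\t1e-5\t42.1",
    "q1\tchr1\t90.48\t21\t2\t0\t1\t21\t221\t201\t1e-3\t33.2", # minus strand
    "q1\tchr1\t95.00\t20\t1\t0\t2\t21\t301\t320\t1e-4\t38.0", # partial: drop
    "q1\tchr1\t90.00\t21\t1\t1\t1\t21\t401\t421\t1e-4\t38.0", # gapped: drop
    "qX\tchr1\t100.00\t21\t0\t0\t1\t21\t501\t521\t1e-5\t42.1" # unknown query
  ), p)
  hits <- read_blast_tab(p, c(q1 = 21L))
  expect_equal(nrow(hits), 2L)
  plus <- hits[hits$strand == "+", ]
  expect_equal(plus$start, 100L)
  expect_equal(plus$end, 121L)
  expect_equal(plus$mismatches, 0L)
  minus <- hits[hits$strand == "-", ]
  expect_equal(minus$start, 200L)
  expect_equal(minus$end, 221L)
  expect_equal(minus$mismatches, 2L)
  expect_error(read_blast_tab(tempfile(), c(q1 = 21L)),
               class = "premirscan_data_error")
})
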