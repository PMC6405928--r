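test_that("canonical folds: perfect hairpin, unpairable sequence", {
  f <- fold_rna("GGGGGAAAAACCCCC")
  expect_identical(f$dotbracket, "(((((.....)))))")
  expect_lt(f$mfe, 0)
  f0 <- fold_rna(strrep("A", 15))
  expect_identical(f0$dotbracket, strrep(".", 15))
  expect_equal(f0$mfe, 0)
  expect_error(fold_rna("ACGT"), class = "premirscan_config_error")
})

test_that("maxpair backend matches the independent Nussinov oracle", {
  set.seed(21)
  for (rep in 1:20) {
    s <- rand_dna(sample(15:40, 1))
    f <- fold_rna(s, backend = "maxpair")
    n_bp <- sum(strsplit(f$dotbracket, "")[[1]] == "(")
    expect_equal(n_bp, oracle_maxpair(s), info = s)
  }
})

test_that("reference backend reaches the independent energy optimum", {
  set.seed(22)
  for (rep in 1:15) {
    s <- rand_dna(sample(15:40, 1))
    f <- fold_rna(s, backend = "reference")
    expect_equal(f$mfe, oracle_min_energy(s), tolerance = 1e-9, info = s)
  }
})

test_that("fixture backend reproduces recorded folds; rnafold errors clearly", {
  tab <- data.frame(id = "h1", seq = "GGGGGAAAAACCCCC",
                    dotbracket = "(((((.....)))))", mfe = -7.2,
                    stringsAsFactors = FALSE)
  f <- fold_rna("GGGGGAAAAACCCCC", backend = "fixture", fixture_table = tab)
  expect_identical(f$dotbracket, tab$dotbracket)
  expect_equal(f$mfe, -7.2)
  expect_error(fold_rna("GGGGGAAAAACCCCC", backend = "fixture"),
               class = "premirscan_config_error")
  if (!nzchar(Sys.which("RNAfold")))
    expect_error(fold_rna("GGGGGAAAAACCCCC", backend = "rnafold"),
                 "RNAfold", class = "premirscan_config_error")
})

test_that("bracket parsing round-trips and rejects garbage", {
  dbs <- c("(((((.....)))))", "((..((....))..))", "((...))((...))",
           "..((((...))))..")
  for (db in dbs)
    expect_identical(dotbracket_from_pairs(pairs_from_dotbracket(db)), db)
  expect_error(pairs_from_dotbracket("(()"), class = "premirscan_format_error")
  expect_error(pairs_from_dotbracket("a.b"), class = "premirscan_format_error")
})

test_that("hairpin metrics: worked bracket examples", {
  m1 <- hairpin_metrics(strrep("A", 16), "((((((....))))))")
  expect_equal(m1$n_bp, 6L)
  expect_equal(m1$stem_len, 6L)
  expect_equal(m1$n_hairpin_loops, 1L)
  expect_equal(m1$terminal_loop_len, 4L)
  # bridged 2-nt internal loop: two helices, one stem of 4 bp
  m2 <- hairpin_metrics(strrep("A", 16), "((..((....))..))")
  expect_equal(m2$n_bp, 4L)
  expect_equal(m2$n_stems, 2L)
  expect_equal(m2$stem_len, 4L)
  expect_equal(m2$n_hairpin_loops, 1L)
  # two hairpins
  m3 <- hairpin_metrics(strrep("A", 14), "((...))((...))")
  expect_equal(m3$n_hairpin_loops, 2L)
  expect_false(passes_filter(m3)$pass)
  expect_true("single_hairpin" %in% passes_filter(m3)$failed)
})

test_that("gc_percent arithmetic and N handling", {
  expect_equal(gc_percent("ATGC"), 50)
  expect_equal(gc_percent("GGCC"), 100)
  expect_equal(gc_percent("ATAT"), 0)
  expect_equal(gc_percent("GCNN"), 50) # N in denominator only
})

test_that("filter boundaries are inclusive on all three ranges", {
  mk <- function(stem, gc, mfe)
    list(n_bp = stem, n_stems = 1L, n_hairpin_loops = 1L, stem_len = stem,
         terminal_loop_len = 5L, gc_percent = gc, mfe = mfe, length = 100L)
  grid <- expand.grid(stem = c(19, 20, 50, 51), gc = c(23.9, 24, 82, 82.1),
                      mfe = c(-19.9, -20, -60, -60.1))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    res <- passes_filter(mk(g$stem, g$gc, g$mfe))
    want <- g$stem >= 20 && g$stem <= 50 && g$gc >= 24 && g$gc <= 82 &&
      g$mfe >= -60 && g$mfe <= -20
    expect_equal(res$pass, want, info = paste(g, collapse = "/"))
    if (!want) expect_gt(length(res$failed), 0)
  }
  expect_error(filter_config(stem_min = 30, stem_max = 10),
               class = "premirscan_config_error")
})

test_that("filter is monotone under range widening", {
  set.seed(23)
  for (rep in 1:60) {
    m <- list(n_bp = sample(0:60, 1), n_stems = sample(1:5, 1),
              n_hairpin_loops = sample(1:3, 1), stem_len = sample(0:60, 1),
              terminal_loop_len = sample(3:10, 1),
              gc_percent = runif(1, 0, 100), mfe = runif(1, -80, 0),
              length = 100L)
    base <- filter_config()
    wide <- filter_config(stem_min = base$stem_min - sample(0:5, 1),
                          stem_max = base$stem_max + sample(0:5, 1),
                          gc_min = base$gc_min - runif(1, 0, 5),
                          gc_max = base$gc_max + runif(1, 0, 5),
                          mfe_min = base$mfe_min - runif(1, 0, 10),
                          mfe_max = base$mfe_max + runif(1, 0, 10))
    if (passes_filter(m, base)$pass) expect_true(passes_filter(m, wide)$pass)
  }
})

test_that("fixture backend accepts a recorded TSV path", {
  p <- tempfile(fileext = ".tsv")
  write.table(data.frame(id = "h1", seq = "GGGGGAAAAACCCCC",
                         dotbracket = "(((((.....)))))", mfe = -7.2),
              p, sep = "\t", quote = FALSE, row.names = FALSE)
  f <- fold_rna("GGGGGAAAAACCCCC", backend = "fixture", fixture_table = p)
  expect_identical(f$dotbracket, "(((((.....)))))")
  expect_equal(f$mfe, -7.2)
})
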