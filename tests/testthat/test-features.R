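test_that("catalog has >= 100 uniquely named features in fixed order", {
  cat1 <- feature_catalog()
  expect_gte(nrow(cat1), 100)
  expect_false(anyDuplicated(cat1$name) > 0)
  expect_identical(cat1$name, feature_catalog()$name)
  expect_true(all(cat1$family %in%
                    c("COMP", "TRIPLET", "MFE_DERIVED", "TOPOLOGY",
                      "NORMALIZED")))
  expect_match(catalog_hash(cat1), "^fc[0-9]+$")
})

test_that("feature vector: homopolymer guards and compositional sums", {
  s <- strrep("A", 40)
  v <- compute_features(s, fold_rna(s))
  expect_equal(unname(v["freq_A"]), 1)
  expect_equal(unname(v["gc_percent"]), 0)
  expect_equal(unname(v["n_bp"]), 0)
  expect_equal(unname(v["MFEI1"]), 0) # guarded division
  expect_equal(unname(v["MFEI4"]), 0)
  set.seed(31)
  for (rep in 1:10) {
    s <- rand_dna(sample(60:120, 1))
    v <- compute_features(s, fold_rna(s))
    mono <- paste0("freq_", c("A", "C", "G", "U"))
    di <- paste0("freq_", as.vector(outer(c("A","C","G","U"),
                                          c("A","C","G","U"), paste0)))
    expect_equal(sum(v[mono]), 1, tolerance = 1e-9)
    expect_equal(sum(v[di]), 1, tolerance = 1e-9)
    expect_equal(sum(v[grepl("^triplet_", names(v))]), 1, tolerance = 1e-9)
    expect_true(all(is.finite(v)))
  }
})

test_that("AMFE and MFEI identities hold against direct arithmetic", {
  hp <- make_hairpin(77, arm_len = 30, loop_len = 8)
  f <- fold_rna(hp$seq)
  v <- compute_features(hp$seq, f)
  m <- hairpin_metrics(hp$seq, f)
  L <- nchar(hp$seq)
  expect_equal(unname(v["AMFE"]), 100 * f$mfe / L, tolerance = 1e-9)
  expect_equal(unname(v["MFEI1"]), (100 * f$mfe / L) / m$gc_percent,
               tolerance = 1e-9)
  expect_equal(unname(v["MFEI4"]), f$mfe / m$n_bp, tolerance = 1e-9)
  expect_equal(unname(v["dP"]), m$n_bp / L, tolerance = 1e-9)
})

test_that("feature computation is a pure function (byte-identical repeats)", {
  s <- make_hairpin(5, arm_len = 24, loop_len = 6)$seq
  f <- fold_rna(s)
  expect_identical(compute_features(s, f), compute_features(s, f))
})

test_that("select_features keeps informative features, drops constants", {
  set.seed(7)
  n <- 200
  X <- matrix(rnorm(2 * n * 100), ncol = 100)
  y <- rep(c(1, -1), each = n)
  for (j in 1:10) X[y == 1, j] <- X[y == 1, j] + 2 # 2-sigma shift
  X[, 100] <- 1 # constant
  colnames(X) <- sprintf("f%03d", 1:100)
  sel <- select_features(X, y)
  expect_true(all(sel$keep[1:10]))
  expect_false(sel$keep[100])
  expect_equal(sel$report$p[100], 1)
  expect_lte(sum(sel$keep[11:99]), 5)
  # order preserved
  expect_identical(sel$report$feature, colnames(X))
  expect_error(select_features(X[1:30, ], y[1:30]),
               class = "premirscan_data_error")
})

test_that("null calibration: permuted labels keep few features", {
  set.seed(19)
  kept <- replicate(20, {
    X <- matrix(rnorm(60 * 40), ncol = 40)
    y <- rep(c(1, -1), each = 30)[sample.int(60)]
    sum(select_features(X, y)$keep)
  })
  # BH at FDR 0.05 under the global null keeps ~0 features almost always
  expect_lte(mean(kept), 2)
})

test_that("negative set construction: reproducible, filtered, attrition", {
  set.seed(41)
  cds <- character(0)
  for (i in 1:4) {
    parts <- character(0)
    for (j in 1:6) {
      parts <- c(parts, make_orf(90),
                 premirscan:::make_pseudo_hairpin(i * 50 + j,
                                                 arm_len = 30)$seq)
    }
    cds[sprintf("cds%d", i)] <- paste(parts, collapse = "")
  }
  neg <- build_negative_set(cds, n_required = 20, seed = 1)
  expect_length(neg$seqs, 20)
  for (k in seq_along(neg$seqs)) {
    f <- fold_rna(neg$seqs[[k]])
    expect_true(passes_filter(hairpin_metrics(neg$seqs[[k]], f))$pass)
  }
  neg2 <- build_negative_set(cds, n_required = 20, seed = 1)
  expect_identical(names(neg$seqs), names(neg2$seqs))
  # hairpin-free input errors with an attrition table
  plain <- c(x = strrep("ACT", 200))
  err <- tryCatch(build_negative_set(plain, 5, seed = 1),
                  premirscan_data_error = function(e) conditionMessage(e))
  expect_match(err, "stem=")
})

test_that("scaler maps train extrema to [0, 100] and never refits", {
  set.seed(53)
  X <- matrix(rnorm(50 * 4), ncol = 4)
  sc <- fit_scaler(X)
  Xs <- apply_scaler(sc, X)
  expect_equal(unname(apply(Xs, 2, min)), rep(0, 4))
  expect_equal(unname(apply(Xs, 2, max)), rep(100, 4))
  held <- matrix(rnorm(10 * 4, 5), ncol = 4)
  before <- unclass(sc)
  out1 <- apply_scaler(sc, held)
  expect_identical(unclass(sc), before) # pure function, no leakage
  expect_true(any(out1 > 100)) # out-of-range stays out of range
})
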