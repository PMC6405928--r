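test_that("perfect and coin-flip confusion matrices", {
  p <- confusion_metrics(50, 0, 50, 0)
  for (mtr in c("TPR", "TNR", "PPV", "NPV", "ACC", "F1", "MCC"))
    expect_equal(p[[mtr]], 1)
  for (mtr in c("FPR", "FNR", "FDR")) expect_equal(p[[mtr]], 0)
  q <- confusion_metrics(25, 25, 25, 25)
  expect_equal(q$ACC, 0.5)
  expect_equal(q$MCC, 0)
  expect_equal(q$informedness, 0)
  expect_error(confusion_metrics(0, 0, 0, 0), class = "premirscan_data_error")
})

test_that("0/0 ratios are flagged undefined and reported as 0", {
  m <- confusion_metrics(0, 0, 10, 0) # no positives anywhere
  expect_equal(m$TPR, 0)
  expect_true(all(c("TPR", "PPV") %in% m$undefined))
})

test_that("metric identity suite on random confusion matrices", {
  set.seed(71)
  for (rep in 1:2000) {
    v <- sample(0:200, 4, replace = TRUE)
    if (sum(v) == 0) next
    m <- confusion_metrics(v[1], v[2], v[3], v[4])
    expect_equal(m$informedness, m$TPR + m$TNR - 1, tolerance = 1e-12)
    expect_equal(m$markedness, m$PPV + m$NPV - 1, tolerance = 1e-12)
    if (!"FDR" %in% m$undefined && !"PPV" %in% m$undefined)
      expect_equal(m$FDR, 1 - m$PPV, tolerance = 1e-12)
    if (!"FNR" %in% m$undefined && !"TPR" %in% m$undefined)
      expect_equal(m$FNR, 1 - m$TPR, tolerance = 1e-12)
    if (!"FPR" %in% m$undefined && !"TNR" %in% m$undefined)
      expect_equal(m$FPR, 1 - m$TNR, tolerance = 1e-12)
    den <- sqrt(v[1] + v[2]) * sqrt(v[1] + v[4]) * sqrt(v[3] + v[2]) *
      sqrt(v[3] + v[4])
    if (den > 0)
      expect_equal(m$MCC, (v[1] * v[3] - v[2] * v[4]) / den,
                   tolerance = 1e-12)
    expect_true(m$MCC >= -1 - 1e-12 && m$MCC <= 1 + 1e-12)
  }
})

test_that("f_measure is the harmonic mean and matches counts-based F1", {
  expect_equal(f_measure(0.5, 0.5), 0.5)
  expect_equal(f_measure(0, 0), 0)
  m <- confusion_metrics(40, 10, 35, 15)
  expect_equal(f_measure(m$PPV, m$TPR), m$F1, tolerance = 1e-12)
})

test_that("ROC endpoints, perfect and degenerate orderings", {
  r <- roc_auc(c(5, 4, 3, 2, 1), c(1, 1, 1, -1, -1))
  expect_equal(r$auc, 1)
  expect_equal(r$points$fpr[1], 0)
  expect_equal(r$points$tpr[1], 0)
  expect_equal(r$points$fpr[nrow(r$points)], 1)
  expect_equal(r$points$tpr[nrow(r$points)], 1)
  expect_true(all(diff(r$points$fpr) >= 0))
  tied <- roc_auc(rep(1, 10), rep(c(1, -1), 5))
  expect_equal(tied$auc, 0.5) # one diagonal trapezoid
  expect_error(roc_auc(1:4, rep(1, 4)), class = "premirscan_data_error")
})

test_that("trapezoidal AUC equals the mid-rank Mann-Whitney statistic", {
  set.seed(3)
  for (rep in 1:30) {
    n <- 200
    labels <- rep(c(1, -1), each = n / 2)
    scores <- if (rep %% 3 == 0) sample(1:20, n, replace = TRUE) # heavy ties
              else rnorm(n) + 0.5 * (labels == 1)
    expect_equal(roc_auc(scores, labels)$auc,
                 oracle_auc_rank(scores, labels), tolerance = 1e-12)
  }
})

test_that("stratified CV: disjoint covering folds, determinism", {
  cl <- make_feature_cloud(50, dim = 4, shift = 4, seed = 2)
  cv <- cross_validate(cl$X, cl$y, k = 5, seed = 7)
  f <- cv$fold_assignment
  expect_equal(sort(unique(f)), 1:5)
  expect_equal(as.integer(table(f)), rep(20L, 5))
  for (fi in 1:5) # stratification: 10 per class in each fold
    expect_equal(as.integer(table(cl$y[f == fi])), c(10L, 10L))
  cv2 <- cross_validate(cl$X, cl$y, k = 5, seed = 7)
  expect_identical(cv$fold_assignment, cv2$fold_assignment)
  expect_equal(cv$summary$mean, cv2$summary$mean, tolerance = 1e-12)
})

test_that("comparison report has the published column layout", {
  cl <- make_feature_cloud(30, dim = 3, shift = 5, seed = 4)
  cv <- cross_validate(cl$X, cl$y, seed = 4)
  p <- tempfile(fileext = ".tsv")
  tab <- model_comparison_report(list(`SVM-Rad` = cv), p)
  expect_identical(names(tab),
                   c("Method", "Se", "Sp", "PPV", "NPV", "Accuracy",
                     "Precision", "Recall", "F-measure", "MCC"))
  expect_match(tab$Accuracy[1], "^[01]\\.[0-9]{3} ± [0-9]\\.[0-9]{3}$")
  expect_true(file.exists(p))
  # Precision column mirrors PPV, Recall mirrors Se (as in the paper)
  expect_identical(tab$Precision, tab$PPV)
  expect_identical(tab$Recall, tab$Se)
})
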