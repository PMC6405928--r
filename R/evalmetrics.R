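# Confusion-matrix metrics (the twelve published formulas), trapezoidal
# ROC/AUC, stratified k-fold cross-validation and comparison reports.

#' Confusion-matrix metrics
#'
#' Computes TPR (sensitivity), TNR (specificity), PPV (precision), NPV, ACC,
#' F1, MCC, FPR, FNR, FDR, informedness (TPR+TNR-1) and markedness
#' (PPV+NPV-1).  Any 0/0 ratio is reported as 0 and listed in `undefined`.
#'
#' @param TP,FP,TN,FN non-negative counts (or give `cm` as a named vector).
#' @param cm optional named vector with elements TP, FP, TN, FN.
#' @return named list of the 12 metrics plus `undefined` (character vector).
#' @export
confusion_metrics <- function(TP, FP, TN, FN, cm = NULL) {
  if (!is.null(cm)) { TP <- cm[["TP"]]; FP <- cm[["FP"]]
                      TN <- cm[["TN"]]; FN <- cm[["FN"]] }
  if (any(c(TP, FP, TN, FN) < 0)) config_error("negative confusion counts")
  if (TP + FP + TN + FN == 0) data_error("all-zero confusion matrix")
  undefined <- character(0)
  div <- function(num, den, name) {
    if (den == 0) { undefined <<- c(undefined, name); 0 } else num / den
  }
  TPR <- div(TP, TP + FN, "TPR")
  TNR <- div(TN, TN + FP, "TNR")
  PPV <- div(TP, TP + FP, "PPV")
  NPV <- div(TN, TN + FN, "NPV")
  ACC <- (TP + TN) / (TP + FP + TN + FN)
  F1 <- div(2 * TP, 2 * TP + FP + FN, "F1")
  mcc_den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  MCC <- if (mcc_den == 0) { undefined <- c(undefined, "MCC"); 0 }
         else (TP * TN - FP * FN) / mcc_den
  FPR <- div(FP, FP + TN, "FPR")
  FNR <- div(FN, TP + FN, "FNR")
  FDR <- div(FP, TP + FP, "FDR")
  list(TPR = TPR, TNR = TNR, PPV = PPV, NPV = NPV, ACC = ACC, F1 = F1,
       MCC = MCC, FPR = FPR, FNR = FNR, FDR = FDR,
       informedness = TPR + TNR - 1, markedness = PPV + NPV - 1,
       undefined = unique(undefined))
}

#' F-measure from precision and recall
#'
#' F1 = 2PR/(P+R); the harmonic-mean identity used for report consistency
#' checks.
#' @param precision,recall rates in [0,1].
#' @export
f_measure <- function(precision, recall) {
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Confusion matrix from predictions
#' @param pred,truth vectors in {-1, +1}.
#' @export
confusion_counts <- function(pred, truth) {
  c(TP = sum(pred == 1 & truth == 1), FP = sum(pred == 1 & truth == -1),
    TN = sum(pred == -1 & truth == -1), FN = sum(pred == -1 & truth == 1))
}

#' ROC curve and trapezoidal AUC
#'
#' Thresholds sweep the distinct score values in descending order (tied
#' scores are grouped, producing one diagonal segment, equivalent to
#' mid-rank handling of the Mann-Whitney statistic).  The curve runs from
#' (0,0) to (1,1); AUC is the trapezoidal sum over consecutive points.
#'
#' @param scores numeric decision scores (larger = more positive).
#' @param labels vector in {-1, +1} with both classes present.
#' @return list of class `roc_curve`: points (data.frame fpr, tpr,
#'   threshold) and auc.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (!all(labels %in% c(-1, 1)) || length(unique(labels)) < 2)
    data_error("roc_auc needs both classes in {-1,+1}")
  np <- sum(labels == 1); nn <- sum(labels == -1)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  uniq <- !duplicated(s)
  grp <- cumsum(uniq)
  tp <- cumsum(l == 1); fp <- cumsum(l == -1)
  last <- which(!duplicated(grp, fromLast = TRUE)) # last index of each group
  pts <- data.frame(fpr = c(0, fp[last] / nn), tpr = c(0, tp[last] / np),
                    threshold = c(Inf, s[last]))
  auc <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + diff(pts$tpr) / 2))
  structure(list(points = pts, auc = auc), class = "roc_curve")
}

# stratified fold assignment: within each class, seeded shuffle then
# round-robin fold labels
stratified_folds <- function(y, k, seed) {
  set.seed(as.integer(seed))
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Stratified k-fold cross-validation of the SVM
#'
#' Seeded stratified fold assignment; the scaler and model are fitted on
#' each training fold only.  Per-fold metrics and a mean +/- sd summary are
#' returned; `scores`/`labels` pool the held-out decision values for ROC.
#'
#' @param X feature matrix; `y` labels in {-1,+1}.
#' @param spec,C,cost_factor SVM configuration (see [svm_train()]).
#' @param k number of folds (default 5).
#' @param seed RNG seed for the fold shuffle.
#' @return list: folds (list of metric lists), summary (data.frame metric,
#'   mean, sd), scores, labels, auc.
#' @export
cross_validate <- function(X, y, spec = kernel_spec(), C = 5, cost_factor = 3,
                           k = 5L, seed = 1L) {
  X <- as.matrix(X); y <- as.numeric(y)
  if (k < 2) config_error("k must be >= 2")
  if (min(table(y)) < k)
    data_error("need at least k members per class for stratified CV")
  fold <- stratified_folds(y, k, seed)
  per <- vector("list", k)
  scores <- numeric(length(y))
  for (f in seq_len(k)) {
    tr <- fold != f; te <- !tr
    m <- svm_train(X[tr, , drop = FALSE], y[tr], spec = spec, C = C,
                   cost_factor = cost_factor, seed = seed)
    sc <- svm_decision(m, X[te, , drop = FALSE])
    scores[te] <- sc
    pred <- ifelse(sc > 0, 1, -1)
    per[[f]] <- confusion_metrics(cm = confusion_counts(pred, y[te]))
  }
  metric_names <- c("TPR", "TNR", "PPV", "NPV", "ACC", "F1", "MCC", "FPR",
                    "FNR", "FDR", "informedness", "markedness")
  tab <- sapply(metric_names, function(mn)
    vapply(per, function(p) p[[mn]], numeric(1)))
  summary <- data.frame(metric = metric_names,
                        mean = colMeans(tab),
                        sd = apply(tab, 2, sd),
                        stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  list(folds = per, summary = summary, scores = scores, labels = y,
       auc = roc_auc(scores, y)$auc, fold_assignment = fold)
}

#' Side-by-side model comparison table
#'
#' One row per named CV result, columns in the published order (Se, Sp, PPV,
#' NPV, Accuracy, Precision, Recall, F-measure, MCC), formatted as
#' "mean +/- sd" at 3 decimals.  Written as TSV when `path` is given.
#'
#' @param results named list of [cross_validate()] results.
#' @param path optional output TSV path.
#' @export
model_comparison_report <- function(results, path = NULL) {
  stopifnot(length(results) >= 1)
  cols <- c(Se = "TPR", Sp = "TNR", PPV = "PPV", NPV = "NPV",
            Accuracy = "ACC", Precision = "PPV", Recall = "TPR",
            `F-measure` = "F1", MCC = "MCC")
  rows <- lapply(names(results), function(nm) {
    s <- results[[nm]]$summary
    vals <- vapply(cols, function(m) {
      i <- match(m, s$metric)
      sprintf("%.3f ± %.3f", s$mean[i], s$sd[i])
    }, character(1))
    c(Method = nm, vals)
  })
  tab <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(tab) <- c("Method", names(cols))
  if (!is.null(path))
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  tab
}
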