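# Per-candidate feature vectors, significance-based feature selection and
# the CDS-derived negative training set.
#
# The published pipeline computes 152 precursor features (the miPlantPremat
# catalog) and keeps the 107 found significant; the exact list is not
# printed, so the default catalog here is an explicit reconstruction of the
# same families (sequence composition, paired/unpaired triplet elements,
# MFE-derived indices, hairpin topology, length-normalised topology), fully
# documented and replaceable by users holding the original list.

NUCS <- c("A", "C", "G", "U")

#' The default feature catalog
#'
#' 133 named features in five families:
#' \describe{
#'   \item{COMP (85)}{4 mononucleotide, 16 dinucleotide and 64 trinucleotide
#'     frequencies (each group sums to 1) plus GC percent.}
#'   \item{TRIPLET (32)}{triplet elements: for each interior position, the
#'     pairing pattern of the 3-nt window (paired/unpaired, 8 patterns)
#'     combined with the centre nucleotide; frequencies over all windows.}
#'   \item{MFE_DERIVED (6)}{MFE, AMFE = 100*MFE/len, MFEI1 = AMFE/GC%,
#'     MFEI2 = MFE/n_stems, MFEI3 = MFE/n_hairpin_loops, MFEI4 = MFE/n_bp.}
#'   \item{TOPOLOGY (6)}{n_bp, n_stems, n_hairpin_loops, stem_len,
#'     terminal_loop_len, dP = n_bp/len.}
#'   \item{NORMALIZED (4)}{n_stems/len, n_hairpin_loops/len, stem_len/len,
#'     terminal_loop_len/len.}
#' }
#' Zero denominators yield feature value 0 (guarded division).
#'
#' @return data.frame of class `feature_catalog` with columns name, family,
#'   formula.
#' @export
feature_catalog <- function() {
  mono <- paste0("freq_", NUCS)
  di <- paste0("freq_", as.vector(outer(NUCS, NUCS, paste0)))
  tri <- paste0("freq_", as.vector(outer(as.vector(outer(NUCS, NUCS, paste0)),
                                         NUCS, paste0)))
  pat <- c("...", "..(", ".(.", "(..", ".((", "(.(", "((.", "(((")
  triplet <- as.vector(t(outer(NUCS, pat, function(n, p) paste0(n, p))))
  mfe <- c("MFE", "AMFE", "MFEI1", "MFEI2", "MFEI3", "MFEI4")
  topo <- c("n_bp", "n_stems", "n_hairpin_loops", "stem_len",
            "terminal_loop_len", "dP")
  norm <- c("n_stems_per_nt", "n_hairpin_loops_per_nt", "stem_len_per_nt",
            "terminal_loop_per_nt")
  cat <- data.frame(
    name = c(mono, di, tri, "gc_percent", paste0("triplet_", triplet),
             mfe, topo, norm),
    family = c(rep("COMP", length(mono) + length(di) + length(tri) + 1L),
               rep("TRIPLET", length(triplet)),
               rep("MFE_DERIVED", length(mfe)),
               rep("TOPOLOGY", length(topo)),
               rep("NORMALIZED", length(norm))),
    stringsAsFactors = FALSE)
  cat$formula <- cat$name
  class(cat) <- c("feature_catalog", class(cat))
  cat
}

#' Stable hash of a feature catalog
#'
#' Polynomial rolling hash over the ordered feature names; models refuse to
#' score vectors produced under a different catalog.
#' @param catalog a [feature_catalog()].
#' @export
catalog_hash <- function(catalog) {
  s <- paste(catalog$name, collapse = "|")
  codes <- utf8ToInt(s)
  h <- 0
  for (c in codes) h <- (h * 131 + c) %% 2147483647
  sprintf("fc%010d", h)
}

guarded_div <- function(num, den) if (!is.finite(den) || den == 0) 0 else num / den

#' Compute the feature vector of a folded candidate
#'
#' Pure function of (seq, fold, catalog); see [feature_catalog()] for the
#' feature definitions.
#'
#' @param seq nucleotide string.
#' @param fold `fold_result` (or dot-bracket string) for `seq`.
#' @param catalog a [feature_catalog()].
#' @return named numeric vector aligned to the catalog order.
#' @export
compute_features <- function(seq, fold, catalog = feature_catalog()) {
  rna <- to_rna(toupper(seq))
  ch <- strsplit(rna, "", fixed = TRUE)[[1]]
  n <- length(ch)
  m <- hairpin_metrics(seq, fold)
  db <- if (is.character(fold)) fold else fold$dotbracket

  vals <- stats::setNames(numeric(nrow(catalog)), catalog$name)

  # composition
  for (k in 1:3) {
    starts <- seq_len(max(0L, n - k + 1L))
    kms <- substring(rna, starts, starts + k - 1L)
    kms <- kms[!grepl("N", kms, fixed = TRUE)]
    tab <- table(kms)
    keys <- paste0("freq_", names(tab))
    present <- keys %in% names(vals)
    if (length(kms))
      vals[keys[present]] <- as.numeric(tab)[present] / length(kms)
  }
  vals["gc_percent"] <- m$gc_percent

  # triplet elements (centre nucleotide x 8 pairing patterns)
  if (n >= 3) {
    st <- chartr(")", "(", db)
    wins <- substring(st, seq_len(n - 2L), seq_len(n - 2L) + 2L)
    centres <- ch[seq_len(n - 2L) + 1L]
    ok <- !centres %in% "N"
    if (any(ok)) {
      keys <- paste0("triplet_", centres[ok], wins[ok])
      tab <- table(keys)
      present <- names(tab) %in% names(vals)
      vals[names(tab)[present]] <- as.numeric(tab)[present] / sum(ok)
    }
  }

  # MFE-derived
  mfe <- if (is.na(m$mfe)) 0 else m$mfe
  amfe <- guarded_div(100 * mfe, n)
  vals["MFE"] <- mfe
  vals["AMFE"] <- amfe
  vals["MFEI1"] <- guarded_div(amfe, m$gc_percent)
  vals["MFEI2"] <- guarded_div(mfe, m$n_stems)
  vals["MFEI3"] <- guarded_div(mfe, m$n_hairpin_loops)
  vals["MFEI4"] <- guarded_div(mfe, m$n_bp)

  # topology
  vals["n_bp"] <- m$n_bp
  vals["n_stems"] <- m$n_stems
  vals["n_hairpin_loops"] <- m$n_hairpin_loops
  vals["stem_len"] <- m$stem_len
  vals["terminal_loop_len"] <- m$terminal_loop_len
  vals["dP"] <- guarded_div(m$n_bp, n)

  # normalised topology
  vals["n_stems_per_nt"] <- guarded_div(m$n_stems, n)
  vals["n_hairpin_loops_per_nt"] <- guarded_div(m$n_hairpin_loops, n)
  vals["stem_len_per_nt"] <- guarded_div(m$stem_len, n)
  vals["terminal_loop_per_nt"] <- guarded_div(m$terminal_loop_len, n)

  if (any(!is.finite(vals))) data_error("non-finite feature value computed")
  vals
}

#' Feature matrix for a set of candidate sequences
#'
#' Folds each sequence (unless folds are supplied) and stacks
#' [compute_features()] rows.
#'
#' @param seqs named character vector.
#' @param folds optional list of `fold_result`s parallel to `seqs`.
#' @param catalog a [feature_catalog()].
#' @param backend folding backend (see [fold_rna()]).
#' @export
feature_matrix <- function(seqs, folds = NULL, catalog = feature_catalog(),
                           backend = "reference") {
  rows <- lapply(seq_along(seqs), function(i) {
    f <- if (is.null(folds)) fold_rna(seqs[[i]], backend = backend)
         else folds[[i]]
    compute_features(seqs[[i]], f, catalog)
  })
  X <- do.call(rbind, rows)
  rownames(X) <- names(seqs)
  X
}

#' Significance-based feature selection
#'
#' Two-sided Mann-Whitney U test per feature between the classes
#' (or Welch t-test with `method = "t"`), Benjamini-Hochberg adjusted;
#' features with adjusted p < alpha are kept in their original order.
#' Constant features get p = 1 by convention.
#'
#' @param X numeric matrix (rows = samples, columns = catalog features).
#' @param y labels in {-1, +1}.
#' @param alpha FDR level (default 0.05).
#' @param method "wilcox" (default) or "t".
#' @return list: keep (logical vector), report (data.frame with feature,
#'   statistic, p, q, keep).
#' @export
select_features <- function(X, y, alpha = 0.05, method = c("wilcox", "t")) {
  method <- match.arg(method)
  stopifnot(all(y %in% c(-1, 1)))
  if (is.null(colnames(X)))
    colnames(X) <- sprintf("feature_%03d", seq_len(ncol(X)))
  if (sum(y == 1) < 20 || sum(y == -1) < 20)
    data_error("select_features requires >= 20 members per class")
  a <- X[y == 1, , drop = FALSE]
  b <- X[y == -1, , drop = FALSE]
  res <- vapply(seq_len(ncol(X)), function(j) {
    xa <- a[, j]; xb <- b[, j]
    if (length(unique(c(xa, xb))) == 1L) return(c(stat = 0, p = 1))
    if (method == "wilcox") {
      w <- suppressWarnings(wilcox.test(xa, xb, exact = FALSE))
      c(stat = unname(w$statistic), p = w$p.value)
    } else {
      tt <- tryCatch(stats::t.test(xa, xb),
                     error = function(e) list(statistic = 0, p.value = 1))
      c(stat = unname(tt$statistic), p = tt$p.value)
    }
  }, c(stat = 0, p = 0))
  p <- res["p", ]
  p[is.na(p)] <- 1
  q <- p.adjust(p, method = "BH")
  keep <- q < alpha
  list(keep = keep,
       report = data.frame(feature = colnames(X), statistic = res["stat", ],
                           p = p, q = q, keep = keep,
                           stringsAsFactors = FALSE))
}

#' Build the CDS-derived negative training set
#'
#' Fragments coding sequences into precursor-scale windows, visits them in a
#' seeded random order, folds each and keeps the first `n_required` windows
#' passing the pseudo-miRNA filters — the published construction of the
#' negative class.
#'
#' @param cds_records named character vector of coding sequences.
#' @param n_required number of negatives wanted.
#' @param filter_cfg a [filter_config()].
#' @param sizes,step window fragmentation parameters.
#' @param seed integer RNG seed.
#' @param backend folding backend.
#' @return list: seqs (named character vector), folds (list), attrition
#'   (named counts of windows failing each criterion).
#' @export
build_negative_set <- function(cds_records, n_required,
                               filter_cfg = filter_config(),
                               sizes = c(90L, 100L, 110L, 120L), step = 10L,
                               seed = 1L, backend = "reference") {
  if (!length(cds_records)) data_error("empty CDS set")
  wins <- list()
  for (sid in names(cds_records)) {
    loc <- list(interval = genomic_interval(sid, 0L,
                                            nchar(cds_records[[sid]]), "+"),
                seq = cds_records[[sid]])
    fr <- fragment_locus(loc, sizes = sizes, step = step)
    if (nrow(fr)) wins[[length(wins) + 1L]] <- fr
  }
  wins <- do.call(rbind, wins)
  if (is.null(wins) || !nrow(wins)) data_error("CDS windows could not be cut")
  wins <- wins[!duplicated(wins$seq), , drop = FALSE]
  set.seed(as.integer(seed))
  ord <- sample.int(nrow(wins))
  out_seqs <- character(0)
  out_folds <- list()
  attrition <- c(stem = 0L, gc = 0L, mfe = 0L, single_hairpin = 0L)
  for (i in ord) {
    f <- fold_rna(wins$seq[i], backend = backend)
    met <- hairpin_metrics(wins$seq[i], f)
    pf <- passes_filter(met, filter_cfg)
    if (pf$pass) {
      id <- sprintf("neg_%s_%d_%d", wins$seq_id[i], wins$start[i], wins$end[i])
      out_seqs[id] <- wins$seq[i]
      out_folds[[id]] <- f
      if (length(out_seqs) >= n_required) break
    } else {
      attrition[pf$failed] <- attrition[pf$failed] + 1L
    }
  }
  if (length(out_seqs) < n_required)
    data_error(sprintf(
      "only %d/%d CDS windows pass the filters (failures: %s)",
      length(out_seqs), n_required,
      paste(sprintf("%s=%d", names(attrition), attrition), collapse = ", ")))
  list(seqs = out_seqs, folds = out_folds, attrition = attrition)
}

#' Fit a min-max scaler on training data
#'
#' Columns are mapped to [0, `hi`] using training minima/maxima; constant
#' columns map to 0.  The default `hi = 100` puts every feature on the
#' percent-like scale the published RBF width (gamma = 1e-4) is effective
#' on: an RBF kernel needs squared distances of order 1/gamma, and [0,1]
#' scaling would make it numerically constant.  Application to new data is
#' a pure function of the stored parameters (no leakage).
#'
#' @param X training feature matrix.
#' @param hi upper bound of the scaled range (default 100).
#' @return list(min, range, hi) of class `feature_scaler`.
#' @export
fit_scaler <- function(X, hi = 100) {
  mn <- apply(X, 2, min)
  rg <- apply(X, 2, max) - mn
  structure(list(min = mn, range = rg, hi = hi), class = "feature_scaler")
}

#' @rdname fit_scaler
#' @param scaler a fitted `feature_scaler`.
#' @param newX matrix to transform.
#' @export
apply_scaler <- function(scaler, newX) {
  newX <- as.matrix(newX)
  hi <- if (is.null(scaler$hi)) 100 else scaler$hi
  rg <- ifelse(scaler$range == 0, 1, scaler$range)
  out <- hi * sweep(sweep(newX, 2, scaler$min), 2, rg, "/")
  out[, scaler$range == 0] <- 0
  out
}
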