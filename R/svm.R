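# Class-weighted kernel SVM.
#
# Published hyperparameter mapping (SVMlight flags): g -> gamma, c -> C,
# j -> positive-class cost factor, t = 2 -> RBF kernel; defaults below are
# exactly those values (gamma 1e-4, C 5, j 3, RBF).  The dual soft-margin QP
#   max  sum(alpha) - 1/2 alpha' (yy' * K) alpha
#   s.t. sum(alpha * y) = 0,  0 <= alpha_i <= C*j (y=+1) or C (y=-1)
# is solved with quadprog; kernels, weighting, scaling, the decision rule
# and persistence are owned and tested here.

#' Kernel specification
#'
#' @param kind "linear", "polynomial", "rbf" or "sigmoid".
#' @param gamma kernel width/scale (> 0; required except for linear).
#' @param degree polynomial degree (default 3, polynomial only).
#' @param coef0 additive constant r (polynomial/sigmoid; default 0).
#' @export
kernel_spec <- function(kind = c("rbf", "linear", "polynomial", "sigmoid"),
                        gamma = 1e-4, degree = 3L, coef0 = 0) {
  kind <- match.arg(kind)
  if (kind != "linear" && (!is.numeric(gamma) || gamma <= 0))
    config_error("gamma must be > 0 for polynomial/rbf/sigmoid kernels")
  list(kind = kind, gamma = gamma, degree = as.integer(degree), coef0 = coef0)
}

#' Evaluate a kernel between two vectors
#'
#' linear: x.z; polynomial: (gamma x.z + r)^d; rbf: exp(-gamma ||x-z||^2);
#' sigmoid: tanh(gamma x.z + r).
#'
#' @param x,z numeric vectors of equal length.
#' @param spec a [kernel_spec()].
#' @export
svm_kernel <- function(x, z, spec) {
  if (length(x) != length(z)) config_error("kernel input dimension mismatch")
  switch(spec$kind,
         linear = sum(x * z),
         polynomial = (spec$gamma * sum(x * z) + spec$coef0)^spec$degree,
         rbf = exp(-spec$gamma * sum((x - z)^2)),
         sigmoid = tanh(spec$gamma * sum(x * z) + spec$coef0))
}

# full Gram matrix between rows of A and rows of B
kernel_matrix <- function(A, B, spec) {
  A <- as.matrix(A); B <- as.matrix(B)
  G <- tcrossprod(A, B)
  switch(spec$kind,
         linear = G,
         polynomial = (spec$gamma * G + spec$coef0)^spec$degree,
         sigmoid = tanh(spec$gamma * G + spec$coef0),
         rbf = {
           d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * G
           d2[d2 < 0] <- 0
           exp(-spec$gamma * d2)
         })
}

#' Train a class-weighted soft-margin kernel SVM
#'
#' Features are min-max scaled to [0,1] on the training data (the scaler is
#' stored in the model).  The positive class carries cost C*j.
#'
#' @param X numeric feature matrix (rows = samples).
#' @param y labels in {-1, +1}; both classes required.
#' @param spec a [kernel_spec()]; default RBF with gamma 1e-4.
#' @param C soft-margin cost (default 5).
#' @param cost_factor positive-class cost multiplier j (default 3).
#' @param seed recorded in metadata (training itself is deterministic).
#' @param scale fit and apply the min-max scaler (default TRUE).
#' @param catalog_hash hash of the feature catalog the columns come from.
#' @return object of class `svm_model`.
#' @export
svm_train <- function(X, y, spec = kernel_spec(), C = 5, cost_factor = 3,
                      seed = 0L, scale = TRUE, catalog_hash = NA_character_) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1)) || length(unique(y)) < 2)
    data_error("training labels must contain both +1 and -1")
  if (nrow(X) != length(y)) data_error("X/y length mismatch")
  scaler <- if (scale) fit_scaler(X) else NULL
  Xs <- if (scale) apply_scaler(scaler, X) else X
  n <- nrow(Xs)
  K <- kernel_matrix(Xs, Xs, spec)
  D <- K * tcrossprod(y)
  # jitter for strict positive definiteness (Grams are only PSD; duplicate
  # rows make them singular); escalate if the Cholesky still fails
  eps <- 1e-6 * mean(abs(diag(D)))
  if (!is.finite(eps) || eps <= 0) eps <- 1e-6
  dvec <- rep(1, n)
  Cup <- ifelse(y > 0, C * cost_factor, C)
  # constraints: sum(alpha*y)=0 (eq), alpha >= 0, -alpha >= -Cup
  Amat <- cbind(y, diag(n), -diag(n))
  bvec <- c(0, rep(0, n), -Cup)
  sol <- NULL
  for (try in 1:4) {
    sol <- tryCatch(quadprog::solve.QP(D + diag(eps, n), dvec, Amat, bvec,
                                       meq = 1),
                    error = function(e) NULL)
    if (!is.null(sol)) break
    eps <- eps * 100
  }
  if (is.null(sol)) data_error("SVM dual QP could not be solved")
  alpha <- pmin(pmax(sol$solution, 0), Cup)
  sv <- alpha > 1e-6 * max(alpha, 1)
  coefs <- alpha[sv] * y[sv]
  # bias from the KKT conditions: free SVs pin it; otherwise the midpoint of
  # the feasible interval from the bound constraints (libsvm-style rho)
  f0 <- as.vector(K[, sv, drop = FALSE] %*% coefs)
  tol <- 1e-6 * max(Cup)
  free <- alpha > tol & alpha < Cup - tol
  if (any(free)) {
    b <- mean(y[free] - f0[free])
  } else {
    at_up <- alpha >= Cup - tol
    at_lo <- alpha <= tol
    lo <- suppressWarnings(max(c((1 - f0)[y > 0 & at_lo],
                                 (-1 - f0)[y < 0 & at_up])))
    hi <- suppressWarnings(min(c((1 - f0)[y > 0 & at_up],
                                 (-1 - f0)[y < 0 & at_lo])))
    if (!is.finite(lo)) lo <- hi
    if (!is.finite(hi)) hi <- lo
    b <- (lo + hi) / 2
  }
  model <- structure(list(
    spec = spec, C = C, cost_factor = cost_factor,
    sv = Xs[sv, , drop = FALSE], coefs = coefs, bias = b,
    scaler = scaler, catalog_hash = catalog_hash,
    meta = list(seed = as.integer(seed), n_pos = sum(y > 0),
                n_neg = sum(y < 0), n_sv = sum(sv),
                package_version = as.character(utils::packageVersion("premirscan")))),
    class = "svm_model")
  model
}

#' Decision scores and class predictions
#'
#' `svm_decision` returns the signed decision value; `svm_classify` returns
#' +1 iff the score is strictly positive (ties to -1).
#'
#' @param model an `svm_model`.
#' @param X matrix (or vector) of unscaled feature rows.
#' @param catalog_hash optional hash to verify against the model's.
#' @export
svm_decision <- function(model, X, catalog_hash = NULL) {
  if (inherits(model, "masked_svm_model")) {
    if (is.null(dim(X))) X <- matrix(X, nrow = 1)
    return(svm_decision(model$inner, X[, model$mask, drop = FALSE]))
  }
  if (!is.null(catalog_hash) && !is.na(model$catalog_hash) &&
      !identical(catalog_hash, model$catalog_hash))
    config_error("feature catalog hash does not match the model")
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  if (ncol(X) != ncol(model$sv))
    config_error("feature dimension does not match the model")
  Xs <- if (!is.null(model$scaler)) apply_scaler(model$scaler, X) else X
  as.vector(kernel_matrix(Xs, model$sv, model$spec) %*% model$coefs +
              model$bias)
}

#' @rdname svm_decision
#' @export
svm_classify <- function(model, X, catalog_hash = NULL) {
  ifelse(svm_decision(model, X, catalog_hash) > 0, 1, -1)
}

#' Persist / restore a model (versioned JSON archive)
#'
#' Round-trips at full double precision: save -> load -> score is identical
#' to ~1e-12.
#'
#' @param model an `svm_model`.
#' @param path file path (.json).
#' @export
svm_save <- function(model, path) {
  obj <- list(format = "premirscan_svm", version = 1L,
              spec = model$spec, C = model$C, cost_factor = model$cost_factor,
              sv = model$sv, coefs = model$coefs, bias = model$bias,
              scaler = if (is.null(model$scaler)) NULL else
                list(min = model$scaler$min, range = model$scaler$range,
                     hi = model$scaler$hi),
              catalog_hash = model$catalog_hash, meta = model$meta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", matrix = "rowmajor")
  invisible(path)
}

#' @rdname svm_save
#' @export
svm_load <- function(path) {
  if (!file.exists(path)) config_error(sprintf("model file not found: %s", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "premirscan_svm"))
    format_error("not a premirscan SVM model file")
  scaler <- NULL
  if (!is.null(obj$scaler))
    scaler <- structure(list(min = unlist(obj$scaler$min),
                             range = unlist(obj$scaler$range),
                             hi = if (is.null(obj$scaler$hi)) 100
                                  else obj$scaler$hi),
                        class = "feature_scaler")
  structure(list(
    spec = list(kind = obj$spec$kind, gamma = obj$spec$gamma,
                degree = as.integer(obj$spec$degree), coef0 = obj$spec$coef0),
    C = obj$C, cost_factor = obj$cost_factor,
    sv = as.matrix(obj$sv), coefs = as.numeric(obj$coefs), bias = obj$bias,
    scaler = scaler,
    catalog_hash = if (is.null(obj$catalog_hash)) NA_character_
                   else obj$catalog_hash,
    meta = obj$meta), class = "svm_model")
}
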