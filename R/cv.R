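# Stratified cross-validated logistic regression ------------------------

#' Stratified k-fold assignment
#'
#' Shuffles the indices of each class under the seed and deals them
#' round-robin over the `k` folds, so per-fold class counts differ from
#' exact proportionality by at most 1 and the folds partition the
#' subjects.
#'
#' @param labels Logical (or `healthy`/`hcc`) class labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids (1..k), one per subject.
#' @export
stratified_kfold <- function(labels, k = 5L, seed = 1L) {
  labels <- as_binary_labels(labels)
  if (!is_count(k) || k < 2) stopf("`k` must be an integer >= 2")
  counts <- table(labels)
  if (any(counts < k)) {
    stopf("every class must have at least k = %d members", k)
  }
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cl in c(TRUE, FALSE)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      start <- sample.int(k, 1L) - 1L  # rotate so no fold is always largest
      folds[idx] <- ((seq_along(idx) - 1L + start) %% k) + 1L
    }
  })
  folds
}

# One IRLS logistic fit: X includes no intercept column (added here).
# Ridge jitter keeps the weighted normal equations well-conditioned;
# separation shows up as non-convergence or exploding coefficients and
# is flagged, with coefficients reported at the last iterate.
logistic_irls <- function(X, y, ridge = 1e-8, max_iter = 100L, tol = 1e-8) {
  X1 <- cbind(`(intercept)` = 1, X)
  p <- ncol(X1)
  beta <- numeric(p)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X1 %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    z <- eta + (y - mu) / w
    XtW <- t(X1 * w)
    beta_new <- drop(solve(XtW %*% X1 + diag(ridge, p), XtW %*% z))
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) { converged <- TRUE; break }
  }
  # on standardized features a coefficient of 15 (odds ratio e^15 per sd)
  # only arises under (quasi-)separation
  separated <- !converged || max(abs(beta)) > 15
  list(coefficients = beta, converged = converged, separated = separated,
       iterations = it)
}

#' Cross-validated logistic regression
#'
#' Stratified k-fold evaluation of a logistic regression classifier.
#' Within each fold the feature columns are standardized on the
#' training subjects only (mean 0, sd 1; constant columns are zeroed)
#' and the frozen parameters are applied to the test subjects. The
#' model is fitted by iteratively reweighted least squares with a ridge
#' jitter of 1e-8 for conditioning (max 100 iterations, tolerance 1e-8
#' on the coefficient change); complete separation is flagged, with
#' coefficients at the last iterate. Per fold, the test-set ROC AUC and
#' the accuracy at probability 0.5 are reported.
#'
#' @param features Numeric matrix (subjects x features) or vector.
#' @param labels Logical (or `healthy`/`hcc`).
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @return Object of class `ev_cv`: list with `k`, `seed`, `folds`
#'   (assignment vector), `fold_auc`, `fold_accuracy`, `coefficients`
#'   (k x (p+1) matrix, original feature scale not restored),
#'   `separated` (logical per fold), `mean_auc`, `mean_accuracy`.
#' @export
logistic_cv <- function(features, labels, k = 5L, seed = 1L) {
  labels <- as_binary_labels(labels)
  X <- as.matrix(features)
  if (is.null(colnames(X))) {
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  if (nrow(X) != length(labels)) stopf("feature rows must match labels")
  folds <- stratified_kfold(labels, k, seed)
  y <- as.numeric(labels)
  fold_auc <- numeric(k); fold_acc <- numeric(k)
  coefs <- matrix(NA_real_, k, ncol(X) + 1L,
                  dimnames = list(NULL, c("(intercept)", colnames(X))))
  separated <- logical(k)
  for (f in seq_len(k)) {
    tr <- folds != f; te <- !tr
    mu <- colMeans(X[tr, , drop = FALSE])
    sd_ <- apply(X[tr, , drop = FALSE], 2, stats::sd)
    scale_fold <- function(M) {
      M <- sweep(M, 2, mu, "-")
      for (j in seq_len(ncol(M))) {
        M[, j] <- if (sd_[j] > 0) M[, j] / sd_[j] else 0
      }
      M
    }
    fit <- logistic_irls(scale_fold(X[tr, , drop = FALSE]), y[tr])
    if (fit$separated) {
      warning(sprintf("fold %d: possible separation or non-convergence", f))
    }
    coefs[f, ] <- fit$coefficients
    separated[f] <- fit$separated
    eta <- drop(cbind(1, scale_fold(X[te, , drop = FALSE])) %*%
                  fit$coefficients)
    prob <- stats::plogis(eta)
    fold_auc[f] <- if (length(unique(y[te])) == 2L) {
      roc_curve(prob, labels[te])$auc
    } else NA_real_
    fold_acc[f] <- mean((prob >= 0.5) == labels[te])
  }
  structure(list(k = as.integer(k), seed = as.integer(seed), folds = folds,
                 fold_auc = fold_auc, fold_accuracy = fold_acc,
                 coefficients = coefs, separated = separated,
                 mean_auc = mean(fold_auc, na.rm = TRUE),
                 mean_accuracy = mean(fold_acc)),
            class = "ev_cv")
}

#' @export
print.ev_cv <- function(x, ...) {
  cat(sprintf("<ev_cv> %d-fold stratified CV (seed %d)\n", x$k, x$seed))
  cat(sprintf("  AUC per fold: %s (mean %.3f)\n",
              paste(sprintf("%.3f", x$fold_auc), collapse = " "), x$mean_auc))
  cat(sprintf("  accuracy per fold: %s (mean %.3f)\n",
              paste(sprintf("%.3f", x$fold_accuracy), collapse = " "),
              x$mean_accuracy))
  if (any(x$separated)) cat("  warning: separation flagged in",
                            sum(x$separated), "fold(s)\n")
  invisible(x)
}
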