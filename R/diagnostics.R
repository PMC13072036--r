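# CD98+ EV Index and diagnostic evaluation ------------------------------

#' Control-normalized CD98+ EV score
#'
#' Subtracts the mean of the disc's negative-control (PBS) well counts
#' from the sample well count, floored at 0. Background binding events
#' add to the disc counts, so normalization is subtraction; a ratio
#' mode is available for sensitivity analyses.
#'
#' @param sample_well_count Numeric vector of sample well counts.
#' @param control_well_counts Numeric vector (one subject) or matrix
#'   (rows = subjects) of same-disc control well counts.
#' @param mode `"subtract"` (default) or `"ratio"`
#'   (`count / mean(controls)`).
#' @return Numeric vector of scores.
#' @examples
#' normalize_score(100, c(20, 20))  # 80
#' normalize_score(10, c(20, 20))   # 0 (floored)
#' @export
normalize_score <- function(sample_well_count, control_well_counts,
                            mode = c("subtract", "ratio")) {
  mode <- match.arg(mode)
  if (is.matrix(control_well_counts)) {
    if (nrow(control_well_counts) != length(sample_well_count)) {
      stopf("control matrix rows must match the number of samples")
    }
    ctrl <- rowMeans(control_well_counts)
  } else {
    if (length(control_well_counts) == 0L) {
      stopf("missing negative-control wells for this disc")
    }
    ctrl <- mean(control_well_counts)
  }
  if (any(is.na(ctrl))) stopf("missing negative-control wells for this disc")
  if (mode == "subtract") pmax(sample_well_count - ctrl, 0)
  else sample_well_count / ctrl
}

#' Concentration-normalized CD98+ EV Index
#'
#' Divides the control-normalized score by the subject's total EV
#' concentration expressed in units of `scale` particles/mL, so that a
#' score of 20 at 2e9 particles/mL (scale 1e9) gives an index of 10.
#'
#' @param cd98_score Numeric score vector from [normalize_score()].
#' @param total_ev_concentration Positive concentration (particles/mL).
#' @param scale Normalization scale (particles/mL), default 1e9.
#' @return Numeric index vector (dimensionless).
#' @export
ev_index <- function(cd98_score, total_ev_concentration, scale = 1e9) {
  if (any(total_ev_concentration <= 0)) {
    stopf("total EV concentration must be > 0")
  }
  cd98_score / (total_ev_concentration / scale)
}

#' ROC curve of a continuous index against a binary label
#'
#' Thresholds are the midpoints between consecutive sorted unique index
#' values plus `-Inf`/`+Inf` sentinels, in descending order; a subject
#' is called positive iff `index >= threshold`. The area under the
#' curve is the trapezoidal area, which equals the Mann-Whitney
#' statistic `U / (n1 * n0)` with ties counting one half.
#'
#' @param indices Numeric vector.
#' @param labels Logical vector (or coercible): `TRUE` = diseased.
#' @return Object of class `ev_roc`: list with `thresholds`
#'   (descending), `sensitivity`, `one_minus_specificity` (both
#'   non-decreasing along the curve, endpoints (0,0) and (1,1)) and
#'   `auc`.
#' @export
roc_curve <- function(indices, labels) {
  labels <- as_binary_labels(labels)
  if (length(indices) != length(labels)) stopf("length mismatch")
  if (!all(is.finite(indices))) stopf("indices must be finite")
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) {
    stopf("both classes must be present to form a ROC curve")
  }
  u <- sort(unique(indices))
  mid <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else numeric(0)
  thr <- c(Inf, rev(mid), -Inf)
  sens <- vapply(thr, function(t) sum(indices >= t & labels) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(indices >= t & !labels) / n0, numeric(1))
  auc <- sum(diff(fpr) * (sens[-1] + sens[-length(sens)]) / 2)
  structure(list(thresholds = thr, sensitivity = sens,
                 one_minus_specificity = fpr, auc = auc,
                 n_positive = n1, n_negative = n0),
            class = "ev_roc")
}

as_binary_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    ok <- labels %in% c("hcc", "healthy")
    if (!all(ok)) stopf("labels must be logical or 'healthy'/'hcc'")
    labels == "hcc"
  } else {
    as.logical(labels)
  }
}

#' @export
print.ev_roc <- function(x, ...) {
  cat(sprintf("<ev_roc> AUC = %.3f (%d positive / %d negative)\n",
              x$auc, x$n_positive, x$n_negative))
  invisible(x)
}

#' @export
plot.ev_roc <- function(x, ...) {
  graphics::plot(x$one_minus_specificity, x$sensitivity, type = "l",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  graphics::legend("bottomright", sprintf("AUC = %.3f", x$auc), bty = "n")
  invisible(x)
}

#' Youden-optimal cutoff
#'
#' The threshold maximizing `J = sensitivity + specificity - 1` over
#' the ROC curve's finite thresholds; ties are broken toward the
#' lowest cutoff (maximizing sensitivity, the screening-oriented
#' choice).
#'
#' @param roc An `ev_roc`.
#' @return Named list `cutoff`, `J`, `sensitivity`, `specificity`.
#' @export
youden_cutoff <- function(roc) {
  stopifnot(inherits(roc, "ev_roc"))
  fin <- is.finite(roc$thresholds)
  thr <- roc$thresholds[fin]
  j <- roc$sensitivity[fin] - roc$one_minus_specificity[fin]
  if (length(thr) == 0L) return(list(cutoff = NA_real_, J = 0,
                                     sensitivity = NA_real_,
                                     specificity = NA_real_))
  best <- which(j >= max(j) - 1e-12)
  pick <- best[which.min(thr[best])]
  list(cutoff = thr[pick], J = j[pick],
       sensitivity = roc$sensitivity[fin][pick],
       specificity = 1 - roc$one_minus_specificity[fin][pick])
}

#' Confusion counts at a fixed cutoff
#'
#' Positive call iff `index >= cutoff`.
#'
#' @param indices Numeric vector.
#' @param labels Logical (or `healthy`/`hcc`).
#' @param cutoff Finite decision cutoff.
#' @return Object of class `confusion_counts`: `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity = tp/(tp+fn)`, `specificity = tn/(tn+fp)`.
#' @export
confusion_at <- function(indices, labels, cutoff) {
  labels <- as_binary_labels(labels)
  if (!is.finite(cutoff)) stopf("`cutoff` must be finite")
  call_pos <- indices >= cutoff
  tp <- sum(call_pos & labels); fn <- sum(!call_pos & labels)
  fp <- sum(call_pos & !labels); tn <- sum(!call_pos & !labels)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
                 cutoff = cutoff),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> cutoff %.4g: TP %d FP %d TN %d FN %d\n",
              x$cutoff, x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("  sensitivity %.1f%%, specificity %.1f%%\n",
              100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}

test_result <- function(method, statistic, df = NA_real_, p_value,
                        two_sided = TRUE) {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(list(method = method, statistic = statistic, df = df,
                 p_value = p_value, two_sided = two_sided),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: statistic = %.4g%s, p = %.4g (%s)\n",
              x$method, x$statistic,
              if (all(is.na(x$df))) "" else
                sprintf(", df = %s", paste(signif(x$df, 4), collapse = ",")),
              x$p_value, if (x$two_sided) "two-sided" else "one-sided"))
  invisible(x)
}

#' Two-proportion z test (pooled)
#'
#' `z = (p1 - p2) / sqrt(p * (1 - p) * (1/n1 + 1/n2))` with the pooled
#' proportion `p = (x1 + x2) / (n1 + n2)`; two-sided p from the normal
#' distribution. When the pooled proportion is 0 or 1 the statistic is
#' defined as 0 with p = 1 (both samples are then identical).
#'
#' @param x1,n1,x2,n2 Successes and sizes of the two samples.
#' @return A `test_result` (`z^2` equals the uncorrected Pearson
#'   chi-square of the corresponding 2x2 table).
#' @export
two_proportion_ztest <- function(x1, n1, x2, n2) {
  if (n1 <= 0 || n2 <= 0) stopf("sample sizes must be positive")
  if (x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2) stopf("need 0 <= x <= n")
  p <- (x1 + x2) / (n1 + n2)
  if (p <= 0 || p >= 1) {
    return(test_result("two-proportion z", 0, p_value = 1))
  }
  z <- (x1 / n1 - x2 / n2) / sqrt(p * (1 - p) * (1 / n1 + 1 / n2))
  test_result("two-proportion z", z,
              p_value = 2 * stats::pnorm(-abs(z)))
}

#' Welch two-sample t test
#'
#' Unpaired two-tailed t test with Welch's correction (Satterthwaite
#' degrees of freedom), wrapping [stats::t.test()]. Degenerate inputs
#' with zero variance in both groups return `t = 0, p = 1` when the
#' means are equal and `t = Inf` (sign of the difference), `p = 0`
#' otherwise.
#'
#' @param values_a,values_b Numeric samples, each of size >= 2.
#' @return A `test_result`.
#' @export
welch_ttest <- function(values_a, values_b) {
  if (length(values_a) < 2 || length(values_b) < 2) {
    stopf("each group needs n >= 2")
  }
  if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0) {
    d <- mean(values_a) - mean(values_b)
    if (d == 0) return(test_result("Welch t", 0, df = NA_real_, p_value = 1))
    return(test_result("Welch t", sign(d) * Inf, df = NA_real_, p_value = 0))
  }
  tt <- stats::t.test(values_a, values_b, var.equal = FALSE)
  test_result("Welch t", unname(tt$statistic), df = unname(tt$parameter),
              p_value = tt$p.value)
}

#' Pearson chi-square test of independence
#'
#' Uncorrected (no Yates continuity correction) Pearson chi-square on an
#' r x c count table, wrapping [stats::chisq.test()];
#' `df = (r - 1)(c - 1)`.
#'
#' @param table Matrix of non-negative counts with positive row and
#'   column margins.
#' @param correct Apply Yates continuity correction (2x2 only); default
#'   `FALSE`.
#' @return A `test_result`.
#' @export
chi_square <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (any(table < 0)) stopf("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stopf("zero row/column margin: chi-square undefined")
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = correct))
  test_result("Pearson chi-square", unname(ct$statistic),
              df = unname(ct$parameter), p_value = ct$p.value)
}

#' Full diagnostic evaluation of a cohort
#'
#' Derives the CD98+ EV index where absent, compares groups with a
#' Welch t test, builds the ROC curve, picks the cutoff (Youden by
#' default, or a fixed value), forms confusion counts, tests
#' categorical covariates against high/low index (median split) with
#' chi-square, and optionally compares the achieved sensitivity to a
#' reference sensitivity with a two-proportion z test.
#'
#' @param cohort An `ev_cohort`.
#' @param cutoff `NULL` for the Youden-optimal cutoff, or a fixed
#'   numeric value.
#' @param reference_sensitivity Optional named numeric vector of
#'   comparator sensitivities (fractions) evaluated on the same number
#'   of diseased subjects.
#' @return List of class `ev_diagnostics` with elements `roc`,
#'   `youden`, `confusion`, `welch`, `chisq` (per covariate),
#'   `z_vs_reference`, `cutoff`.
#' @export
evaluate_diagnostics <- function(cohort, cutoff = NULL,
                                 reference_sensitivity = NULL) {
  if (!"cd98_index" %in% names(cohort)) cohort <- derive_index(cohort)
  idx <- cohort$cd98_index
  lab <- as_binary_labels(cohort$group)
  roc <- roc_curve(idx, lab)
  yj <- youden_cutoff(roc)
  use_cut <- cutoff %||% yj$cutoff
  conf <- confusion_at(idx, lab, use_cut)
  welch <- welch_ttest(idx[lab], idx[!lab])
  hcc <- cohort[lab, , drop = FALSE]
  hi <- hcc$cd98_index > stats::median(hcc$cd98_index)
  chisq <- list()
  for (v in c("sex", "smoking", "alcohol", "cirrhosis", "stage")) {
    if (v %in% names(hcc)) {
      tab <- table(hi, hcc[[v]])
      if (all(dim(tab) >= 2) && all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
        chisq[[v]] <- chi_square(tab)
      }
    }
  }
  zref <- NULL
  if (!is.null(reference_sensitivity)) {
    n1 <- conf$tp + conf$fn
    zref <- lapply(reference_sensitivity, function(s) {
      two_proportion_ztest(conf$tp, n1, round(s * n1), n1)
    })
  }
  structure(list(roc = roc, youden = yj, confusion = conf, welch = welch,
                 chisq = chisq, z_vs_reference = zref, cutoff = use_cut),
            class = "ev_diagnostics")
}

#' @export
print.ev_diagnostics <- function(x, ...) {
  cat("<ev_diagnostics>\n")
  print(x$roc)
  cat(sprintf("  cutoff %.4g (Youden J = %.3f)\n", x$cutoff, x$youden$J))
  print(x$confusion)
  print(x$welch)
  invisible(x)
}
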