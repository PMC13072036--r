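test_that("score normalization subtracts disc controls with a floor", {
  expect_equal(normalize_score(100, c(20, 20)), 80)
  expect_equal(normalize_score(10, c(20, 20)), 0)
  # additive invariance: shifting sample and controls by c is a no-op
  set.seed(2)
  for (i in 1:20) {
    s <- rpois(1, 80); ctrl <- rpois(3, 15); off <- rpois(1, 30)
    expect_equal(normalize_score(s + off, ctrl + off),
                 normalize_score(s, ctrl))
  }
  expect_equal(normalize_score(c(100, 50), rbind(c(20, 20), c(60, 40))),
               c(80, 0))
  expect_error(normalize_score(10, numeric(0)), "control")
  expect_equal(normalize_score(100, c(20, 20), mode = "ratio"), 5)
})

test_that("the index scales inversely with total concentration", {
  expect_equal(ev_index(20, 2e9, 1e9), 10)
  expect_equal(ev_index(0, 5e9), 0)
  expect_equal(ev_index(10, 2e9), ev_index(10, 1e9) / 2)
  expect_error(ev_index(10, 0), "concentration")
})

test_that("ROC endpoints, monotonicity and trivial cases are correct", {
  roc <- roc_curve(c(1, 2, 3, 10, 11, 12), c(F, F, F, T, T, T))
  expect_equal(roc$auc, 1)
  expect_equal(roc$sensitivity[1], 0)
  expect_equal(roc$one_minus_specificity[1], 0)
  expect_equal(roc$sensitivity[length(roc$sensitivity)], 1)
  expect_equal(roc$one_minus_specificity[length(roc$thresholds)], 1)
  expect_true(all(diff(roc$sensitivity) >= 0))
  expect_true(all(diff(roc$one_minus_specificity) >= 0))
  expect_equal(roc_curve(rep(5, 10), rep(c(TRUE, FALSE), 5))$auc, 0.5)
  expect_error(roc_curve(1:5, rep(TRUE, 5)), "both classes")
})

test_that("trapezoidal AUC equals the Mann-Whitney statistic exactly", {
  set.seed(33)
  for (i in 1:100) {
    n1 <- sample(5:40, 1); n0 <- sample(5:40, 1)
    v <- c(rnorm(n1, 1), rnorm(n0))
    if (i %% 3 == 0) v <- round(v)  # force ties regularly
    lab <- rep(c(TRUE, FALSE), c(n1, n0))
    expect_equal(roc_curve(v, lab)$auc, oracle_auc(v, lab),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(21)
  for (i in 1:10) {
    v <- c(rnorm(30, 1), rnorm(25))
    lab <- rep(c(1, 0), c(30, 25))
    ref <- suppressMessages(as.numeric(pROC::auc(lab, v)))
    expect_equal(roc_curve(v, lab == 1)$auc, ref, tolerance = 1e-10)
  }
})

test_that("Youden cutoff equals the exhaustive-scan maximizer", {
  set.seed(17)
  for (i in 1:50) {
    n1 <- sample(5:30, 1); n0 <- sample(5:30, 1)
    v <- round(c(rnorm(n1, 1.2), rnorm(n0)), sample(0:2, 1))
    lab <- rep(c(TRUE, FALSE), c(n1, n0))
    yj <- youden_cutoff(roc_curve(v, lab))
    or <- oracle_youden(v, lab)
    expect_equal(yj$J, or$J, tolerance = 1e-12)
    expect_equal(yj$cutoff, or$cutoff, tolerance = 1e-12)
  }
  sep <- youden_cutoff(roc_curve(c(1, 2, 8, 9), c(F, F, T, T)))
  expect_equal(sep$J, 1)
  expect_gt(sep$cutoff, 2); expect_lt(sep$cutoff, 8)
  expect_equal(youden_cutoff(roc_curve(rep(3, 6), rep(c(T, F), 3)))$J, 0)
})

test_that("confusion counts match hand enumeration and edge cutoffs", {
  idx <- c(7, 9, 2, 8, 1, 3)
  lab <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  cc <- confusion_at(idx, lab, 6)
  expect_equal(c(cc$tp, cc$fn, cc$fp, cc$tn), c(2, 1, 1, 2))
  expect_equal(cc$sensitivity, 2 / 3)
  expect_equal(cc$specificity, 2 / 3)
  all_pos <- confusion_at(idx, lab, 0)
  expect_equal(all_pos$sensitivity, 1)
  expect_equal(all_pos$specificity, 0)
  hi <- confusion_at(idx, lab, 100)
  expect_equal(hi$sensitivity, 0)
  expect_equal(hi$specificity, 1)
})

test_that("z^2 equals the uncorrected Pearson chi-square on 2x2 tables", {
  set.seed(5)
  for (i in 1:100) {
    n1 <- sample(10:200, 1); n2 <- sample(10:200, 1)
    x1 <- sample(1:(n1 - 1), 1); x2 <- sample(1:(n2 - 1), 1)
    z <- two_proportion_ztest(x1, n1, x2, n2)
    tab <- matrix(c(x1, n1 - x1, x2, n2 - x2), 2, byrow = TRUE)
    chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(z$statistic^2, unname(chi$statistic), tolerance = 1e-10)
    expect_equal(z$p_value, chi$p.value, tolerance = 1e-10)
  }
})

test_that("z test is antisymmetric and handles degenerate pools", {
  expect_equal(two_proportion_ztest(5, 10, 10, 20)$statistic, 0)
  expect_equal(two_proportion_ztest(5, 10, 10, 20)$p_value, 1)
  a <- two_proportion_ztest(8, 20, 3, 15)
  b <- two_proportion_ztest(3, 15, 8, 20)
  expect_equal(a$statistic, -b$statistic)
  expect_equal(a$p_value, b$p_value)
  d <- two_proportion_ztest(0, 10, 0, 12)
  expect_equal(d$statistic, 0)
  expect_equal(d$p_value, 1)
  expect_error(two_proportion_ztest(11, 10, 1, 5), "x <= n")
})

test_that("Welch test reduces to the pooled t in balanced equal-variance data", {
  set.seed(9)
  a <- rnorm(30); b <- rnorm(30, 0.5)
  w <- welch_ttest(a, b)
  pooled <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(w$statistic, unname(pooled$statistic), tolerance = 1e-6)
  # scale invariance
  w2 <- welch_ttest(10 * a, 10 * b)
  expect_equal(w$statistic, w2$statistic, tolerance = 1e-12)
  same <- c(1, 2, 3, 4)
  expect_equal(welch_ttest(same, same)$statistic, 0)
  expect_equal(welch_ttest(c(2, 2), c(2, 2))$p_value, 1)
  expect_error(welch_ttest(1, c(1, 2)), "n >= 2")
})

test_that("chi-square matches hand computation and is permutation-invariant", {
  tab <- matrix(c(10, 20, 20, 10), 2, byrow = TRUE)
  # hand Pearson: E = 15 everywhere, X2 = 4 * 25/15
  res <- chi_square(tab)
  expect_equal(res$statistic, 4 * 25 / 15, tolerance = 1e-12)
  expect_equal(res$df, 1)
  perm <- chi_square(tab[2:1, 2:1])
  expect_equal(res$statistic, perm$statistic)
  indep <- outer(c(30, 70), c(40, 60)) / 100
  expect_equal(chi_square(indep)$statistic, 0, tolerance = 1e-12)
  expect_error(chi_square(matrix(c(0, 0, 3, 4), 2)), "margin")
})

test_that("cohort-level evaluation separates the groups as planted", {
  cohort <- derive_index(simulate_cohort(cohort_spec(seed = 12L)))
  dg <- evaluate_diagnostics(cohort)
  expect_gt(dg$roc$auc, 0.6)
  expect_lt(dg$welch$p_value, 0.01)
  expect_equal(dg$confusion$tp + dg$confusion$fn, sum(cohort$group == "hcc"))
  expect_equal(dg$confusion$tn + dg$confusion$fp,
               sum(cohort$group == "healthy"))
  fixed <- evaluate_diagnostics(cohort, cutoff = 6)
  expect_equal(fixed$cutoff, 6)
  ref <- evaluate_diagnostics(cohort, reference_sensitivity = c(afp20 = 0.33))
  expect_s3_class(ref$z_vs_reference$afp20, "test_result")
})
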