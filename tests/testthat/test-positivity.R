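test_that("local background is exact on flat fields and excludes neighbors", {
  fld <- tiny_field(n = 3L, combos = c(1L, 1L, 1L))
  lm <- suppressMessages(segment_field(fld))
  for (i in seq_len(lm$n_components)) {
    expect_equal(local_background(fld$channels$cd9, lm, i), 100)
  }
  # two adjacent components: the neighbor's pixels never enter the annulus
  m <- matrix(FALSE, 24, 24)
  m[10:12, 8:10] <- TRUE
  m[10:12, 14:16] <- TRUE
  lm2 <- label_components(m, 8L)
  ann <- sevtools:::component_annulus(lm2, 1L, r_in = 2L, r_out = 5L)
  expect_true(length(ann) > 0)
  expect_true(all(lm2$labels[ann] == 0L))
})

test_that("local background tracks a linear ramp at the component ring", {
  img <- outer(rep(1, 40), seq_len(40))  # ramp in x: value = column
  m <- matrix(FALSE, 40, 40)
  m[18:22, 18:22] <- TRUE
  lm <- label_components(m, 8L)
  bg <- local_background(img, lm, 1L, r_in = 2L, r_out = 5L)
  expect_equal(bg, 20, tolerance = 5 / 20)  # ramp slope x r_out bound
})

test_that("empty annulus falls back to the global median", {
  m <- matrix(TRUE, 9, 9)  # a single component fills the image
  lm <- label_components(m, 8L)
  img <- matrix(42, 9, 9)
  expect_message(bg <- local_background(img, lm, 1L), "global median")
  expect_equal(bg, 42)
})

test_that("measurements conserve the component count and share pixels", {
  fld <- tiny_field(n = 6L, combos = c(0L, 1L, 2L, 4L, 5L, 7L))
  lm <- suppressMessages(segment_field(fld))
  meas <- measure_evs(fld, lm)
  expect_s3_class(meas, "ev_measurements")
  expect_equal(nrow(meas), lm$n_components)
  expect_equal(meas$area, lm$area)
  empty <- label_components(matrix(FALSE, 16, 16), 8L)
  expect_equal(nrow(measure_evs(fld, empty)), 0L)
})

test_that("noise-free corrected means match the analytic spot profile", {
  fld <- tiny_field(n = 4L, combos = rep(5L, 4),  # CD63+CD98+
                    amp_total = 20000, amp_marker = 10000)
  lm <- suppressMessages(segment_field(fld))
  meas <- measure_evs(fld, lm)
  sigma <- fld$spec$psf_sigma
  for (i in seq_len(nrow(meas))) {
    j <- which.min((fld$truth$x - meas$x[i])^2 + (fld$truth$y - meas$y[i])^2)
    idx <- which(lm$labels == i)
    rows <- ((idx - 1) %% nrow(lm$labels))      # 0-based
    cols <- ((idx - 1) %/% nrow(lm$labels))
    g <- exp(-((cols - fld$truth$x[j])^2 + (rows - fld$truth$y[j])^2) /
               (2 * sigma^2))
    expected <- 10000 * g / (2 * pi * sigma^2)  # untruncated Gaussian
    expect_equal(meas$corr_cd98[i], mean(expected), tolerance = 0.02)
  }
  # absent marker channel is exactly background-corrected to zero
  expect_true(all(meas$corr_cd9 == 0))
})

test_that("positivity calls are exact on noise-free planted fields", {
  combos <- c(0L, 1L, 2L, 3L, 4L, 5L, 6L, 7L)
  fld <- tiny_field(n = 8L, combos = combos, width = 128L, height = 128L)
  lm <- suppressMessages(segment_field(fld))
  meas <- measure_evs(fld, lm)
  expect_equal(nrow(meas), 8L)
  # match each detected EV to its planted truth by position
  j <- vapply(seq_len(nrow(meas)), function(i) {
    which.min((fld$truth$x - meas$x[i])^2 + (fld$truth$y - meas$y[i])^2)
  }, integer(1))
  expect_equal(meas$combination, fld$truth$combination[j])
})

test_that("raising k_sigma never flips a negative call to positive", {
  expect_false(call_positive(0, k_sigma = 3, sigma_bg = 2))
  expect_false(call_positive(0, k_sigma = 0.5, sigma_bg = 2))
  vals <- runif(50, 0, 30)
  for (sig in c(1, 5)) {
    lo <- call_positive(vals, 2, sig)
    hi <- call_positive(vals, 4, sig)
    expect_true(all(lo | !hi))  # hi-positive implies lo-positive
  }
  expect_true(call_positive(1e-9, k_sigma = 3, sigma_bg = 0))
})

test_that("positivity is invariant to a constant marker-channel offset", {
  fld <- tiny_field(n = 5L, combos = c(1L, 3L, 5L, 7L, 0L))
  lm <- suppressMessages(segment_field(fld))
  m1 <- measure_evs(fld, lm)
  fld$channels$cd98 <- fld$channels$cd98 + 25L
  m2 <- measure_evs(fld, lm)
  expect_equal(m1$pos_cd98, m2$pos_cd98)
  expect_equal(m1$corr_cd98, m2$corr_cd98)
})

test_that("co-expression table equals a hand tabulation", {
  codes <- c(0L, 0L, 1L, 1L, 1L, 5L, 7L, 7L, 4L, 2L)
  meas <- data.frame(combination = codes)
  class(meas) <- c("ev_measurements", "data.frame")
  tab <- coexpression_table(meas)
  expect_equal(tab$n_total, 10L)
  expect_equal(unname(tab$counts), c(2L, 3L, 1L, 0L, 1L, 1L, 0L, 2L))
  expect_equal(sum(tab$counts), tab$n_total)
  expect_equal(sum(tab$fractions), 1, tolerance = 1e-9)
  # marginal = sum of the four combinations containing the marker
  fl <- combo_flags(0:7)
  expect_equal(unname(tab$marginals["cd98"]), sum(tab$fractions[fl$cd98]))
  expect_equal(unname(tab$marginals["cd63"]), 0.6)
  expect_error(coexpression_table(meas[0, , drop = FALSE]), "no measurements")
})

test_that("all-triple-positive input gives unit fractions and marginals", {
  meas <- data.frame(combination = rep(7L, 12))
  tab <- coexpression_table(meas)
  expect_equal(unname(tab$fractions[8]), 1)
  expect_equal(unname(tab$marginals), c(1, 1, 1))
})

test_that("pooling across fields sums counts rather than averaging fractions", {
  a <- data.frame(combination = rep(7L, 30))
  b <- data.frame(combination = rep(0L, 10))
  tab <- coexpression_table(list(a, b))
  expect_equal(tab$n_total, 40L)
  expect_equal(unname(tab$fractions[8]), 0.75)
})

test_that("line scans reproduce constants and analytic Gaussian sections", {
  flat <- list(total = matrix(7, 32, 32), cd63 = matrix(1, 32, 32),
               cd9 = matrix(2, 32, 32), cd98 = matrix(3, 32, 32))
  ls <- line_scan(flat, c(2, 10), c(28, 10), width = 3)
  expect_true(all(ls$total == 7))
  expect_true(all(ls$cd98 == 3))
  expect_error(line_scan(flat, c(5, 5), c(5, 5)), "zero-length")
  expect_error(line_scan(flat, c(-2, 5), c(10, 5)), "inside")

  spec <- field_spec(width = 64L, height = 64L, n_evs = 1L,
                     shot_noise = FALSE, read_noise_sigma = 0)
  truth <- data.frame(ev_id = 1L, x = 32, y = 30, cd63 = FALSE, cd9 = FALSE,
                      cd98 = TRUE, combination = 4L, amp_total = 40000,
                      amp_cd63 = 0, amp_cd9 = 0, amp_cd98 = 30000)
  fld <- render_field(spec, truth)
  ls2 <- line_scan(fld, c(20, 30), c(44, 30))
  expect_equal(ls2$position[which.max(ls2$total)], 12)  # spot center column
  sigma <- spec$psf_sigma
  xs <- 20 + ls2$position
  analytic <- 100 + 40000 / (2 * pi * sigma^2) * exp(-(xs - 32)^2 / (2 * sigma^2))
  keep <- analytic > 150  # compare where quantization noise is negligible
  expect_equal(ls2$total[keep], analytic[keep], tolerance = 0.01)
})
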