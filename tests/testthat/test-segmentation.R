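make_hist <- function(counts, lo = 0, hi = length(counts)) {
  structure(list(bin_edges = seq(lo, hi, length.out = length(counts) + 1L),
                 counts = counts), class = "ev_histogram")
}

test_that("two-spike histogram thresholds strictly between the spikes", {
  counts <- integer(256)
  counts[10] <- 1000L
  counts[200] <- 10L
  thr <- triangle_threshold(make_hist(counts))
  edges <- seq(0, 256, length.out = 257)
  expect_gt(as.numeric(thr), edges[10])
  expect_lt(as.numeric(thr), edges[201])
})

test_that("symmetric histogram resolves toward the higher-intensity side", {
  counts <- integer(101)
  counts[51] <- 1000L
  counts[c(31, 71)] <- 5L
  counts[c(41, 61)] <- 100L
  thr <- triangle_threshold(make_hist(counts))
  expect_gt(attr(thr, "bin"), 51)  # documented tie-break: upper tail
})

test_that("triangle threshold matches the brute-force geometric oracle", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(c(64L, 128L, 256L), 1)
    peak <- sample(seq_len(n), 1)
    x <- seq_len(n)
    counts <- as.integer(rpois(n, 200 * exp(-(x - peak)^2 / 50) +
                                  5 * exp(-abs(x - peak) / 40)))
    if (sum(counts > 0) < 2) next
    thr <- triangle_threshold(make_hist(counts))
    expect_identical(attr(thr, "bin"), oracle_triangle_bin(counts))
  }
})

test_that("degenerate histograms raise an error", {
  counts <- integer(256); counts[7] <- 500L
  expect_error(triangle_threshold(make_hist(counts)), "degenerate")
  expect_error(build_histogram(matrix(5, 4, 4)), "degenerate")
})

test_that("opening removes specks, keeps blobs, and is idempotent", {
  m <- matrix(FALSE, 32, 32)
  m[5, 5] <- TRUE                       # isolated pixel
  disk <- outer(1:32, 1:32, function(r, c) (r - 20)^2 + (c - 20)^2 <= 25)
  m[disk] <- TRUE
  cleaned <- morphological_clean(m)
  expect_false(cleaned[5, 5])
  # the disk survives nearly intact: no additions, only single-pixel
  # boundary tips may be eroded away
  expect_true(all(disk[cleaned]))
  expect_gt(sum(cleaned & disk) / sum(disk), 0.9)
  set.seed(1)
  for (i in 1:5) {
    rnd <- matrix(runif(400) < 0.3, 20, 20)
    once <- morphological_clean(rnd)
    expect_identical(morphological_clean(once), once)
    # never adds foreground outside the dilation of the input
    dil <- EBImage::dilate(matrix(as.numeric(rnd), 20, 20),
                           EBImage::makeBrush(3, "disc")) > 0
    expect_true(all(!once | dil))
  }
})

test_that("labeling honors 4- vs 8-connectivity and computes centroids", {
  m <- matrix(FALSE, 6, 6)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE  # diagonal neighbors
  expect_equal(label_components(m, 8L)$n_components, 1L)
  expect_equal(label_components(m, 4L)$n_components, 2L)
  sq <- matrix(FALSE, 8, 8)
  sq[3:4, 5:6] <- TRUE
  lm <- label_components(sq, 8L)
  expect_equal(lm$area, 4)
  expect_equal(unname(lm$centroid[1, ]), c(4.5, 2.5))  # 0-based (x, y)
})

test_that("area gate matches a brute-force filter and relabels compactly", {
  expect_equal(
    suppressMessages(area_gate(label_components(matrix(c(
      TRUE, FALSE, rep(FALSE, 14)), 4, 4), 8L), 2, 50))$n_components, 0L)
  set.seed(8)
  for (i in 1:10) {
    m <- matrix(runif(900) < 0.25, 30, 30)
    lm <- label_components(m, 8L)
    lo <- sample(1:3, 1); hi <- sample(4:9, 1)
    gated <- suppressMessages(area_gate(lm, lo, hi))
    keep <- which(lm$area >= lo & lm$area <= hi)
    expect_equal(gated$n_components, length(keep))
    expect_equal(gated$area, lm$area[keep])
    expect_equal(gated$centroid, lm$centroid[keep, , drop = FALSE])
    if (gated$n_components > 0) {
      expect_equal(sort(unique(as.vector(gated$labels[gated$labels > 0]))),
                   seq_len(gated$n_components))
    }
  }
})

test_that("noise-free planted spots are recovered exactly with centroids", {
  spec <- field_spec(width = 160L, height = 160L, n_evs = 20L,
                     shot_noise = FALSE, read_noise_sigma = 0, seed = 5L)
  fld <- simulate_field(spec)
  lm <- suppressMessages(segment_field(fld))
  expect_equal(lm$n_components, 20L)
  # match centroids to truth within 1 px
  d <- sqrt(outer(lm$centroid[, "x"], fld$truth$x, "-")^2 +
              outer(lm$centroid[, "y"], fld$truth$y, "-")^2)
  expect_true(all(apply(d, 2, min) <= 1))
})

test_that("segmentation is invariant to adding a constant offset", {
  fld <- simulate_field(field_spec(width = 128L, height = 128L, n_evs = 12L,
                                   seed = 6L))
  a <- suppressMessages(segment_field(fld$channels$total))
  b <- suppressMessages(segment_field(fld$channels$total + 57))
  expect_identical(a$labels, b$labels)
})

test_that("raising min_area never increases the component count", {
  fld <- simulate_field(field_spec(width = 128L, height = 128L, n_evs = 12L,
                                   seed = 13L))
  counts <- vapply(c(1, 2, 5, 10, 20), function(mn) {
    p <- segmentation_params(min_area = mn, max_area = 50)
    suppressMessages(segment_field(fld$channels$total, p))$n_components
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("two spots closer than the PSF width merge into one component", {
  spec <- field_spec(width = 64L, height = 64L, n_evs = 2L,
                     shot_noise = FALSE, read_noise_sigma = 0,
                     min_separation = 0)
  truth <- data.frame(ev_id = 1:2, x = c(30, 31.5), y = c(30, 30),
                      cd63 = TRUE, cd9 = FALSE, cd98 = FALSE,
                      combination = 1L, amp_total = 3000, amp_cd63 = 1500,
                      amp_cd9 = 0, amp_cd98 = 0)
  fld <- render_field(spec, truth)
  lm <- suppressMessages(segment_field(fld))
  expect_equal(lm$n_components, 1L)
})
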