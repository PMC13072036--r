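# Independent oracles used across test files. These deliberately avoid
# the package's own code paths.

# Brute-force triangle threshold: true perpendicular point-to-line
# distance evaluated for every bin strictly between the histogram peak
# and the far end of the longer tail; same documented tie-breaks
# (peak ties -> lowest bin, tail ties -> higher-intensity side,
# distance ties -> bin nearest the peak).
oracle_triangle_bin <- function(counts) {
  nz <- which(counts > 0)
  stopifnot(length(nz) >= 2)
  b_p <- which.max(counts)
  lo <- nz[1]; hi <- nz[length(nz)]
  b_e <- if ((hi - b_p) >= (b_p - lo)) hi else lo
  if (abs(b_e - b_p) <= 1L) return(min(b_p, b_e))
  cand <- if (b_e > b_p) (b_p + 1L):(b_e - 1L) else (b_e + 1L):(b_p - 1L)
  len <- sqrt((b_e - b_p)^2 + (counts[b_e] - counts[b_p])^2)
  d <- vapply(cand, function(b) {
    abs((counts[b_e] - counts[b_p]) * (b - b_p) -
          (b_e - b_p) * (counts[b] - counts[b_p])) / len
  }, numeric(1))
  best <- which(d >= max(d) - 1e-9 * max(max(d), 1))
  cand[best][which.min(abs(cand[best] - b_p))]
}

# Mann-Whitney AUC via midranks (ties credited one half).
oracle_auc <- function(values, labels) {
  labels <- as.logical(labels)
  r <- rank(values)
  n1 <- sum(labels); n0 <- sum(!labels)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Exhaustive Youden scan over every candidate cutoff (midpoints of
# consecutive unique values), ties toward the lowest cutoff.
oracle_youden <- function(values, labels) {
  labels <- as.logical(labels)
  u <- sort(unique(values))
  cand <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else u
  j <- vapply(cand, function(t) {
    mean(values[labels] >= t) - mean(values[!labels] >= t)
  }, numeric(1))
  best <- which(j >= max(j) - 1e-12)
  list(cutoff = cand[best][which.min(cand[best])], J = max(j))
}

# A tiny noise-free field with hand-chosen, well-separated spots.
tiny_field <- function(n = 6L, combos = NULL, seed = 7L, amp_total = 8000,
                       amp_marker = 3000, width = 96L, height = 96L) {
  spec <- field_spec(width = width, height = height, n_evs = n,
                     shot_noise = FALSE, read_noise_sigma = 0,
                     seed = seed)
  truth <- sample_field_truth(spec, seed = seed)
  if (!is.null(combos)) {
    fl <- combo_flags(combos)
    truth$cd63 <- fl$cd63; truth$cd9 <- fl$cd9; truth$cd98 <- fl$cd98
    truth$combination <- combos
  }
  truth$amp_total <- rep(amp_total, n)
  truth$amp_cd63 <- ifelse(truth$cd63, amp_marker, 0)
  truth$amp_cd9 <- ifelse(truth$cd9, amp_marker, 0)
  truth$amp_cd98 <- ifelse(truth$cd98, amp_marker, 0)
  render_field(spec, truth, seed = seed)
}

# Planted population values for the co-expression profile (fractions).
planted_freqs <- function() default_combination_freqs()
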