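# Synthetic multichannel fields -----------------------------------------
#
# A synthetic field emulates one 20x field of view from a multiplex
# single-EV imaging experiment: a total-stain channel (amine-reactive
# dye, labels every vesicle) plus one immunofluorescence channel per
# marker (CD63, CD9, CD98). Each vesicle is far below the diffraction
# limit, so it renders as a point-spread-function-shaped spot whose
# amplitude in a marker channel is positive iff the vesicle carries that
# marker. The planted per-vesicle truth is retained so the downstream
# pipeline can be validated exactly.

CHANNELS <- c("total", "cd63", "cd9", "cd98")

#' Specification of a synthetic single-EV field
#'
#' Collects every parameter of the synthetic field generator: geometry,
#' point-spread function, per-channel background and amplitude
#' distributions, noise model, spot placement constraint, marker
#' combination frequencies, spectral crosstalk and the RNG seed.
#'
#' @param width,height Field size in pixels.
#' @param n_evs Number of vesicles to plant.
#' @param psf_sigma Isotropic Gaussian PSF sigma in pixels. Spots are
#'   rendered on a window truncated at 4 sigma and normalized to unit
#'   sum over that window, so a spot's amplitude equals its total
#'   integrated signal.
#' @param background_per_channel Additive background level per channel
#'   (length-4, ADU), order `total, cd63, cd9, cd98`.
#' @param read_noise_sigma Gaussian read-noise sd (ADU); applied after
#'   shot noise.
#' @param shot_noise Logical; if `TRUE`, Poisson noise on signal plus
#'   background.
#' @param min_separation Minimum center-to-center spot distance in
#'   pixels, enforced by rejection sampling (vesicle suspensions that do
#'   not aggregate give well-separated spots).
#' @param combination_freqs Probability 8-vector over marker
#'   combinations; see [default_combination_freqs()].
#' @param amplitude_mean,amplitude_sd Length-4 per-channel amplitude
#'   mean/sd (ADU, total integrated signal per spot). The total-stain
#'   amplitude is drawn log-normal (moment-matched) to mimic vesicle
#'   size/labeling heterogeneity; marker amplitudes are normal truncated
#'   at 1 ADU.
#' @param crosstalk 4x4 channel mixing matrix applied to the noiseless
#'   spot signal (rows = observed channel, cols = source channel);
#'   identity by default.
#' @param seed Integer seed used by [simulate_field()] and
#'   [render_field()].
#' @return A list of class `field_spec`.
#' @export
field_spec <- function(width = 512L, height = 512L, n_evs = 269L,
                       psf_sigma = 1.3,
                       background_per_channel = c(100, 100, 100, 100),
                       read_noise_sigma = 2,
                       shot_noise = TRUE,
                       min_separation = 8,
                       combination_freqs = default_combination_freqs(),
                       amplitude_mean = c(3000, 1800, 1800, 1800),
                       amplitude_sd = c(1100, 350, 350, 350),
                       crosstalk = diag(4),
                       seed = 1L) {
  if (!is_count(width) || !is_count(height) || width < 8 || height < 8) {
    stopf("field dimensions must be integers >= 8")
  }
  if (!is_count(n_evs)) stopf("`n_evs` must be a non-negative integer")
  if (!is.numeric(psf_sigma) || psf_sigma <= 0) stopf("`psf_sigma` must be > 0")
  if (min_separation < 0) stopf("`min_separation` must be >= 0")
  combination_freqs <- validate_combination_freqs(combination_freqs)
  stopifnot(length(background_per_channel) == 4L,
            all(background_per_channel >= 0),
            length(amplitude_mean) == 4L, length(amplitude_sd) == 4L,
            all(amplitude_mean > 0), all(amplitude_sd >= 0),
            is.matrix(crosstalk), all(dim(crosstalk) == c(4L, 4L)),
            read_noise_sigma >= 0)
  structure(list(
    width = as.integer(width), height = as.integer(height),
    n_evs = as.integer(n_evs), psf_sigma = psf_sigma,
    background_per_channel = as.numeric(background_per_channel),
    read_noise_sigma = read_noise_sigma, shot_noise = isTRUE(shot_noise),
    min_separation = min_separation,
    combination_freqs = combination_freqs,
    amplitude_mean = as.numeric(amplitude_mean),
    amplitude_sd = as.numeric(amplitude_sd),
    crosstalk = crosstalk, seed = as.integer(seed)
  ), class = "field_spec")
}

# Truncated-normal draw with lower bound `lo` via inverse-CDF.
rtruncnorm_lo <- function(n, mean, sd, lo) {
  if (sd == 0) return(rep(max(mean, lo), n))
  plo <- stats::pnorm(lo, mean, sd)
  stats::qnorm(stats::runif(n, plo, 1), mean, sd)
}

#' Sample planted vesicle ground truth for a field
#'
#' Draws vesicle centers (rejection-sampled to honor
#' `spec$min_separation` and a border margin of 4 PSF sigma),
#' marker combinations and per-channel amplitudes. A marker channel
#' amplitude is zero iff the vesicle lacks that marker; the total-stain
#' amplitude is always positive.
#'
#' @param spec A [field_spec()].
#' @param seed Seed; defaults to `spec$seed`.
#' @return data.frame with columns `ev_id`, `x`, `y` (0-based subpixel
#'   center coordinates, `x` = column, `y` = row), `cd63`, `cd9`, `cd98`
#'   (logical), `combination` (code 0..7) and `amp_total`, `amp_cd63`,
#'   `amp_cd9`, `amp_cd98`.
#' @export
sample_field_truth <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "field_spec"))
  n <- spec$n_evs
  margin <- 4 * spec$psf_sigma + 1
  if (spec$width - 2 * margin <= 0 || spec$height - 2 * margin <= 0) {
    stopf("field too small for the PSF margin")
  }
  with_seed(seed, {
    code <- sample_combinations(spec$combination_freqs, n)
    xs <- numeric(n); ys <- numeric(n)
    min2 <- spec$min_separation^2
    tries <- 0L
    i <- 1L
    while (i <= n) {
      x <- stats::runif(1, margin, spec$width - margin)
      y <- stats::runif(1, margin, spec$height - margin)
      ok <- i == 1L ||
        min((xs[seq_len(i - 1L)] - x)^2 + (ys[seq_len(i - 1L)] - y)^2) >= min2
      if (ok) {
        xs[i] <- x; ys[i] <- y; i <- i + 1L
      }
      tries <- tries + 1L
      if (tries > 2000L * n + 10000L) {
        stopf("could not place %d spots with min_separation = %g", n,
              spec$min_separation)
      }
    }
    fl <- combo_flags(code)
    # log-normal total-stain amplitude, moment-matched to (mean, sd)
    m <- spec$amplitude_mean[1]; s <- spec$amplitude_sd[1]
    sdlog <- sqrt(log1p((s / m)^2))
    meanlog <- log(m) - sdlog^2 / 2
    amp_total <- stats::rlnorm(n, meanlog, sdlog)
    amp_marker <- function(k, on) {
      a <- numeric(n)
      a[on] <- rtruncnorm_lo(sum(on), spec$amplitude_mean[k],
                             spec$amplitude_sd[k], 1)
      a
    }
    data.frame(
      ev_id = seq_len(n), x = xs, y = ys,
      cd63 = fl$cd63, cd9 = fl$cd9, cd98 = fl$cd98,
      combination = code,
      amp_total = amp_total,
      amp_cd63 = amp_marker(2L, fl$cd63),
      amp_cd9 = amp_marker(3L, fl$cd9),
      amp_cd98 = amp_marker(4L, fl$cd98)
    )
  })
}

#' Render a synthetic multichannel field
#'
#' Renders every planted vesicle as an isotropic 2-D Gaussian spot
#' (sigma = `spec$psf_sigma`, truncated at 4 sigma, unit-sum kernel so
#' the spot integrates to its amplitude), applies spectral crosstalk as
#' a linear mixing of the noiseless spot signals, adds per-channel
#' background, then optional Poisson shot noise on signal + background
#' followed by Gaussian read noise. Intensities are rounded and clipped
#' to the unsigned 16-bit range. Rendering is deterministic given
#' `(spec, seed)`.
#'
#' @param spec A [field_spec()].
#' @param truth Ground-truth data.frame as from [sample_field_truth()].
#' @param seed Seed for the noise draws; defaults to `spec$seed`.
#' @return An object of class `ev_field`: list with `channels` (named
#'   list of 4 height x width integer matrices), `truth`, `spec`.
#' @export
render_field <- function(spec, truth, seed = spec$seed) {
  stopifnot(inherits(spec, "field_spec"))
  need <- c("ev_id", "x", "y", "amp_total", "amp_cd63", "amp_cd9", "amp_cd98")
  if (!all(need %in% names(truth))) stopf("`truth` lacks required columns")
  if (nrow(truth) > 0 &&
      (any(truth$x < 0 | truth$x > spec$width - 1) ||
       any(truth$y < 0 | truth$y > spec$height - 1))) {
    stopf("truth centers must lie inside the field")
  }
  amps <- as.matrix(truth[, c("amp_total", "amp_cd63", "amp_cd9", "amp_cd98")])
  if (nrow(truth) > 0 && any(amps < 0)) stopf("amplitudes must be non-negative")

  h <- spec$height; w <- spec$width
  signal <- lapply(1:4, function(i) matrix(0, h, w))
  r <- ceiling(4 * spec$psf_sigma)
  for (i in seq_len(nrow(truth))) {
    # 0-based center (x=col, y=row) -> 1-based pixel-center coordinates
    cx <- truth$x[i] + 1; cy <- truth$y[i] + 1
    cols <- max(1L, floor(cx) - r):min(w, ceiling(cx) + r)
    rows <- max(1L, floor(cy) - r):min(h, ceiling(cy) + r)
    kx <- exp(-(cols - cx)^2 / (2 * spec$psf_sigma^2))
    ky <- exp(-(rows - cy)^2 / (2 * spec$psf_sigma^2))
    kern <- outer(ky, kx)
    kern <- kern / sum(kern)
    for (k in 1:4) {
      a <- amps[i, k]
      if (a > 0) signal[[k]][rows, cols] <- signal[[k]][rows, cols] + a * kern
    }
  }
  # spectral crosstalk: observed_c = sum_k M[c,k] * signal_k (spot signal only)
  if (!isTRUE(all.equal(spec$crosstalk, diag(4), tolerance = 0))) {
    sig <- vapply(signal, identity, matrix(0, h, w))
    dim(sig) <- c(h * w, 4L)
    mixed <- sig %*% t(spec$crosstalk)
    signal <- lapply(1:4, function(k) matrix(mixed[, k], h, w))
  }
  channels <- with_seed(seed, lapply(1:4, function(k) {
    img <- signal[[k]] + spec$background_per_channel[k]
    if (spec$shot_noise) {
      img <- matrix(stats::rpois(h * w, lambda = pmax(img, 0)), h, w)
    }
    if (spec$read_noise_sigma > 0) {
      img <- img + stats::rnorm(h * w, 0, spec$read_noise_sigma)
    }
    over <- sum(img > 65535)
    if (over > 0) {
      message(sprintf("render_field: %d pixel(s) clipped at 65535 in channel %s",
                      over, CHANNELS[k]))
    }
    m <- matrix(as.integer(pmin(pmax(round(img), 0), 65535)), h, w)
    m
  }))
  names(channels) <- CHANNELS
  structure(list(channels = channels, truth = truth, spec = spec),
            class = "ev_field")
}

#' Simulate a complete synthetic field
#'
#' Convenience wrapper: samples ground truth with
#' [sample_field_truth()] and renders it with [render_field()], using
#' independent RNG streams derived from `seed`.
#'
#' @inheritParams sample_field_truth
#' @return An `ev_field` object.
#' @export
simulate_field <- function(spec, seed = spec$seed) {
  truth <- sample_field_truth(spec, seed = child_seed(seed, 1L))
  render_field(spec, truth, seed = child_seed(seed, 2L))
}

#' @export
print.ev_field <- function(x, ...) {
  cat(sprintf("<ev_field> %d x %d px, 4 channels (%s), %d planted EVs\n",
              x$spec$width, x$spec$height, paste(CHANNELS, collapse = ", "),
              nrow(x$truth)))
  invisible(x)
}
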