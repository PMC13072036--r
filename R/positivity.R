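# Mask transfer, background correction and positivity --------------------
#
# The label map derived from the total-stain channel defines, for every
# detected vesicle, a single pixel set that is applied unchanged to all
# marker channels. Per channel, a local background (median over an
# annulus around the component, excluding all foreground) is subtracted
# from the component mean, and a marker is called positive when the
# corrected mean exceeds k_sigma robust background standard deviations.

#' Positivity-calling parameters
#'
#' @param r_in,r_out Inner/outer dilation radii (px) of the local
#'   background annulus; `r_out > r_in >= 0`.
#' @param k_sigma Positivity threshold in robust background sd units; a
#'   marker is positive iff its background-corrected component mean
#'   exceeds `k_sigma * sigma_bg` (strictly above 0 when `sigma_bg` is
#'   0, as in noise-free renders).
#' @return List of class `positivity_params`.
#' @export
positivity_params <- function(r_in = 2L, r_out = 5L, k_sigma = 3) {
  if (!(r_out > r_in && r_in >= 0)) stopf("need r_out > r_in >= 0")
  if (k_sigma < 0) stopf("`k_sigma` must be >= 0")
  structure(list(r_in = as.integer(r_in), r_out = as.integer(r_out),
                 k_sigma = k_sigma), class = "positivity_params")
}

dilate_mask <- function(mask, radius) {
  if (radius <= 0) return(mask != 0)
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  brush <- EBImage::makeBrush(2L * radius + 1L, shape = "disc")
  EBImage::dilate(m, brush) > 0
}

# Absolute pixel indices of the background annulus around one component:
# dilate the component by r_in and r_out, difference, drop pixels of any
# foreground component. Returns integer(0) when the annulus is empty.
component_annulus <- function(labelmap, ev_id, r_in = 2L, r_out = 5L) {
  stopifnot(inherits(labelmap, "ev_labels"))
  if (!(r_out > r_in && r_in >= 0)) stopf("need r_out > r_in >= 0")
  lab <- labelmap$labels
  idx <- which(lab == ev_id)
  if (length(idx) == 0L) stopf("no component with label %d", ev_id)
  h <- nrow(lab)
  rows <- ((idx - 1L) %% h) + 1L
  cols <- ((idx - 1L) %/% h) + 1L
  pad <- r_out + 1L
  r0 <- max(1L, min(rows) - pad); r1 <- min(h, max(rows) + pad)
  c0 <- max(1L, min(cols) - pad); c1 <- min(ncol(lab), max(cols) + pad)
  sub <- lab[r0:r1, c0:c1, drop = FALSE]
  comp <- sub == ev_id
  ring <- dilate_mask(comp, r_out) & !dilate_mask(comp, r_in) & sub == 0L
  ridx <- which(ring)
  if (length(ridx) == 0L) return(integer(0))
  rr <- ((ridx - 1L) %% nrow(sub)) + r0
  cc <- ((ridx - 1L) %/% nrow(sub)) + c0
  (cc - 1L) * h + rr
}

#' Local background around one component
#'
#' Median intensity over the annulus obtained by dilating the component
#' by `r_in` and `r_out` pixels and differencing, with pixels belonging
#' to any foreground component excluded. Falls back to the global image
#' median when the annulus is empty.
#'
#' @param channel Intensity matrix.
#' @param labelmap `ev_labels` from the total-stain channel.
#' @param ev_id Component label.
#' @param r_in,r_out Annulus radii (px), `r_out > r_in >= 0`.
#' @return Scalar background intensity.
#' @export
local_background <- function(channel, labelmap, ev_id, r_in = 2L, r_out = 5L) {
  ann <- component_annulus(labelmap, ev_id, r_in, r_out)
  if (length(ann) == 0L) {
    message(sprintf("local_background: empty annulus for label %d; using global median",
                    ev_id))
    return(stats::median(as.numeric(channel)))
  }
  stats::median(channel[ann])
}

#' Robust per-channel background noise scale
#'
#' Median absolute deviation (scaled to the normal sd, constant 1.4826)
#' of the pixels outside the `r_out`-dilated foreground.
#'
#' @param channel Intensity matrix.
#' @param labelmap `ev_labels`.
#' @param r_out Exclusion dilation radius (px).
#' @return Scalar robust sd.
#' @export
background_sigma <- function(channel, labelmap, r_out = 5L) {
  bg <- !dilate_mask(labelmap$labels > 0L, r_out)
  if (!any(bg)) return(stats::mad(as.numeric(channel)))
  stats::mad(channel[bg])
}

#' Call marker positivity for one measurement
#'
#' @param corrected_mean Background-corrected component mean.
#' @param k_sigma Threshold in background sd units.
#' @param sigma_bg Robust background sd for the channel.
#' @return Logical: `corrected_mean > k_sigma * sigma_bg`, or
#'   `corrected_mean > 0` when `sigma_bg == 0`.
#' @export
call_positive <- function(corrected_mean, k_sigma = 3, sigma_bg = 0) {
  if (sigma_bg == 0) corrected_mean > 0 else
    corrected_mean > k_sigma * sigma_bg
}

#' Measure every detected vesicle across channels
#'
#' For each labeled component: the same pixel set is averaged in every
#' channel, a per-channel [local_background()] is subtracted (floored
#' at 0), and the three marker channels are called positive or negative
#' with [call_positive()] against per-channel [background_sigma()].
#'
#' @param field An `ev_field` (or a named list of 4 channel matrices).
#' @param labelmap `ev_labels` derived from the field's total-stain
#'   channel.
#' @param params A [positivity_params()].
#' @return data.frame of class `ev_measurements`, one row per component:
#'   `ev_id`, `x`, `y` (0-based centroid), `area`, then per channel
#'   `raw_<ch>`, `bg_<ch>`, `corr_<ch>`, plus `pos_cd63`, `pos_cd9`,
#'   `pos_cd98` and `combination` (code 0..7). The per-channel robust
#'   background sds are attached as attribute `"sigma_bg"`.
#' @export
measure_evs <- function(field, labelmap, params = positivity_params()) {
  channels <- if (inherits(field, "ev_field")) field$channels else field
  stopifnot(all(CHANNELS %in% names(channels)),
            inherits(labelmap, "ev_labels"))
  k <- labelmap$n_components
  sigma_bg <- vapply(CHANNELS, function(ch) {
    background_sigma(channels[[ch]], labelmap, params$r_out)
  }, numeric(1))
  raw <- matrix(NA_real_, k, 4L, dimnames = list(NULL, CHANNELS))
  bg <- raw
  if (k > 0L) {
    lab <- labelmap$labels
    idx_all <- which(lab > 0L)
    by_lab <- split(idx_all, lab[idx_all])
    global_median <- vapply(CHANNELS, function(ch) {
      stats::median(as.numeric(channels[[ch]]))
    }, numeric(1))
    for (i in seq_len(k)) {
      idx <- by_lab[[as.character(i)]]
      ann <- component_annulus(labelmap, i, params$r_in, params$r_out)
      for (ch in CHANNELS) {
        raw[i, ch] <- mean(channels[[ch]][idx])
        bg[i, ch] <- if (length(ann) > 0) {
          stats::median(channels[[ch]][ann])
        } else {
          global_median[[ch]]
        }
      }
    }
  }
  corr <- pmax(raw - bg, 0)
  pos <- matrix(FALSE, k, 3L, dimnames = list(NULL, c("cd63", "cd9", "cd98")))
  for (ch in colnames(pos)) {
    pos[, ch] <- as.logical(call_positive(corr[, ch], params$k_sigma,
                                          sigma_bg[[ch]]))
  }
  out <- data.frame(
    ev_id = seq_len(k),
    x = labelmap$centroid[, "x"], y = labelmap$centroid[, "y"],
    area = labelmap$area,
    raw_total = raw[, "total"], raw_cd63 = raw[, "cd63"],
    raw_cd9 = raw[, "cd9"], raw_cd98 = raw[, "cd98"],
    bg_total = bg[, "total"], bg_cd63 = bg[, "cd63"],
    bg_cd9 = bg[, "cd9"], bg_cd98 = bg[, "cd98"],
    corr_total = corr[, "total"], corr_cd63 = corr[, "cd63"],
    corr_cd9 = corr[, "cd9"], corr_cd98 = corr[, "cd98"],
    pos_cd63 = pos[, "cd63"], pos_cd9 = pos[, "cd9"],
    pos_cd98 = pos[, "cd98"],
    combination = combo_code(pos[, "cd63"], pos[, "cd9"], pos[, "cd98"])
  )
  attr(out, "sigma_bg") <- sigma_bg
  attr(out, "k_sigma") <- params$k_sigma
  class(out) <- c("ev_measurements", "data.frame")
  out
}

#' Tabulate marker co-expression
#'
#' Counts and fractions of the eight CD63/CD9/CD98 combinations among
#' all detected (total-stain positive) vesicles, plus per-marker
#' marginal fractions. When several fields are supplied, counts are
#' pooled across fields before fractions are formed.
#'
#' @param measurements An `ev_measurements` data.frame, or a list of
#'   them (one per field).
#' @return Object of class `coexpression_table`: list with `n_total`,
#'   `counts` and `fractions` (named 8-vectors in code order) and
#'   `marginals` (named fractions for `cd63`, `cd9`, `cd98`).
#' @export
coexpression_table <- function(measurements) {
  if (is.data.frame(measurements)) measurements <- list(measurements)
  code <- unlist(lapply(measurements, function(m) m$combination))
  n <- length(code)
  if (n == 0L) stopf("no measurements: co-expression fractions are undefined")
  counts <- tabulate(code + 1L, 8L)
  names(counts) <- combo_labels()
  fractions <- counts / n
  fl <- combo_flags(0:7)
  marginals <- c(cd63 = sum(fractions[fl$cd63]),
                 cd9 = sum(fractions[fl$cd9]),
                 cd98 = sum(fractions[fl$cd98]))
  structure(list(n_total = n, counts = counts, fractions = fractions,
                 marginals = marginals),
            class = "coexpression_table")
}

#' @export
print.coexpression_table <- function(x, digits = 3, ...) {
  cat(sprintf("<coexpression_table> %d detected EVs\n", x$n_total))
  df <- data.frame(count = x$counts,
                   fraction = round(x$fractions, digits))
  print(df)
  cat(sprintf("marginals: CD63 %.1f%%  CD9 %.1f%%  CD98 %.1f%%\n",
              100 * x$marginals["cd63"], 100 * x$marginals["cd9"],
              100 * x$marginals["cd98"]))
  invisible(x)
}

#' Export a co-expression table as CSV
#'
#' One row per combination (marker flags, count, fraction) plus a
#' marginals CSV if `marginals_path` is given.
#'
#' @param tab A `coexpression_table`.
#' @param path Combination CSV path.
#' @param marginals_path Optional marginals CSV path.
#' @return Invisibly, the combination data.frame.
#' @export
write_coexpression <- function(tab, path, marginals_path = NULL) {
  stopifnot(inherits(tab, "coexpression_table"))
  fl <- combo_flags(0:7)
  df <- data.frame(combination = names(tab$counts),
                   cd63 = fl$cd63, cd9 = fl$cd9, cd98 = fl$cd98,
                   count = as.integer(tab$counts),
                   fraction = as.numeric(tab$fractions))
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(marginals_path)) {
    utils::write.csv(
      data.frame(marker = names(tab$marginals),
                 fraction = as.numeric(tab$marginals)),
      marginals_path, row.names = FALSE)
  }
  invisible(df)
}
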