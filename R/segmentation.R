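# Spot segmentation ------------------------------------------------------
#
# Vesicles are detected in the total-stain channel only: global triangle
# threshold on a 256-bin histogram, binary opening + hole filling,
# connected-component labeling (8-connectivity by default) and an area
# gate that keeps diffraction-limited spots. The resulting label map is
# then transferred unchanged to the marker channels.

#' Segmentation parameters
#'
#' @param n_bins Histogram bins for the triangle threshold (default 256).
#' @param open_radius Disk radius (px) of the binary opening; 0 disables.
#' @param min_area,max_area Component area gate in px^2 (inclusive).
#' @param connectivity Pixel connectivity for labeling, 4 or 8.
#' @return List of class `segmentation_params`.
#' @export
segmentation_params <- function(n_bins = 256L, open_radius = 1L,
                                min_area = 2L, max_area = 80L,
                                connectivity = 8L) {
  if (!is_count(n_bins) || n_bins < 2) stopf("`n_bins` must be an integer >= 2")
  if (open_radius < 0) stopf("`open_radius` must be >= 0")
  if (!(min_area > 0 && min_area <= max_area)) {
    stopf("need 0 < min_area <= max_area")
  }
  if (!connectivity %in% c(4L, 8L)) stopf("`connectivity` must be 4 or 8")
  structure(list(n_bins = as.integer(n_bins),
                 open_radius = as.integer(open_radius),
                 min_area = as.numeric(min_area),
                 max_area = as.numeric(max_area),
                 connectivity = as.integer(connectivity)),
            class = "segmentation_params")
}

#' Intensity histogram over the observed range
#'
#' Bins image intensities into `n_bins` equal-width bins spanning
#' `[min(img), max(img)]` (not the dtype range, so low-contrast fields
#' use the full bin resolution).
#'
#' @param img Numeric matrix.
#' @param n_bins Number of bins.
#' @return List of class `ev_histogram` with `bin_edges` (`n_bins + 1`
#'   strictly increasing values) and `counts` (length `n_bins`, summing
#'   to the pixel count).
#' @export
build_histogram <- function(img, n_bins = 256L) {
  v <- as.numeric(img)
  if (!all(is.finite(v))) stopf("image contains non-finite values")
  lo <- min(v); hi <- max(v)
  if (hi <= lo) {
    stopf("degenerate histogram: image has a single intensity value")
  }
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  idx <- findInterval(v, edges, rightmost.closed = TRUE, all.inside = TRUE)
  structure(list(bin_edges = edges, counts = tabulate(idx, n_bins)),
            class = "ev_histogram")
}

#' Global triangle threshold
#'
#' Selects a threshold from a unimodal-with-tail histogram: draw the
#' chord from the histogram peak `(b_p, h_p)` to the farthest non-empty
#' bin `(b_e, h_e)` on the longer-tail side of the peak, and pick the
#' bin strictly between them whose point `(b, h_b)` has maximal
#' perpendicular distance to that chord. Ties in peak location take the
#' lowest bin; ties in tail length take the higher-intensity side; ties
#' in distance take the bin nearest the peak. The returned threshold is
#' the upper edge of the selected bin (pixels are foreground iff
#' strictly above it).
#'
#' @param hist An `ev_histogram` with at least two non-empty bins.
#' @return Threshold intensity (scalar) with attribute `"bin"`, the
#'   1-based index of the selected bin.
#' @export
triangle_threshold <- function(hist) {
  stopifnot(inherits(hist, "ev_histogram"))
  counts <- as.numeric(hist$counts)
  nz <- which(counts > 0)
  if (length(nz) < 2L) {
    stopf("degenerate histogram: fewer than two non-empty bins")
  }
  b_p <- which.max(counts)
  lo <- nz[1]; hi <- nz[length(nz)]
  # longer tail side; tie -> higher-intensity side
  b_e <- if ((hi - b_p) >= (b_p - lo)) hi else lo
  if (abs(b_e - b_p) <= 1L) {
    # no interior bin: threshold separates the two adjacent bins
    b <- min(b_p, b_e)
    thr <- hist$bin_edges[b + 1L]
    attr(thr, "bin") <- b
    return(thr)
  }
  cand <- if (b_e > b_p) (b_p + 1L):(b_e - 1L) else (b_e + 1L):(b_p - 1L)
  h_p <- counts[b_p]; h_e <- counts[b_e]
  # |cross product|; the common 1/||chord|| factor does not affect the argmax
  d <- abs((h_e - h_p) * (cand - b_p) - (b_e - b_p) * (counts[cand] - h_p))
  best <- d >= max(d) - 1e-9 * max(max(d), 1)
  b <- cand[best][which.min(abs(cand[best] - b_p))]
  thr <- hist$bin_edges[b + 1L]
  attr(thr, "bin") <- b
  thr
}

#' Morphological cleanup of a binary mask
#'
#' Binary opening with a disk structuring element of radius
#' `open_radius` followed by hole filling. Removes sub-resolution specks
#' while leaving compact spots intact; never creates foreground outside
#' the dilation of the input.
#'
#' @param mask Logical or 0/1 matrix.
#' @param params A [segmentation_params()].
#' @return Logical matrix of the same shape.
#' @export
morphological_clean <- function(mask, params = segmentation_params()) {
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  if (params$open_radius > 0) {
    brush <- EBImage::makeBrush(2L * params$open_radius + 1L, shape = "disc")
    m <- EBImage::opening(m, brush)
  }
  m <- EBImage::fillHull(m)
  matrix(m > 0, nrow(mask), ncol(mask))
}

#' Label connected components
#'
#' Flood-fill labeling of a binary mask under 4- or 8-connectivity.
#' Labels are assigned in raster-scan order of each component's first
#' pixel, so they are contiguous `1..K`.
#'
#' @param mask Logical matrix.
#' @param connectivity 4 or 8.
#' @return Object of class `ev_labels`: list with `labels` (integer
#'   matrix), `n_components`, `area` (px^2 per component) and `centroid`
#'   (K x 2 matrix of 0-based `x` = column, `y` = row means).
#' @export
label_components <- function(mask, connectivity = 8L) {
  if (!connectivity %in% c(4L, 8L)) stopf("`connectivity` must be 4 or 8")
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  fg <- which(mask)
  if (connectivity == 8L) {
    dr <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
    dc <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  } else {
    dr <- c(-1L, 1L, 0L, 0L)
    dc <- c(0L, 0L, -1L, 1L)
  }
  k <- 0L
  stack <- integer(length(fg))
  for (p in fg) {
    if (lab[p] != 0L) next
    k <- k + 1L
    lab[p] <- k
    top <- 1L
    stack[1L] <- p
    while (top > 0L) {
      q <- stack[top]; top <- top - 1L
      r0 <- ((q - 1L) %% h) + 1L
      c0 <- ((q - 1L) %/% h) + 1L
      for (j in seq_along(dr)) {
        rr <- r0 + dr[j]; cc <- c0 + dc[j]
        if (rr >= 1L && rr <= h && cc >= 1L && cc <= w) {
          qq <- (cc - 1L) * h + rr
          if (mask[qq] && lab[qq] == 0L) {
            lab[qq] <- k
            top <- top + 1L
            stack[top] <- qq
          }
        }
      }
    }
  }
  labels_from_matrix(lab, k)
}

# Build the ev_labels structure (areas, 0-based centroids) from a label
# matrix with labels 1..k.
labels_from_matrix <- function(lab, k) {
  if (k > 0L) {
    idx <- which(lab > 0L)
    l <- lab[idx]
    h <- nrow(lab)
    rows <- ((idx - 1L) %% h) + 1L
    cols <- ((idx - 1L) %/% h) + 1L
    area <- as.numeric(tabulate(l, k))
    cx <- as.numeric(rowsum(cols - 1, l)) / area
    cy <- as.numeric(rowsum(rows - 1, l)) / area
  } else {
    area <- numeric(0); cx <- numeric(0); cy <- numeric(0)
  }
  structure(list(labels = lab, n_components = k, area = area,
                 centroid = cbind(x = cx, y = cy)),
            class = "ev_labels")
}

#' Gate components by area
#'
#' Removes components whose pixel area falls outside
#' `[min_area, max_area]` and re-compacts the surviving labels to
#' `1..K'` preserving order.
#'
#' @param labelmap An `ev_labels` object.
#' @param min_area,max_area Inclusive area bounds (px^2).
#' @return A gated `ev_labels`; the number of removed components is
#'   reported via `message()`.
#' @export
area_gate <- function(labelmap, min_area, max_area) {
  stopifnot(inherits(labelmap, "ev_labels"))
  keep <- labelmap$area >= min_area & labelmap$area <= max_area
  dropped <- sum(!keep)
  if (dropped > 0) {
    message(sprintf("area_gate: removed %d component(s) outside [%g, %g] px^2",
                    dropped, min_area, max_area))
  }
  remap <- integer(labelmap$n_components)
  remap[keep] <- seq_len(sum(keep))
  lab <- labelmap$labels
  pos <- lab > 0L
  lab[pos] <- remap[lab[pos]]
  structure(list(labels = lab, n_components = sum(keep),
                 area = labelmap$area[keep],
                 centroid = labelmap$centroid[keep, , drop = FALSE]),
            class = "ev_labels")
}

#' Segment vesicle spots in the total-stain channel
#'
#' Full detection chain: 256-bin histogram over the observed range,
#' global [triangle_threshold()], strict `>` binarization,
#' [morphological_clean()], connected-component labeling and
#' [area_gate()]. Deterministic; adding a constant to the image leaves
#' the result unchanged (the histogram, and hence the threshold, shift
#' with it).
#'
#' @param img 2-D intensity matrix (the total-stain channel) or an
#'   `ev_field` (its total channel is used).
#' @param params A [segmentation_params()].
#' @return An `ev_labels` object.
#' @export
segment_field <- function(img, params = segmentation_params()) {
  if (inherits(img, "ev_field")) img <- img$channels$total
  stopifnot(is.matrix(img))
  hist <- build_histogram(img, params$n_bins)
  thr <- triangle_threshold(hist)
  mask <- img > as.numeric(thr)
  mask <- morphological_clean(mask, params)
  lm <- label_components(mask, params$connectivity)
  area_gate(lm, params$min_area, params$max_area)
}

#' @export
print.ev_labels <- function(x, ...) {
  cat(sprintf("<ev_labels> %d x %d px, %d component(s)\n",
              nrow(x$labels), ncol(x$labels), x$n_components))
  if (x$n_components > 0) {
    cat(sprintf("  area: median %.1f px^2, range [%g, %g]\n",
                stats::median(x$area), min(x$area), max(x$area)))
  }
  invisible(x)
}

#' Export a label map
#'
#' Writes the label matrix as a 16-bit TIFF and the per-component table
#' (label, area, centroid) as CSV.
#'
#' @param labelmap An `ev_labels`.
#' @param tiff_path,csv_path Output paths.
#' @return Invisibly, the component data.frame.
#' @export
write_labelmap <- function(labelmap, tiff_path, csv_path) {
  stopifnot(inherits(labelmap, "ev_labels"))
  tiff::writeTIFF(labelmap$labels / 65535, tiff_path, bits.per.sample = 16L,
                  compression = "none")
  df <- data.frame(label = seq_len(labelmap$n_components),
                   area = labelmap$area,
                   centroid_x = labelmap$centroid[, "x"],
                   centroid_y = labelmap$centroid[, "y"])
  utils::write.csv(df, csv_path, row.names = FALSE)
  invisible(df)
}
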