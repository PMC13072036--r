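# Field I/O --------------------------------------------------------------
#
# On disk a field is a 4-page 16-bit TIFF (fixed page order: total-stain,
# CD63, CD9, CD98) plus two plain-text sidecars next to it: the planted
# ground truth as CSV and the generating field_spec as JSON (which also
# records the channel order).

field_sidecars <- function(path) {
  base <- sub("\\.tiff?$", "", path, ignore.case = TRUE)
  list(truth = paste0(base, "_truth.csv"), spec = paste0(base, "_spec.json"))
}

#' Write and read synthetic fields
#'
#' `write_field()` stores the four channels as a multi-page 16-bit TIFF
#' (page order `total, cd63, cd9, cd98`, recorded in the TIFF
#' description tag and in the JSON sidecar), the ground truth as a
#' sidecar CSV (`<base>_truth.csv`, one row per vesicle) and the
#' generating spec as JSON (`<base>_spec.json`). `read_field()`
#' reverses this; the round trip is lossless for channel data and
#' truth.
#'
#' @param field An `ev_field` object.
#' @param path TIFF file path.
#' @return `write_field()` returns `path` invisibly; `read_field()`
#'   returns an `ev_field`.
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "ev_field"))
  pages <- lapply(field$channels, function(ch) {
    m <- ch / 65535
    attr(m, "description") <- paste(CHANNELS, collapse = ",")
    m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  sc <- field_sidecars(path)
  utils::write.csv(field$truth, sc$truth, row.names = FALSE)
  spec <- field$spec
  spec$crosstalk <- as.vector(spec$crosstalk)
  spec$channel_order <- CHANNELS
  jsonlite::write_json(unclass(spec), sc$spec, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  if (!file.exists(path)) stopf("no such field file: %s", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (length(pages) != 4L) {
    stopf("field TIFF must have 4 channel pages (%s); found %d",
          paste(CHANNELS, collapse = ", "), length(pages))
  }
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stopf("channel pages disagree in shape")
  }
  channels <- lapply(pages, function(p) matrix(as.integer(p), nrow(p), ncol(p)))
  names(channels) <- CHANNELS
  sc <- field_sidecars(path)
  truth <- if (file.exists(sc$truth)) {
    utils::read.csv(sc$truth)
  } else NULL
  spec <- if (file.exists(sc$spec)) {
    js <- jsonlite::read_json(sc$spec, simplifyVector = TRUE)
    js$channel_order <- NULL
    js$crosstalk <- matrix(js$crosstalk, 4L, 4L)
    js$combination_freqs <- validate_combination_freqs(js$combination_freqs)
    do.call(field_spec, js)
  } else NULL
  structure(list(channels = channels, truth = truth, spec = spec),
            class = "ev_field")
}
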