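# File round-tripping for renders: 8-bit RGB PNG images, single-channel PNG
# masks holding class codes as pixel values, run-length JSON masks, and
# layout sidecar JSON.

#' Write / read a rendered ECG image as 8-bit RGB PNG
#'
#' @param image H x W x 3 array, values 0-255.
#' @param path File path.
#' @return `write_ecg_png()` returns `path` invisibly; `read_ecg_png()`
#'   returns the integer image array.
#' @export
write_ecg_png <- function(image, path) {
  png::writePNG(image / 255, path)
  invisible(path)
}

#' @rdname write_ecg_png
#' @export
read_ecg_png <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 2L) arr <- array(arr, dim = c(dim(arr), 1L))
  out <- array(as.integer(round(arr[, , 1:min(3, dim(arr)[3]), drop = FALSE] * 255)),
               dim = c(dim(arr)[1:2], min(3, dim(arr)[3])))
  if (dim(out)[3] == 1L) out <- array(rep(out, 3L), dim = c(dim(out)[1:2], 3L))
  out
}

#' Write / read a pixel mask as single-channel PNG
#'
#' Class codes are stored directly as 8-bit pixel values (0-7), so the files
#' look almost black in a viewer but round-trip exactly.
#'
#' @param mask H x W integer matrix of wave-class codes.
#' @param path File path.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask / 255, path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3L) arr <- arr[, , 1L]
  matrix(as.integer(round(arr * 255)), nrow = nrow(arr))
}

#' Run-length-encoded JSON form of a mask
#'
#' Row-major run-length encoding: `{h, w, values, lengths}`.
#'
#' @param mask H x W integer matrix.
#' @param path File path.
#' @export
write_mask_rle <- function(mask, path) {
  r <- rle(as.integer(t(mask)))
  writeLines(jsonlite::toJSON(
    list(h = nrow(mask), w = ncol(mask),
         values = r$values, lengths = r$lengths),
    auto_unbox = TRUE
  ), path)
  invisible(path)
}

#' @rdname write_mask_rle
#' @export
read_mask_rle <- function(path) {
  x <- jsonlite::fromJSON(path)
  v <- inverse.rle(structure(list(lengths = x$lengths, values = x$values),
                             class = "rle"))
  matrix(as.integer(v), nrow = x$h, byrow = TRUE)
}

#' Write / read layout metadata as sidecar JSON
#'
#' @param layout An `ecg_layout` from [build_layout()].
#' @param path File path.
#' @export
write_layout_json <- function(layout, path) {
  writeLines(jsonlite::toJSON(
    list(px_per_mm = layout$px_per_mm, px_per_second = layout$px_per_second,
         px_per_mv = layout$px_per_mv, width = layout$width,
         height = layout$height, trace_width = layout$trace_width,
         leads = layout$leads),
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  ), path)
  invisible(path)
}

#' @rdname write_layout_json
#' @export
read_layout_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  structure(
    list(px_per_mm = x$px_per_mm, px_per_second = x$px_per_second,
         px_per_mv = x$px_per_mv, width = as.integer(x$width),
         height = as.integer(x$height), trace_width = as.integer(x$trace_width),
         leads = tibble::as_tibble(x$leads)),
    class = "ecg_layout"
  )
}
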