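#' Binary mask and label map raster I/O
#'
#' Expert masks arrive as binary raster images; label maps are exported as
#' grayscale PNGs with evenly spaced levels (0 = unclassified).
#'
#' @name mask_io
NULL

#' @rdname mask_io
#' @param mask logical matrix.
#' @param path output PNG path.
#' @return invisibly, `path`.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask)), path)
  invisible(path)
}

#' @rdname mask_io
#' @param threshold gray level above which a pixel counts as foreground.
#' @return logical matrix.
#' @export
read_mask_png <- function(path, threshold = 0.5) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img > threshold
}

#' @rdname mask_io
#' @param lm a [label_map()].
#' @return invisibly, `path`.
#' @export
write_labels_png <- function(lm, path) {
  png::writePNG(lm$labels / length(lm$classes), path)
  invisible(path)
}

#' @rdname mask_io
#' @param classes class names the PNG levels encode.
#' @return a [label_map()].
#' @export
read_labels_png <- function(path, classes) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  label_map(matrix(as.integer(round(img * length(classes))), nrow(img)),
            classes)
}
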