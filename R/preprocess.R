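#' Median filter specification
#'
#' Impulse noise on the targeted acquisitions arrives in clusters of at most
#' two pixels, so the default 3 x 3 mask is sufficient to remove it without
#' blurring region boundaries.
#'
#' @param mask_rows,mask_cols odd positive mask dimensions (default 3 x 3).
#' @param edge_policy how pixels beyond the image border are supplied:
#'   `"reflect"` mirrors the image at the border (default; keeps the
#'   reference stripe at row 1 undarkened, which matters because the stripe
#'   feeds calibration), `"replicate"` repeats the edge pixel.
#' @return a `median_spec` object.
#' @export
median_spec <- function(mask_rows = 3L, mask_cols = 3L,
                        edge_policy = c("reflect", "replicate")) {
  edge_policy <- match.arg(edge_policy)
  hs_assert(mask_rows >= 1 && mask_rows %% 2 == 1, "hs_parameter_error",
            "mask_rows must be odd and positive, got %s", toString(mask_rows))
  hs_assert(mask_cols >= 1 && mask_cols %% 2 == 1, "hs_parameter_error",
            "mask_cols must be odd and positive, got %s", toString(mask_cols))
  structure(list(mask_rows = as.integer(mask_rows),
                 mask_cols = as.integer(mask_cols),
                 edge_policy = edge_policy),
            class = "median_spec")
}

#' Per-band median filtering of a cube
#'
#' Each band image is filtered independently with a 2-D median mask; there
#' is no smoothing along the spectral axis.  Output dimensions are
#' unchanged and the output value range is a subset of the input range (a
#' median never extrapolates).
#'
#' @param cube a [hyper_cube()].
#' @param spec a [median_spec()].
#' @return the filtered cube, stage `"filtered"`.
#' @export
median_filter_cube <- function(cube, spec = median_spec()) {
  d <- dim(cube)
  hs_assert(spec$mask_rows <= d[1] && spec$mask_cols <= d[2],
            "hs_parameter_error",
            "mask %d x %d exceeds image %d x %d",
            spec$mask_rows, spec$mask_cols, d[1], d[2])
  reflect <- spec$edge_policy == "reflect"
  out <- cube$values
  for (k in seq_len(d[3]))
    out[, , k] <- .cpp_median_filter(cube$values[, , k],
                                     spec$mask_rows, spec$mask_cols, reflect)
  cube_with_values(cube, out, stage = "filtered")
}

#' Median filter a single 2-D image
#'
#' @param img numeric matrix.
#' @param spec a [median_spec()].
#' @return filtered matrix of the same size.
#' @export
median_filter_image <- function(img, spec = median_spec()) {
  hs_assert(is.matrix(img), "hs_type_error", "`img` must be a matrix")
  hs_assert(spec$mask_rows <= nrow(img) && spec$mask_cols <= ncol(img),
            "hs_parameter_error", "mask exceeds image")
  .cpp_median_filter(img, spec$mask_rows, spec$mask_cols,
                     spec$edge_policy == "reflect")
}
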