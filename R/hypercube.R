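#' Hyperspectral cube container
#'
#' A `hyper_cube` holds a line-scan hyperspectral acquisition as a dense
#' 3-D array `values[m, n, k]` (row, column, band) together with its
#' wavelength axis and ground sampling.  The same container is carried
#' through the processing stages: `"raw"` camera counts, `"filtered"`
#' (after median filtering), `"calibrated"` (reflectance in `[0, 1]` after
#' white-stripe calibration) and `"normalized"` (after sequence
#' normalization).
#'
#' Row index 1 is the top of the frame: the white reference stripe, when
#' present, occupies the lowest row indices.
#'
#' @param values numeric 3-D array indexed `[row, column, band]`.
#' @param wavelengths_nm strictly increasing numeric vector, one wavelength
#'   per band, in nanometres.
#' @param pixel_pitch_um ground sample size of one (square) pixel in
#'   micrometres; the acquisitions this package targets use 130 um.
#' @param stage processing stage, one of `"raw"`, `"filtered"`,
#'   `"calibrated"`, `"normalized"`.
#' @param header_extra named list of verbatim ENVI header entries that are
#'   not interpreted but must survive a read/write round trip.
#' @return an object of class `hyper_cube`.
#' @examples
#' cube <- hyper_cube(array(runif(4 * 5 * 3), c(4, 5, 3)),
#'                    wavelengths_nm = c(450, 550, 650))
#' dim(cube)
#' @export
hyper_cube <- function(values, wavelengths_nm,
                       pixel_pitch_um = 130,
                       stage = c("raw", "filtered", "calibrated", "normalized"),
                       header_extra = list()) {
  stage <- match.arg(stage)
  hs_assert(is.array(values) && length(dim(values)) == 3L,
            "hs_type_error", "`values` must be a 3-D array [row, column, band]")
  k <- dim(values)[3]
  hs_assert(length(wavelengths_nm) == k, "hs_type_error",
            "need one wavelength per band (%d bands, %d wavelengths)",
            k, length(wavelengths_nm))
  hs_assert(all(diff(wavelengths_nm) > 0), "hs_type_error",
            "wavelengths must be strictly increasing")
  structure(
    list(values = values,
         wavelengths_nm = as.numeric(wavelengths_nm),
         pixel_pitch_um = pixel_pitch_um,
         stage = stage,
         header_extra = header_extra),
    class = "hyper_cube")
}

#' @export
dim.hyper_cube <- function(x) dim(x$values)

#' @export
print.hyper_cube <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<hyper_cube> %d x %d pixels, %d bands (%.1f-%.1f nm), stage: %s\n",
              d[1], d[2], d[3],
              min(x$wavelengths_nm), max(x$wavelengths_nm), x$stage))
  invisible(x)
}

#' Extract one spectral band as a 2-D image
#'
#' @param cube a [hyper_cube()].
#' @param k band index in `1..K`.
#' @return numeric matrix `M x N`.
#' @export
cube_band <- function(cube, k) {
  K <- dim(cube)[3]
  hs_assert(length(k) == 1L && k >= 1 && k <= K, "hs_index_error",
            "band index %s out of range 1..%d", toString(k), K)
  cube$values[, , k]
}

#' Extract the spectrum of one pixel
#'
#' @param cube a [hyper_cube()].
#' @param m,n row and column indices.
#' @return numeric vector of length `K`, named by wavelength (nm).
#' @export
pixel_spectrum <- function(cube, m, n) {
  d <- dim(cube)
  hs_assert(m >= 1 && m <= d[1] && n >= 1 && n <= d[2], "hs_index_error",
            "pixel (%s, %s) out of range %d x %d", toString(m), toString(n),
            d[1], d[2])
  v <- cube$values[m, n, ]
  names(v) <- format(cube$wavelengths_nm, trim = TRUE)
  v
}

# internal: replace values, keep metadata, optionally advance the stage
cube_with_values <- function(cube, values, stage = cube$stage) {
  cube$values <- values
  cube$stage <- stage
  cube
}
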