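#' Region-of-interest specification
#'
#' A rectangular ROI on the scene (strictly below the reference stripe)
#' from which per-band statistics and reference spectra are taken.  The
#' study-scale default is 150 x 150 pixels on the imaged hand.
#'
#' @param m0,n0 top-left corner (row, column), 1-based.
#' @param height,width ROI size in pixels (default 150 x 150).
#' @return a `roi_spec` object.
#' @export
roi_spec <- function(m0, n0, height = 150L, width = 150L) {
  hs_assert(m0 >= 1 && n0 >= 1 && height >= 1 && width >= 1,
            "hs_roi_error", "ROI indices and size must be positive")
  structure(list(m0 = as.integer(m0), n0 = as.integer(n0),
                 height = as.integer(height), width = as.integer(width)),
            class = "roi_spec")
}

.roi_check <- function(cube, roi, contour = NULL) {
  d <- dim(cube)
  hs_assert(roi$m0 + roi$height - 1L <= d[1] &&
              roi$n0 + roi$width - 1L <= d[2], "hs_roi_error",
            "ROI %dx%d at (%d, %d) does not fit inside %d x %d image",
            roi$height, roi$width, roi$m0, roi$n0, d[1], d[2])
  if (!is.null(contour))
    hs_assert(roi$m0 > max(contour), "hs_roi_error",
              "ROI overlaps the reference stripe (top row %d <= contour %d)",
              roi$m0, max(contour))
  invisible(TRUE)
}

#' Automatic ROI placement
#'
#' Binarizes the reference band below the stripe with an Otsu threshold,
#' takes the largest connected bright region (the imaged body part) and
#' places a square ROI where it is best covered by that region, preferring
#' positions near the region centroid.
#'
#' @param cube calibrated [hyper_cube()].
#' @param contour stripe contour from [detect_pattern_contour()]; `NULL`
#'   for cubes without a stripe.
#' @param size ROI side length in pixels.
#' @param k_ref band used for the brightness mask (default mid-spectrum).
#' @return a [roi_spec()].
#' @export
auto_roi <- function(cube, contour = NULL, size = 150L, k_ref = NULL) {
  d <- dim(cube)
  if (is.null(k_ref)) k_ref <- as.integer(ceiling(d[3] / 2))
  top <- if (is.null(contour)) 0L else max(contour)
  hs_assert(d[1] - top >= size && d[2] >= size, "hs_roi_error",
            "image too small for a %d x %d ROI below row %d", size, size, top)
  img <- cube_band(cube, k_ref)[(top + 1L):d[1], , drop = FALSE]
  mask <- img > otsu_threshold(as.vector(img))
  lab <- .cpp_label_components(mask)
  hs_assert(max(lab) > 0L, "hs_roi_error", "no bright region found")
  big <- which.max(tabulate(lab[lab > 0L]))
  comp <- lab == big
  idx <- which(comp, arr.ind = TRUE)
  cen <- colMeans(idx)
  # coverage of each size x size window via an integral image
  ii <- rbind(0, cbind(0, apply(apply(comp, 2, cumsum), 1, cumsum)))
  ii <- t(ii)  # restore orientation: ii[m + 1, n + 1] = sum comp[1:m, 1:n]
  Mr <- nrow(comp) - size + 1L; Nc <- ncol(comp) - size + 1L
  rows <- seq_len(Mr); cols <- seq_len(Nc)
  cov <- ii[rows + size, cols + size, drop = FALSE] -
    ii[rows, cols + size, drop = FALSE] -
    ii[rows + size, cols, drop = FALSE] + ii[rows, cols, drop = FALSE]
  best <- max(cov)
  cand <- which(cov == best, arr.ind = TRUE)
  d2 <- (cand[, 1] + (size - 1) / 2 - cen[1])^2 +
    (cand[, 2] + (size - 1) / 2 - cen[2])^2
  pick <- cand[which.min(d2), ]
  roi_spec(m0 = pick[1] + top, n0 = pick[2], height = size, width = size)
}

#' Per-band ROI statistics
#'
#' Mean, minimum and maximum brightness of the ROI for every band; the
#' band-mean curve drives the sequence normalization.
#'
#' @param cube a [hyper_cube()].
#' @param roi a [roi_spec()].
#' @param contour optional stripe contour; when given, the ROI is checked
#'   to lie strictly below it.
#' @return a `roi_band_stats` object with fields `mean`, `min`, `max`
#'   (length-K vectors) and `wavelengths_nm`.
#' @export
roi_band_stats <- function(cube, roi, contour = NULL) {
  .roi_check(cube, roi, contour)
  sub <- cube$values[roi$m0:(roi$m0 + roi$height - 1L),
                     roi$n0:(roi$n0 + roi$width - 1L), , drop = FALSE]
  flat <- matrix(sub, nrow = roi$height * roi$width)
  structure(list(mean = colMeans(flat),
                 min = apply(flat, 2, min),
                 max = apply(flat, 2, max),
                 wavelengths_nm = cube$wavelengths_nm,
                 roi = roi),
            class = "roi_band_stats")
}

#' @export
as.data.frame.roi_band_stats <- function(x, ...) {
  data.frame(k = seq_along(x$mean), wavelength_nm = x$wavelengths_nm,
             mean = x$mean, min = x$min, max = x$max)
}

#' Sequence normalization against the ROI band-mean curve
#'
#' Lighting, camera angle and individual variability shift the whole ROI
#' brightness curve up or down between acquisitions.  Because lighting
#' acts multiplicatively on reflectance, the cube is divided band-wise by
#' the ROI mean and rescaled to a common level:
#' `L_O(m,n,k) = L_K(m,n,k) * target / mean(k)`, clipped to `[0, 1]`.
#' After normalization the ROI band-mean curve is flat at `target`,
#' regardless of the acquisition's own brightness, so two acquisitions
#' differing only by a global gain normalize identically (the gain cancels
#' inside the factor).  The default target is mid-scale, 0.5, keeping
#' typical tissue reflectances well inside `[0, 1]`; pass
#' `target = mean(stats$mean)` to retain the acquisition's own level
#' instead (at the cost of gain invariance).
#'
#' @param cube calibrated [hyper_cube()].
#' @param stats [roi_band_stats()] computed from the same cube.
#' @param target common ROI band-mean level after normalization.
#' @param eps smallest admissible band mean.
#' @return the normalized cube, stage `"normalized"`, carrying the applied
#'   per-band factors in `$norm_factor`.
#' @export
normalize_sequence <- function(cube, stats, target = 0.5, eps = 1e-6) {
  d <- dim(cube)
  hs_assert(length(stats$mean) == d[3], "hs_type_error",
            "stats have %d bands, cube has %d", length(stats$mean), d[3])
  hs_assert(is.numeric(target) && target > 0 && target <= 1,
            "hs_parameter_error", "target must lie in (0, 1]")
  if (any(stats$mean <= eps))
    hs_stop("hs_degenerate_band",
            "%d band mean(s) <= %g: cannot normalize", sum(stats$mean <= eps), eps)
  factor <- target / stats$mean
  out <- cube$values
  for (k in seq_len(d[3])) out[, , k] <- pmin(1, out[, , k] * factor[k])
  res <- cube_with_values(cube, out, stage = "normalized")
  res$norm_factor <- factor
  res
}

#' Carry a reference spectrum into the normalized scale
#'
#' Reference spectra are defined on the calibrated reflectance scale;
#' before comparing them with a cube processed by [normalize_sequence()]
#' they must undergo the same per-band scaling (and clipping).
#'
#' @param ref a [reference_spectrum()].
#' @param x either the normalized cube returned by [normalize_sequence()]
#'   or the [roi_band_stats()] the normalization used.
#' @param target the normalization target, when `x` is a `roi_band_stats`.
#' @return the transformed [reference_spectrum()].
#' @export
normalize_reference <- function(ref, x, target = 0.5) {
  factor <- if (inherits(x, "hyper_cube")) {
    hs_assert(!is.null(x$norm_factor), "hs_type_error",
              "cube carries no normalization factors")
    x$norm_factor
  } else {
    target / x$mean
  }
  hs_assert(length(factor) == length(ref$values), "hs_spectrum_error",
            "factor length %d, reference length %d",
            length(factor), length(ref$values))
  ref$values <- pmin(1, ref$values * factor)
  ref
}
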