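#' Reference spectrum of a tissue class
#'
#' Per-band expected reflectance of a class (skin, tattoo, background, ...),
#' taken either from the mean spectrum of an ROI or from a literature-style
#' wavelength/reflectance table.
#'
#' @param class_name class label.
#' @param values numeric vector of reflectances in `[0, 1]`.
#' @param wavelengths_nm wavelengths the values are defined on; may be
#'   `NULL` when the values are already on the cube's grid.
#' @param provenance `"roi_mean"` or `"table"`.
#' @return a `reference_spectrum` object.
#' @export
reference_spectrum <- function(class_name, values, wavelengths_nm = NULL,
                               provenance = c("roi_mean", "table")) {
  provenance <- match.arg(provenance)
  hs_assert(all(is.finite(values)), "hs_spectrum_error",
            "reference '%s' contains non-finite values", class_name)
  if (!is.null(wavelengths_nm))
    hs_assert(length(wavelengths_nm) == length(values), "hs_spectrum_error",
              "wavelength/value length mismatch for '%s'", class_name)
  structure(list(class_name = class_name, values = as.numeric(values),
                 wavelengths_nm = wavelengths_nm, provenance = provenance),
            class = "reference_spectrum")
}

#' Resample a reference spectrum onto a cube's wavelength grid
#'
#' Linear interpolation; beyond the tabulated range the end values are
#' held constant.
#'
#' @param ref a [reference_spectrum()] with its own wavelength axis.
#' @param wavelengths_nm target grid.
#' @return the resampled [reference_spectrum()].
#' @export
resample_reference <- function(ref, wavelengths_nm) {
  hs_assert(!is.null(ref$wavelengths_nm), "hs_spectrum_error",
            "reference '%s' has no wavelength axis to resample from",
            ref$class_name)
  v <- approx(ref$wavelengths_nm, ref$values, xout = wavelengths_nm,
              rule = 2)$y
  reference_spectrum(ref$class_name, v, wavelengths_nm, ref$provenance)
}

#' Read a reference spectrum from a two-column CSV
#'
#' Expected columns: `wavelength_nm`, `reflectance`.
#'
#' @param path CSV file path.
#' @param class_name class label for the spectrum.
#' @return a [reference_spectrum()] with provenance `"table"`.
#' @export
read_reference_csv <- function(path, class_name) {
  df <- read.csv(path)
  hs_assert(all(c("wavelength_nm", "reflectance") %in% names(df)),
            "hs_format_error",
            "%s must have columns wavelength_nm, reflectance", path)
  reference_spectrum(class_name, df$reflectance, df$wavelength_nm,
                     provenance = "table")
}

#' Mean ROI spectrum as a reference
#'
#' @param cube a [hyper_cube()].
#' @param roi a [roi_spec()].
#' @param class_name class label.
#' @return a [reference_spectrum()] with provenance `"roi_mean"`.
#' @export
reference_from_roi <- function(cube, roi, class_name) {
  stats <- roi_band_stats(cube, roi)
  reference_spectrum(class_name, stats$mean, cube$wavelengths_nm, "roi_mean")
}

#' Spectral deviation map
#'
#' Per pixel, the mean absolute deviation of its spectrum from the
#' reference: `L_D(m,n) = (1/K) * sum_k |L_O(m,n,k) - L_zw(k)|`.  Low
#' values mean the pixel resembles the class; for inputs in `[0, 1]` the
#' map is in `[0, 1]`.
#'
#' @param cube normalized (or calibrated) [hyper_cube()].
#' @param ref a [reference_spectrum()] on the cube's band grid.
#' @return numeric matrix `M x N` of class `distance_map` with attribute
#'   `class_name`.
#' @export
distance_map <- function(cube, ref) {
  d <- dim(cube)
  hs_assert(length(ref$values) == d[3], "hs_spectrum_error",
            "reference '%s' has %d bands, cube has %d",
            ref$class_name, length(ref$values), d[3])
  acc <- matrix(0, d[1], d[2])
  for (k in seq_len(d[3]))
    acc <- acc + abs(cube$values[, , k] - ref$values[k])
  structure(acc / d[3], class = c("distance_map", "matrix"),
            class_name = ref$class_name)
}

#' Binarize a deviation map at tolerance p_w
#'
#' The threshold is the accepted mean spectral deviation: `p_w = 0.01`
#' admits pixels within 1% of the reference, `p_w = 0.1` within 10%.
#'
#' @param dmap a [distance_map()].
#' @param p_w tolerance in `(0, 1)`.
#' @return logical matrix, `TRUE` where the pixel is within tolerance.
#' @export
binarize_map <- function(dmap, p_w) {
  hs_assert(is.numeric(p_w) && length(p_w) == 1L && p_w > 0 && p_w < 1,
            "hs_parameter_error", "p_w must lie in (0, 1)")
  unclass(dmap) < p_w
}

#' Area-versus-threshold curve
#'
#' `A(p_w)` counts the pixels accepted at each tolerance of the grid.  The
#' curve is non-decreasing by construction; a plateau ("flat region")
#' marks a range of thresholds over which the segmented object is stable.
#'
#' @param dmap a [distance_map()].
#' @param grid increasing vector of thresholds inside `(0, 1)`; default
#'   `0.01, 0.02, ..., 0.99`.
#' @return a `threshold_curve` object: list with `p_w`, `area` and
#'   `n_pixels`.
#' @export
area_curve <- function(dmap, grid = seq(0.01, 0.99, by = 0.01)) {
  hs_assert(length(grid) > 0, "hs_parameter_error", "empty threshold grid")
  hs_assert(all(grid > 0 & grid < 1), "hs_parameter_error",
            "grid must lie inside (0, 1)")
  hs_assert(!is.unsorted(grid, strictly = TRUE), "hs_parameter_error",
            "grid must be strictly increasing")
  d <- sort(as.vector(unclass(dmap)))
  # A(p) = #{d < p}: position of p in the sorted deviations
  area <- findInterval(grid, d, left.open = TRUE)
  threshold_curve(grid, area, length(d))
}

#' @rdname area_curve
#' @param p_w threshold grid values.
#' @param area accepted-pixel counts for each grid value.
#' @param n_pixels total pixel count `M * N` of the underlying map.
#' @export
threshold_curve <- function(p_w, area, n_pixels) {
  hs_assert(length(p_w) == length(area), "hs_parameter_error",
            "grid/area length mismatch")
  hs_assert(all(diff(area) >= 0), "hs_parameter_error",
            "area must be non-decreasing in p_w")
  hs_assert(all(area <= n_pixels), "hs_parameter_error",
            "area exceeds the pixel count")
  structure(list(p_w = as.numeric(p_w), area = as.numeric(area),
                 n_pixels = n_pixels),
            class = "threshold_curve")
}

#' @export
as.data.frame.threshold_curve <- function(x, ...) {
  data.frame(p_w = x$p_w, area = x$area)
}

#' Select the binarization threshold
#'
#' Three policies:
#' * `"flat_region"` (default): the midpoint of the longest plateau of the
#'   area curve.  A grid interval is flat when its normalized slope
#'   `|dA| / (n_pixels * dp_w)` is below `s_tol`; runs where the object is
#'   empty throughout or already covers the whole image are not plateaus of
#'   a meaningful segmentation and are skipped.  If no flat run exists a
#'   `hs_no_flat_region` error is raised (callers typically fall back to
#'   Otsu).
#' * `"otsu"`: Otsu threshold of the deviation-map histogram (`dmap`
#'   required).
#' * `"manual"`: echoes `manual_value`.
#'
#' @param curve a [threshold_curve()].
#' @param policy `"flat_region"`, `"otsu"` or `"manual"`.
#' @param manual_value threshold to use under the manual policy.
#' @param dmap the [distance_map()], needed by the Otsu policy.
#' @param s_tol normalized-slope tolerance of the flat-region policy.
#' @return the selected threshold `p_w`.
#' @export
select_threshold <- function(curve,
                             policy = c("flat_region", "otsu", "manual"),
                             manual_value = NULL, dmap = NULL, s_tol = 0.05) {
  policy <- match.arg(policy)
  if (policy == "manual") {
    hs_assert(is.numeric(manual_value) && manual_value > 0 && manual_value < 1,
              "hs_parameter_error", "manual policy needs manual_value in (0, 1)")
    return(manual_value)
  }
  hs_assert(is.null(manual_value), "hs_parameter_error",
            "manual_value only applies to the manual policy")
  if (policy == "otsu") {
    hs_assert(!is.null(dmap), "hs_parameter_error",
              "otsu policy needs the distance map")
    return(otsu_threshold(as.vector(unclass(dmap))))
  }
  p <- curve$p_w; a <- curve$area
  slope <- abs(diff(a)) / (curve$n_pixels * diff(p))
  flat <- slope < s_tol
  r <- rle(flat)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  best_w <- -1; best <- NULL
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    s <- starts[i]; e <- ends[i]    # intervals s..e cover p[s]..p[e+1]
    if (a[e + 1L] == 0 || a[s] == curve$n_pixels) next
    w <- p[e + 1L] - p[s]
    if (w > best_w) { best_w <- w; best <- c(s, e) }
  }
  if (is.null(best))
    hs_stop("hs_no_flat_region",
            "no flat run of the area curve below slope tolerance %g", s_tol)
  (p[best[1]] + p[best[2] + 1L]) / 2
}

#' Label map
#'
#' Discrete per-pixel class labels; `0` is the unclassified set, `1..C`
#' index `classes`.
#'
#' @param labels integer matrix of codes in `0..length(classes)`.
#' @param classes character vector of class names (no duplicates).
#' @return a `label_map` object.
#' @export
label_map <- function(labels, classes) {
  hs_assert(!anyDuplicated(classes), "hs_config_error",
            "duplicate class names")
  hs_assert(is.matrix(labels), "hs_type_error", "labels must be a matrix")
  lv <- sort(unique(as.vector(labels)))
  hs_assert(all(lv %in% 0:length(classes)), "hs_type_error",
            "label codes outside 0..%d", length(classes))
  structure(list(labels = matrix(as.integer(labels), nrow(labels)),
                 classes = as.character(classes)),
            class = "label_map")
}

#' Pixel counts per class
#'
#' @param lm a [label_map()].
#' @return data.frame with columns `class`, `pixels`, `share_pct`
#'   (percentage of the whole image); includes the `unclassified` row.
#'   Counts sum to `M * N`.
#' @export
label_counts <- function(lm) {
  total <- length(lm$labels)
  cnt <- tabulate(lm$labels + 1L, nbins = length(lm$classes) + 1L)
  data.frame(class = c(lm$classes, "unclassified"),
             pixels = c(cnt[-1], cnt[1]),
             share_pct = round(100 * c(cnt[-1], cnt[1]) / total, 1))
}

#' @export
print.label_map <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_map> %d x %d, classes: %s\n", d[1], d[2],
              toString(x$classes)))
  print(label_counts(x))
  invisible(x)
}

#' Multi-class spectral segmentation
#'
#' Computes the deviation of each pixel to every reference spectrum and
#' assigns the pixel to the closest class, provided that deviation is below
#' the tolerance `p_w`; otherwise the pixel stays unclassified.  Ties are
#' broken by reference order.
#'
#' @param cube normalized [hyper_cube()].
#' @param refs list of [reference_spectrum()] with distinct class names,
#'   on the cube's band grid.
#' @param p_w deviation tolerance in `(0, 1)`.
#' @return a [label_map()]; the per-class deviation maps are attached as
#'   attribute `distance_maps` (a named list) for reuse by
#'   [refine_labels()].
#' @export
multiclass_segment <- function(cube, refs, p_w) {
  hs_assert(length(refs) >= 1, "hs_config_error", "need at least one reference")
  nm <- vapply(refs, function(r) r$class_name, character(1))
  hs_assert(!anyDuplicated(nm), "hs_config_error", "duplicate class names: %s",
            toString(nm[duplicated(nm)]))
  hs_assert(p_w > 0 && p_w < 1, "hs_parameter_error", "p_w must lie in (0, 1)")
  dmaps <- lapply(refs, function(r) distance_map(cube, r))
  names(dmaps) <- nm
  d <- dim(cube)
  dm <- vapply(dmaps, as.vector, numeric(d[1] * d[2]))
  amin <- max.col(-dm, ties.method = "first")
  dmin <- dm[cbind(seq_len(nrow(dm)), amin)]
  lab <- ifelse(dmin < p_w, amin, 0L)
  out <- label_map(matrix(lab, d[1], d[2]), nm)
  attr(out, "distance_maps") <- dmaps
  out
}
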