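#' Otsu threshold over a 256-bin histogram
#'
#' Classical automatic threshold selection: the value range is split into
#' `bins` equal-width histogram bins and the cut maximizing the
#' between-class variance is chosen.  When several cuts tie (e.g. perfectly
#' separated classes), the midpoint of the tied run of candidate thresholds
#' is returned.
#'
#' @param values numeric vector with at least two distinct values.
#' @param bins number of histogram bins (default 256).
#' @return the threshold, a value inside the data range.
#' @export
otsu_threshold <- function(values, bins = 256L) {
  values <- as.numeric(values)
  values <- values[is.finite(values)]
  r <- range(values)
  hs_assert(length(values) >= 2 && diff(r) > 0, "hs_degenerate_histogram",
            "Otsu needs at least two distinct finite values")
  breaks <- seq(r[1], r[2], length.out = bins + 1L)
  idx <- findInterval(values, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  cnt <- tabulate(idx, nbins = bins)
  mids <- (breaks[-1] + breaks[-(bins + 1L)]) / 2
  w <- cumsum(cnt)
  mu <- cumsum(cnt * mids)
  tot <- w[bins]
  mu_t <- mu[bins]
  t <- seq_len(bins - 1L)
  w0 <- w[t]; w1 <- tot - w0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, bins - 1L)
  sigma_b[valid] <- w0[valid] * w1[valid] *
    (mu[t][valid] / w0[valid] - (mu_t - mu[t][valid]) / w1[valid])^2
  best <- which(sigma_b >= max(sigma_b) - 1e-12 * max(abs(sigma_b), 1))
  cand <- breaks[t + 1L]        # upper edge of the last class-0 bin
  (cand[min(best)] + cand[max(best)]) / 2
}

#' White-stripe search specification
#'
#' The reference pattern is a white stripe imaged across the full width at
#' the top of the frame.  At the nominal camera distance it covers about 80
#' rows, with a +/- 5 row uncertainty from frame shift or rotation, so the
#' lower boundary is searched for in rows `1..(expected_rows + tolerance)`.
#'
#' @param expected_rows nominal stripe height in rows (default 80).
#' @param tolerance extra rows searched beyond the nominal height
#'   (default 5).
#' @param p_r gradient binarization threshold, or `"auto"` to derive it
#'   from the gradients in the search window by [otsu_threshold()].
#' @return a `pattern_search_spec` object.
#' @export
pattern_search_spec <- function(expected_rows = 80L, tolerance = 5L,
                                p_r = "auto") {
  hs_assert(expected_rows >= 1, "hs_parameter_error",
            "expected_rows must be positive")
  hs_assert(tolerance >= 0, "hs_parameter_error", "tolerance must be >= 0")
  hs_assert(identical(p_r, "auto") || (is.numeric(p_r) && p_r > 0),
            "hs_parameter_error", "p_r must be 'auto' or a positive number")
  structure(list(expected_rows = as.integer(expected_rows),
                 tolerance = as.integer(tolerance), p_r = p_r),
            class = "pattern_search_spec")
}

#' Detect the lower boundary of the white reference stripe
#'
#' For every column the absolute brightness difference of adjacent rows is
#' computed inside the search window and binarized at `p_r` (Otsu over all
#' window gradients when `"auto"`).  The contour is the largest crossing
#' row per column - the stripe's boundary with the scene.  Columns without
#' a crossing (local stripe defects) inherit the median contour of the
#' columns that do cross; if fewer than 10% of columns cross, the stripe is
#' declared absent.
#'
#' The contour is treated as geometry, common to all bands; it is detected
#' on a single reference band, by default the mid-spectrum band where
#' stripe/scene contrast is high.
#'
#' @param cube a [hyper_cube()] (stage raw or filtered).
#' @param spec a [pattern_search_spec()].
#' @param k_ref band used for detection (default `ceiling(K / 2)`).
#' @return integer vector of per-column contour rows, with attributes
#'   `p_r` (threshold used), `k_ref` and `filled` (columns that inherited
#'   the median contour).
#' @export
detect_pattern_contour <- function(cube, spec = pattern_search_spec(),
                                   k_ref = NULL) {
  d <- dim(cube)
  win <- spec$expected_rows + spec$tolerance
  hs_assert(d[1] >= win + 1L, "hs_parameter_error",
            "cube has %d rows; stripe search needs at least %d", d[1], win + 1L)
  if (is.null(k_ref)) k_ref <- as.integer(ceiling(d[3] / 2))
  img <- cube_band(cube, k_ref)
  g <- abs(img[2:(win + 1L), , drop = FALSE] -
             img[1:win, , drop = FALSE])          # g[m, n]: edge below row m
  if (diff(range(g)) <= 1e-12)
    hs_stop("hs_pattern_not_found",
            "no brightness step in rows 1..%d: reference stripe not found", win)
  p_r <- if (identical(spec$p_r, "auto")) {
    tryCatch(otsu_threshold(as.vector(g)),
             hs_degenerate_histogram = function(e)
               hs_stop("hs_pattern_not_found", "degenerate gradients: %s",
                       conditionMessage(e)))
  } else spec$p_r
  contour <- apply(g > p_r, 2L, function(col) {
    w <- which(col)
    if (length(w)) max(w) else NA_integer_
  })
  crossing <- !is.na(contour)
  if (mean(crossing) < 0.10)
    hs_stop("hs_pattern_not_found",
            "only %.1f%% of columns show a stripe edge above p_r = %.4g",
            100 * mean(crossing), p_r)
  fill <- as.integer(round(median(contour[crossing])))
  contour[!crossing] <- fill
  structure(as.integer(contour), p_r = p_r, k_ref = k_ref,
            filled = which(!crossing))
}

#' Per-column, per-band mean brightness of the stripe
#'
#' For each column `n`, the mean of the cube over rows `1..contour[n]` is
#' the local 100%-reflectance level used for calibration.
#'
#' @param cube a [hyper_cube()].
#' @param contour integer vector of per-column contour rows (from
#'   [detect_pattern_contour()]).
#' @return numeric matrix `N x K` of pattern means.
#' @export
pattern_mean <- function(cube, contour) {
  d <- dim(cube)
  hs_assert(length(contour) == d[2], "hs_contour_error",
            "contour length %d does not match %d columns",
            length(contour), d[2])
  hs_assert(all(contour >= 1) && all(contour <= d[1]), "hs_contour_error",
            "contour rows must lie in 1..%d", d[1])
  top <- max(contour)
  # cumulative sums down the rows of the stripe window, per column and band
  cs <- apply(cube$values[seq_len(top), , , drop = FALSE], c(2, 3), cumsum)
  if (top == 1L) cs <- array(cs, c(1L, d[2], d[3]))   # apply drops the dim
  lw <- matrix(0, d[2], d[3])
  for (n in seq_len(d[2])) lw[n, ] <- cs[contour[n], n, ] / contour[n]
  lw
}

#' Calibration profile
#'
#' Bundles the detected stripe contour and the per-column/per-band pattern
#' means; the unit against which the scene is expressed as reflectance.
#'
#' @param contour per-column contour rows.
#' @param pattern_mean `N x K` matrix of stripe means (`L_w`).
#' @return a `calibration_profile` object.
#' @export
calibration_profile <- function(contour, pattern_mean) {
  hs_assert(is.matrix(pattern_mean) && nrow(pattern_mean) == length(contour),
            "hs_type_error", "pattern_mean must be an N x K matrix")
  structure(list(contour = as.integer(contour), pattern_mean = pattern_mean),
            class = "calibration_profile")
}

#' Build a calibration profile from a cube
#'
#' Convenience wrapper: detect the contour, then average the stripe.
#'
#' @inheritParams detect_pattern_contour
#' @return a [calibration_profile()].
#' @export
fit_calibration <- function(cube, spec = pattern_search_spec(), k_ref = NULL) {
  contour <- detect_pattern_contour(cube, spec, k_ref)
  prof <- calibration_profile(contour, pattern_mean(cube, contour))
  attr(prof, "p_r") <- attr(contour, "p_r")
  attr(prof, "k_ref") <- attr(contour, "k_ref")
  prof
}

#' Calibrate a cube to reflectance
#'
#' Every pixel is divided by the pattern mean of its column and band, so
#' values become fractions of the local white level; values above 1 (noise,
#' specular highlights) are clipped to 1.  Each band is calibrated
#' independently.
#'
#' @param cube a [hyper_cube()], normally median-filtered.
#' @param profile a [calibration_profile()].
#' @param eps smallest admissible pattern mean; anything darker signals an
#'   occluded or missing stripe.
#' @return the calibrated cube, stage `"calibrated"`, values in `[0, 1]`.
#' @export
calibrate_cube <- function(cube, profile, eps = 1e-6) {
  d <- dim(cube)
  lw <- profile$pattern_mean
  hs_assert(nrow(lw) == d[2] && ncol(lw) == d[3], "hs_type_error",
            "profile is %d x %d, cube needs %d x %d",
            nrow(lw), ncol(lw), d[2], d[3])
  if (any(lw <= eps))
    hs_stop("hs_dark_pattern",
            "%d pattern mean(s) <= %g: stripe occluded or missing",
            sum(lw <= eps), eps)
  out <- cube$values
  for (k in seq_len(d[3]))
    out[, , k] <- pmin(1, sweep(out[, , k], 2L, lw[, k], "/"))
  cube_with_values(cube, out, stage = "calibrated")
}

#' Write / read a calibration profile as a two-file CSV archive
#'
#' @param profile a [calibration_profile()].
#' @param base_path path prefix; `_contour.csv` and `_pattern_mean.csv` are
#'   appended.
#' @return `write_calibration_profile` invisibly returns the paths written;
#'   `read_calibration_profile` returns the profile.
#' @export
write_calibration_profile <- function(profile, base_path) {
  pc <- paste0(base_path, "_contour.csv")
  pm <- paste0(base_path, "_pattern_mean.csv")
  write.csv(data.frame(column = seq_along(profile$contour),
                       contour_row = profile$contour), pc, row.names = FALSE)
  write.csv(profile$pattern_mean, pm, row.names = FALSE)
  invisible(c(contour = pc, pattern_mean = pm))
}

#' @rdname write_calibration_profile
#' @export
read_calibration_profile <- function(base_path) {
  contour <- read.csv(paste0(base_path, "_contour.csv"))$contour_row
  lw <- as.matrix(read.csv(paste0(base_path, "_pattern_mean.csv")))
  dimnames(lw) <- NULL
  calibration_profile(contour, lw)
}
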