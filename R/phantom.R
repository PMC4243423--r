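#' Synthetic phantom specification
#'
#' Describes a synthetic line-scan acquisition with known ground truth:
#' a white reference stripe across the top of the frame (with optional
#' per-column edge jitter emulating frame shift/rotation), a large
#' skin-like region containing a dark tattoo patch, a spectrally distinct
#' background, column-wise lighting falloff, a smooth lamp spectrum,
#' Gaussian sensor noise and impulse noise in clusters of at most
#' `impulse_max_cluster` pixels.
#'
#' The class spectra are parametric stand-ins for real tissue optics:
#' skin combines a melanin-like exponential rise of reflectance with
#' wavelength with haemoglobin-like Gaussian absorption dips at 542 and
#' 577 nm; the tattoo is flat and dark; the background is a smooth ramp of
#' opposite slope to skin so that no skin/tattoo mixture resembles it.
#' The outermost pixel ring of the tattoo patch is rendered as a partial
#' volume mixture (`ring_mix` tattoo + rest skin) and counts as tattoo in
#' the ground truth - the hard case for threshold segmentation that the
#' conditional refinement is meant to fix.
#'
#' @param M,N,K rows, columns, bands.
#' @param wavelengths_nm band grid (default `K` points over 397-1030 nm).
#' @param stripe_rows nominal stripe height (default proportional to the
#'   study's 80 rows out of 899).
#' @param stripe_jitter per-column edge jitter in rows (default 2).
#' @param lighting_tilt relative column lighting falloff left to right
#'   (default 0.2, i.e. 20%).
#' @param skin_rect,tattoo_rect region rectangles `c(row0, row1, col0,
#'   col1)`; the tattoo must lie strictly inside the skin.
#' @param ring_mix tattoo weight of the partial-volume boundary ring.
#' @param exposure global exposure factor keeping the raw signal below
#'   full scale.
#' @param sigma Gaussian noise standard deviation (default 0.01).
#' @param impulse_density expected impulse clusters per pixel and band.
#' @param impulse_max_cluster largest impulse cluster in pixels (default 2).
#' @param roi suggested [roi_spec()] inside the skin, away from the tattoo.
#' @param seed RNG seed making the phantom fully reproducible.
#' @return a `phantom_spec` object.
#' @export
phantom_spec <- function(M = 180L, N = 260L, K = 64L,
                         wavelengths_nm = seq(397, 1030, length.out = K),
                         stripe_rows = max(3L, round(80 / 899 * M)),
                         stripe_jitter = 2L,
                         lighting_tilt = 0.2,
                         skin_rect = round(c(0.22 * M, 0.92 * M,
                                             0.15 * N, 0.85 * N)),
                         tattoo_rect = round(c(0.50 * M, 0.72 * M,
                                               0.46 * N, 0.65 * N)),
                         ring_mix = 0.65,
                         exposure = 0.85,
                         sigma = 0.01,
                         impulse_density = 5e-4,
                         impulse_max_cluster = 2L,
                         roi = NULL,
                         seed = 1L) {
  hs_assert(M >= 20 && N >= 20 && K >= 4, "hs_spec_error",
            "phantom needs at least 20 x 20 pixels and 4 bands")
  sr <- skin_rect; tr <- tattoo_rect
  hs_assert(sr[1] > stripe_rows + stripe_jitter, "hs_spec_error",
            "skin region must lie below the stripe")
  hs_assert(sr[2] <= M && sr[4] <= N, "hs_spec_error",
            "skin region must fit inside the image")
  hs_assert(tr[1] > sr[1] && tr[2] < sr[2] && tr[3] > sr[3] && tr[4] < sr[4],
            "hs_spec_error",
            "tattoo must lie strictly inside the skin (regions must not overlap)")
  hs_assert(ring_mix > 0.5 && ring_mix < 1, "hs_spec_error",
            "ring_mix must be in (0.5, 1): the ring is closer to the tattoo")
  hs_assert(impulse_density >= 0 && impulse_density <= 1, "hs_spec_error",
            "impulse_density must be in [0, 1]")
  hs_assert(sigma >= 0, "hs_spec_error", "sigma must be >= 0")
  if (is.null(roi)) {
    size <- min(round(0.33 * M), tr[3] - sr[3] - 2L, sr[2] - sr[1] - 2L)
    roi <- roi_spec(m0 = sr[1] + 3L, n0 = sr[3] + 3L,
                    height = size, width = size)
  }
  hs_assert(roi$m0 >= sr[1] && roi$m0 + roi$height - 1L <= sr[2] &&
              roi$n0 >= sr[3] && roi$n0 + roi$width - 1L <= sr[4],
            "hs_spec_error", "ROI must lie inside the skin region")
  hs_assert(roi$n0 + roi$width - 1L < tr[3] || roi$n0 > tr[4] ||
              roi$m0 + roi$height - 1L < tr[1] || roi$m0 > tr[2],
            "hs_spec_error", "ROI must not touch the tattoo")
  structure(list(M = as.integer(M), N = as.integer(N), K = as.integer(K),
                 wavelengths_nm = wavelengths_nm,
                 stripe_rows = as.integer(stripe_rows),
                 stripe_jitter = as.integer(stripe_jitter),
                 lighting_tilt = lighting_tilt,
                 skin_rect = as.integer(sr), tattoo_rect = as.integer(tr),
                 ring_mix = ring_mix, exposure = exposure, sigma = sigma,
                 impulse_density = impulse_density,
                 impulse_max_cluster = as.integer(impulse_max_cluster),
                 roi = roi, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' The study-scale phantom
#'
#' The desk-scale default (180 x 260 pixels, 64 bands) keeps the study's
#' layout - stripe height, region proportions, ROI placement - at roughly
#' one fifth linear scale so the full pipeline runs in seconds.
#' `full_size = TRUE` returns the full acquisition geometry
#' (899 x 1312 pixels, 800 bands, 80 stripe rows, 150 x 150 ROI).
#'
#' @param full_size use the full acquisition geometry.
#' @param seed RNG seed.
#' @param ... further arguments passed to [phantom_spec()].
#' @return a [phantom_spec()].
#' @export
default_study_phantom <- function(full_size = FALSE, seed = 1L, ...) {
  if (full_size) phantom_spec(M = 899L, N = 1312L, K = 800L,
                              stripe_rows = 80L, seed = seed, ...)
  else phantom_spec(seed = seed, ...)
}

# noise-free class reflectance curves ------------------------------------

phantom_skin_reflectance <- function(wl) {
  0.8 - 0.45 * exp(-(wl - 397) / 220) -
    0.08 * exp(-((wl - 542) / 12)^2 / 2) -
    0.06 * exp(-((wl - 577) / 12)^2 / 2)
}

phantom_background_reflectance <- function(wl) {
  0.75 - 0.5 * (wl - 397) / 633
}

phantom_lamp_gain <- function(wl) {
  0.7 + 0.3 * exp(-((wl - 650) / 300)^2)
}

.phantom_reflectances <- function(wl) {
  list(pattern = rep(1, length(wl)),
       background = phantom_background_reflectance(wl),
       skin = phantom_skin_reflectance(wl),
       tattoo = rep(0.03, length(wl)))
}

#' Generate a phantom acquisition
#'
#' Renders the raw cube (stage `"raw"`, values in `[0, 1]`), the exact
#' ground-truth label map and the noise-free class reference spectra.
#' Identical seeds give bit-identical output.
#'
#' @param spec a [phantom_spec()].
#' @return a `phantom_scene`: list with elements `cube` ([hyper_cube()]),
#'   `truth` ([label_map()] over classes pattern / background / skin /
#'   tattoo), `references` (list of [reference_spectrum()] on the
#'   calibrated reflectance scale), `roi` (suggested [roi_spec()]) and
#'   `spec`.
#' @export
make_phantom <- function(spec = default_study_phantom()) {
  set.seed(spec$seed)
  M <- spec$M; N <- spec$N; K <- spec$K
  wl <- spec$wavelengths_nm
  refl <- .phantom_reflectances(wl)

  # stripe lower edge per column, smoothed so it looks like shift/rotation
  edge <- rep(spec$stripe_rows, N)
  if (spec$stripe_jitter > 0) {
    raw <- sample(seq(-spec$stripe_jitter, spec$stripe_jitter), N,
                  replace = TRUE)
    sm <- if (N >= 9) as.integer(runmed(raw, 9)) else raw
    edge <- pmax(1L, spec$stripe_rows + sm)
  }

  classes <- c("pattern", "background", "skin", "tattoo")
  lab <- matrix(2L, M, N)
  sr <- spec$skin_rect; tr <- spec$tattoo_rect
  lab[sr[1]:sr[2], sr[3]:sr[4]] <- 3L
  lab[tr[1]:tr[2], tr[3]:tr[4]] <- 4L
  row_idx <- matrix(seq_len(M), M, N)
  lab[row_idx <= matrix(edge, M, N, byrow = TRUE)] <- 1L

  # per-class mixing weights; the tattoo's outermost ring is partial volume
  w <- lapply(classes, function(cl) matrix(0, M, N))
  names(w) <- classes
  for (ci in seq_along(classes)) w[[ci]][lab == ci] <- 1
  ring <- matrix(FALSE, M, N)
  ring[tr[1]:tr[2], tr[3]:tr[4]] <- TRUE
  if (tr[2] - tr[1] > 2 && tr[4] - tr[3] > 2)
    ring[(tr[1] + 1L):(tr[2] - 1L), (tr[3] + 1L):(tr[4] - 1L)] <- FALSE
  w$tattoo[ring] <- spec$ring_mix
  w$skin[ring] <- 1 - spec$ring_mix

  light <- 1 - spec$lighting_tilt * (seq_len(N) - 1) / (N - 1)
  gain <- phantom_lamp_gain(wl)
  n_imp <- round(spec$impulse_density * M * N)

  values <- array(0, c(M, N, K))
  for (k in seq_len(K)) {
    Rk <- w$pattern * refl$pattern[k] + w$background * refl$background[k] +
      w$skin * refl$skin[k] + w$tattoo * refl$tattoo[k]
    Lk <- sweep(Rk * spec$exposure * gain[k], 2L, light, "*")
    if (spec$sigma > 0) Lk <- Lk + rnorm(M * N, sd = spec$sigma)
    if (n_imp > 0) {
      at <- cbind(sample(M, n_imp, replace = TRUE),
                  sample(N, n_imp, replace = TRUE))
      sz <- sample(spec$impulse_max_cluster, n_imp, replace = TRUE)
      val <- sample(c(0, 1), n_imp, replace = TRUE)
      Lk[at] <- val
      ext <- sz > 1L
      if (any(ext)) {
        off <- matrix(c(0L, 1L, 0L, -1L, 1L, 0L, -1L, 0L), ncol = 2,
                      byrow = TRUE)
        nb <- at[ext, , drop = FALSE] +
          off[sample(4L, sum(ext), replace = TRUE), , drop = FALSE]
        nb[, 1] <- pmin(pmax(nb[, 1], 1L), M)
        nb[, 2] <- pmin(pmax(nb[, 2], 1L), N)
        Lk[nb] <- val[ext]
      }
    }
    values[, , k] <- pmin(1, pmax(0, Lk))
  }

  refs <- lapply(classes, function(cl)
    reference_spectrum(cl, refl[[cl]], wl, provenance = "table"))
  names(refs) <- classes

  structure(list(cube = hyper_cube(values, wl, stage = "raw"),
                 truth = label_map(lab, classes),
                 references = refs,
                 roi = spec$roi,
                 stripe_edge = edge,
                 spec = spec),
            class = "phantom_scene")
}
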