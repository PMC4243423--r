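test_that("Otsu separates well-separated classes and matches exhaustive search", {
  t1 <- otsu_threshold(c(0, 0, 0, 1, 1, 1))
  expect_gt(t1, 0); expect_lt(t1, 1)

  set.seed(99)
  x <- c(rnorm(5000, 0.2, 0.05), rnorm(5000, 0.8, 0.05))
  t2 <- otsu_threshold(x)
  expect_gt(t2, 0.3); expect_lt(t2, 0.7)
  binw <- diff(range(x)) / 256
  expect_lt(abs(t2 - oracle_otsu(x)), binw + 1e-12)

  # midpoint tie-break on a two-point sample
  t3 <- otsu_threshold(c(0, 1))
  expect_gt(t3, 0); expect_lte(t3, 1)
  expect_equal(t3, 0.5, tolerance = 0.01)

  expect_error(otsu_threshold(rep(0.3, 10)), class = "hs_degenerate_histogram")
})

test_that("Otsu equals the exhaustive oracle on assorted random inputs", {
  set.seed(123)
  for (rep in 1:6) {
    x <- switch(1 + rep %% 3,
                runif(2000),
                c(runif(500, 0, 0.3), runif(1500, 0.6, 1)),
                rbeta(1000, 2, 5))
    binw <- diff(range(x)) / 256
    expect_lt(abs(otsu_threshold(x) - oracle_otsu(x)), binw + 1e-12)
  }
})

test_that("a sharp stripe edge is detected exactly in every column", {
  cube <- stripe_cube(M = 30, N = 12, edge = 10)
  spec <- pattern_search_spec(expected_rows = 10, tolerance = 5)
  contour <- detect_pattern_contour(cube, spec)
  expect_identical(as.integer(contour), rep(10L, 12))

  edges <- rep(c(8L, 9L, 10L, 11L, 12L), length.out = 12)
  cube2 <- stripe_cube(M = 30, N = 12, edge = edges)
  contour2 <- detect_pattern_contour(cube2, spec)
  expect_identical(as.integer(contour2), edges)
})

test_that("a cube without a stripe raises pattern-not-found", {
  flat <- hyper_cube(array(0.3, c(30, 8, 2)), c(400, 500))
  expect_error(detect_pattern_contour(flat, pattern_search_spec(10, 5)),
               class = "hs_pattern_not_found")
})

test_that("columns without a crossing inherit the median contour", {
  edges <- rep(10L, 12)
  cube <- stripe_cube(M = 30, N = 12, edge = edges)
  cube$values[, 4, ] <- 0.3            # one dead column, no stripe
  contour <- detect_pattern_contour(cube, pattern_search_spec(10, 5))
  expect_identical(as.integer(contour), rep(10L, 12))
  expect_identical(attr(contour, "filled"), 4L)
})

test_that("pattern means average the stripe rows per column and band", {
  cube <- stripe_cube(M = 20, N = 6, K = 2, edge = 4, bright = 1)
  lw <- pattern_mean(cube, rep(4L, 6))
  expect_equal(lw, matrix(1, 6, 2))

  cube2 <- stripe_cube(M = 20, N = 6, K = 2, edge = 4, bright = 1)
  cube2$values[c(1, 3), , ] <- 0.8     # alternate 0.8 / 1.0 over 4 rows
  expect_equal(pattern_mean(cube2, rep(4L, 6)), matrix(0.9, 6, 2))

  g <- seq(0.5, 1, length.out = 6)     # linear column gradient in the stripe
  cube3 <- stripe_cube(M = 20, N = 6, K = 2, edge = 4, bright = 1)
  for (n in 1:6) cube3$values[1:4, n, ] <- g[n]
  expect_equal(pattern_mean(cube3, rep(4L, 6)),
               matrix(g, 6, 2), tolerance = 1e-12)

  expect_error(pattern_mean(cube, rep(0L, 6)), class = "hs_contour_error")
})

test_that("calibration divides by the column pattern mean and clips at 1", {
  cube <- stripe_cube(M = 10, N = 3, K = 1, edge = 2, bright = 0.9, scene = 0.45)
  prof <- calibration_profile(rep(2L, 3), matrix(0.9, 3, 1))
  cal <- calibrate_cube(cube, prof)
  expect_equal(cal$values[5, 1, 1], 0.5)        # 0.45 / 0.9
  expect_equal(cal$values[1, 1, 1], 1)          # pattern pixel / own mean
  expect_identical(cal$stage, "calibrated")

  cube$values[6, 1, 1] <- 1.5                   # above the white level
  cal2 <- calibrate_cube(cube, prof)
  expect_equal(cal2$values[6, 1, 1], 1)

  dark <- calibration_profile(rep(2L, 3), matrix(1e-9, 3, 1))
  expect_error(calibrate_cube(cube, dark), class = "hs_dark_pattern")
})

test_that("calibration removes multiplicative column lighting exactly", {
  # no median filter here: on a noise-free cube it would only smear the
  # column-lighting field across region edges and hide the exact algebra
  scene <- make_phantom(small_phantom(sigma = 0, lighting_tilt = 0.2))
  spec <- pattern_search_spec(scene$spec$stripe_rows, 5)
  prof <- fit_calibration(scene$cube, spec)
  cal <- calibrate_cube(scene$cube, prof)
  expect_true(all(cal$values >= 0 & cal$values <= 1))

  sr <- scene$spec$skin_rect
  skin_rows <- (sr[1] + 2):(sr[2] - 2)
  skin_cols <- (sr[3] + 2):(scene$spec$tattoo_rect[3] - 2)
  for (k in c(1, 4, 8)) {
    band <- cal$values[skin_rows, skin_cols, k]
    expect_lt(max(band) - min(band), 1e-6)      # spatially flat per band
  }
  # the pattern region means are 1 before clipping, hence exactly 1 here
  lw_cal <- pattern_mean(cal, prof$contour)
  expect_equal(lw_cal, matrix(1, dim(cal)[2], dim(cal)[3]), tolerance = 1e-9)
})

test_that("calibration is independent of row order below the stripe", {
  cube <- stripe_cube(M = 12, N = 4, K = 2, edge = 3)
  set.seed(2)
  cube$values[4:12, , ] <- array(runif(9 * 4 * 2), c(9, 4, 2))
  prof <- fit_calibration(cube, pattern_search_spec(3, 2))
  cal1 <- calibrate_cube(cube, prof)
  perm <- sample(4:12)
  cube2 <- cube
  cube2$values[4:12, , ] <- cube$values[perm, , ]
  cal2 <- calibrate_cube(cube2, prof)
  expect_equal(cal2$values[4:12, , ], cal1$values[perm, , ])
})

test_that("calibration profiles round trip through the CSV archive", {
  dir <- withr::local_tempdir()
  prof <- calibration_profile(c(3L, 4L, 3L), matrix(runif(6), 3, 2))
  write_calibration_profile(prof, file.path(dir, "p"))
  back <- read_calibration_profile(file.path(dir, "p"))
  expect_identical(back$contour, prof$contour)
  expect_equal(back$pattern_mean, prof$pattern_mean, tolerance = 1e-12)
})
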