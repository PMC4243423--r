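test_that("distance map measures mean absolute spectral deviation", {
  cube <- tiny_cube(3, 3, 8, stage = "normalized")
  ref <- reference_spectrum("x", cube$values[2, 2, ])
  dm <- distance_map(cube, ref)
  expect_equal(dm[2, 2], 0)

  off <- cube_with_values(cube, cube$values * 0 + 0.45)
  ref2 <- reference_spectrum("y", rep(0.4, 8))
  expect_equal(unclass(distance_map(off, ref2)),
               matrix(0.05, 3, 3), tolerance = 1e-12, ignore_attr = TRUE)

  expect_error(distance_map(cube, reference_spectrum("z", rep(0.1, 5))),
               class = "hs_spectrum_error")
})

test_that("distance map equals the direct-summation oracle", {
  set.seed(31)
  for (rep in 1:4) {
    cube <- tiny_cube(4, 4, 8, seed = rep, stage = "normalized")
    ref <- reference_spectrum("r", runif(8))
    expect_equal(unclass(distance_map(cube, ref)), oracle_distance(cube, ref),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("binarization thresholds express deviation tolerance", {
  dm <- structure(matrix(c(0.005, 0.05, 0.3, 0.8), 2, 2),
                  class = c("distance_map", "matrix"))
  expect_equal(sum(binarize_map(dm, 0.01)), 1)   # 1% tolerance
  expect_equal(sum(binarize_map(dm, 0.1)), 2)    # 10% tolerance
  expect_true(all(binarize_map(dm, 0.999)))
  expect_error(binarize_map(dm, 1.2), class = "hs_parameter_error")
  expect_error(binarize_map(dm, 0), class = "hs_parameter_error")
})

test_that("masks nest as the threshold grows and the area curve is monotone", {
  set.seed(8)
  dm <- structure(matrix(runif(400), 20, 20),
                  class = c("distance_map", "matrix"))
  grid <- seq(0.05, 0.95, by = 0.05)
  prev <- binarize_map(dm, grid[1])
  for (p in grid[-1]) {
    cur <- binarize_map(dm, p)
    expect_true(all(cur[prev]))                  # nesting
    prev <- cur
  }
  curve <- area_curve(dm, grid)
  expect_true(all(diff(curve$area) >= 0))
  expect_equal(curve$area, vapply(grid, function(p) sum(unclass(dm) < p),
                                  numeric(1)))

  const <- structure(matrix(0.5, 5, 5), class = c("distance_map", "matrix"))
  expect_equal(area_curve(const, c(0.4, 0.6))$area, c(0, 25))
  expect_error(area_curve(dm, numeric(0)), class = "hs_parameter_error")
})

test_that("flat-region selection returns the plateau midpoint", {
  grid <- seq(0.01, 0.99, by = 0.01)
  # plateau over [0.15, 0.30]: area constant there, rising on both sides
  area <- ifelse(grid <= 0.15, round(4000 * grid / 0.15),
                 ifelse(grid <= 0.30, 4000,
                        pmin(10000, 4000 + round(60000 * (grid - 0.30)))))
  curve <- threshold_curve(grid, area, 10000)
  expect_equal(select_threshold(curve, "flat_region"), 0.225, tolerance = 0.011)

  linear <- threshold_curve(grid, round(10000 * grid), 10000)
  expect_error(select_threshold(linear, "flat_region"),
               class = "hs_no_flat_region")
})

test_that("saturated and empty runs do not count as plateaus", {
  grid <- seq(0.01, 0.99, by = 0.01)
  # empty until 0.5, full from 0.6: the only informative plateau is absent;
  # leading all-zero and trailing full-coverage runs must not be selected
  area <- ifelse(grid < 0.5, 0, ifelse(grid < 0.6, round(100 * (grid - 0.5) * 1000), 5000))
  area <- pmin(area, 5000)
  curve <- threshold_curve(grid, area, 5000)
  expect_error(select_threshold(curve, "flat_region"),
               class = "hs_no_flat_region")
})

test_that("otsu and manual policies behave as documented", {
  set.seed(4)
  dm <- structure(matrix(c(runif(200, 0, 0.1), runif(200, 0.5, 0.6)), 20, 20),
                  class = c("distance_map", "matrix"))
  curve <- area_curve(dm)
  t_otsu <- select_threshold(curve, "otsu", dmap = dm)
  expect_gt(t_otsu, 0.1); expect_lt(t_otsu, 0.5)
  expect_equal(select_threshold(curve, "manual", manual_value = 0.2), 0.2)
  expect_error(select_threshold(curve, "manual"), class = "hs_parameter_error")
})

test_that("multi-class assignment picks the nearest admissible reference", {
  K <- 6
  refs <- list(reference_spectrum("a", rep(0.2, K)),
               reference_spectrum("b", rep(0.8, K)))
  vals <- array(0, c(2, 2, K))
  vals[1, 1, ] <- 0.2        # exactly a
  vals[1, 2, ] <- 0.75       # near b
  vals[2, 1, ] <- 0.5        # 0.3 from both: unclassified at p_w = 0.2
  vals[2, 2, ] <- 0.22       # near a
  cube <- hyper_cube(vals, seq(400, 900, 100), stage = "normalized")
  lm <- multiclass_segment(cube, refs, 0.2)
  expect_identical(lm$labels, matrix(c(1L, 0L, 2L, 1L), 2, 2))
  cnt <- label_counts(lm)
  expect_equal(sum(cnt$pixels), 4)
  expect_equal(cnt$pixels[cnt$class == "unclassified"], 1)

  expect_error(multiclass_segment(cube, list(refs[[1]], refs[[1]]), 0.2),
               class = "hs_config_error")
})

test_that("shrinking p_w only moves pixels to unclassified, never between classes", {
  scene <- make_phantom(small_phantom(sigma = 0.01, impulse_density = 5e-4))
  res <- run_pipeline(list(phantom = scene$spec, roi = "phantom",
                           references = "phantom"))
  lm_hi <- res$labels_raw
  lm_lo <- multiclass_segment(res$cube_normalized, res$references,
                              res$p_w / 2)
  moved <- lm_lo$labels != lm_hi$labels
  expect_true(all(lm_lo$labels[moved] == 0L))
  expect_equal(sum(label_counts(lm_lo)$pixels), prod(dim(lm_lo$labels)))
})

test_that("reference spectra resample onto the cube grid by interpolation", {
  ref <- reference_spectrum("lit", c(0.1, 0.5, 0.3), c(400, 600, 800),
                            provenance = "table")
  rs <- resample_reference(ref, c(400, 500, 700, 900))
  expect_equal(rs$values, c(0.1, 0.3, 0.4, 0.3))

  dir <- withr::local_tempdir()
  path <- file.path(dir, "ref.csv")
  write.csv(data.frame(wavelength_nm = c(400, 600, 800),
                       reflectance = c(0.1, 0.5, 0.3)), path, row.names = FALSE)
  back <- read_reference_csv(path, "lit")
  expect_equal(back$values, c(0.1, 0.5, 0.3))
  expect_identical(back$provenance, "table")
})
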