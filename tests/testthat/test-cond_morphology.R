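test_that("the default structuring element is the 13-pixel 5x5 disk", {
  se <- disk_se(5)
  expect_equal(sum(se), 13)
  expect_true(all(se == se[5:1, 5:1]))
  expect_false(se[1, 1]); expect_true(se[1, 3]); expect_true(se[3, 1])
})

test_that("local means match brute-force neighbourhood enumeration", {
  # constant guide, full mask
  g <- matrix(0.4, 6, 6)
  full <- matrix(TRUE, 6, 6)
  lm <- local_means(g, full)
  expect_equal(lm$s_re, matrix(0.4, 6, 6))
  expect_true(all(is.na(lm$s_rd)))

  # single-pixel mask: s_re is the guide value at that pixel
  single <- matrix(FALSE, 6, 6)
  single[3, 4] <- TRUE
  set.seed(55)
  g2 <- matrix(runif(36), 6, 6)
  lm2 <- local_means(g2, single)
  expect_equal(lm2$s_re[3, 4], g2[3, 4])

  # random instances vs the oracle
  for (rep in 1:5) {
    mask <- matrix(runif(36) > 0.5, 6, 6)
    g3 <- matrix(runif(36), 6, 6)
    got <- local_means(g3, mask)
    expect_equal(got$s_re, oracle_local_mean(g3, mask, disk_se(5), FALSE))
    expect_equal(got$s_rd, oracle_local_mean(g3, mask, disk_se(5), TRUE))
  }
  expect_error(local_means(matrix(1, 3, 3), matrix(TRUE, 3, 3), disk_se(5)),
               class = "hs_parameter_error")
})

test_that("p_we = 1 disables erosion; huge p_mn disables dilation", {
  set.seed(9)
  mask <- matrix(runif(100) > 0.4, 10, 10)
  guide <- matrix(runif(100), 10, 10)
  off <- cond_morph_spec(p_mn = 0.1, p_we = 1, p_wd = 0.5)
  expect_identical(conditional_erode(mask, guide, off), mask)
  hard <- cond_morph_spec(p_mn = 1e6, p_we = 0, p_wd = 1)
  expect_identical(conditional_dilate(mask, guide, hard), mask)
})

test_that("at p = 0 thresholds with a positive guide, operators are classical", {
  set.seed(17)
  spec0 <- cond_morph_spec(p_mn = 0, p_we = 0, p_wd = 0)
  for (rep in 1:4) {
    M <- sample(10:32, 1); N <- sample(10:32, 1)
    mask <- matrix(runif(M * N) > 0.6, M, N)
    guide <- matrix(runif(M * N, 0.1, 1), M, N)
    expect_identical(conditional_erode(mask, guide, spec0),
                     oracle_erode(mask, disk_se(5)))
    expect_identical(conditional_dilate(mask, guide, spec0),
                     oracle_dilate(mask, disk_se(5)))
  }
  # a compact island shrinks exactly as classical 5x5-round erosion
  island <- matrix(FALSE, 12, 12)
  island[5:7, 5:7] <- TRUE
  g <- matrix(1, 12, 12)
  expect_identical(conditional_erode(island, g, spec0),
                   oracle_erode(island, disk_se(5)))
})

test_that("erosion output is a subset and dilation a superset of the input", {
  set.seed(23)
  for (rep in 1:6) {
    mask <- matrix(runif(400) > 0.5, 20, 20)
    guide <- matrix(runif(400), 20, 20)
    spec <- cond_morph_spec(p_mn = runif(1, 0, 0.8), p_we = runif(1),
                            p_wd = runif(1))
    er <- conditional_erode(mask, guide, spec)
    di <- conditional_dilate(mask, guide, spec)
    expect_true(all(mask[er]))            # eroded set within the mask
    expect_true(all(di[mask]))            # mask within the dilated set
    expect_type(er, "logical"); expect_type(di, "logical")
  }
  empty <- matrix(FALSE, 10, 10)
  fullm <- matrix(TRUE, 10, 10)
  g <- matrix(0.5, 10, 10)
  spec <- cond_morph_spec(p_mn = 0.1, p_we = 0, p_wd = 0)
  expect_identical(conditional_erode(empty, g, spec), empty)
  expect_identical(conditional_dilate(fullm, g, spec), fullm)
})

test_that("a larger p_wd never dilates less", {
  set.seed(29)
  mask <- matrix(runif(225) > 0.7, 15, 15)
  guide <- matrix(runif(225, 0.05, 0.6), 15, 15)
  d0 <- conditional_dilate(mask, guide, cond_morph_spec(p_mn = 0.3, p_wd = 0))
  d1 <- conditional_dilate(mask, guide, cond_morph_spec(p_mn = 0.3, p_wd = 1))
  expect_true(all(d1[d0]))
})

test_that("refinement leaves a stable map unchanged when conditions never fire", {
  scene <- make_phantom(small_phantom())
  labels <- scene$truth
  guides <- lapply(seq_along(labels$classes), function(ci)
    matrix(0, dim(labels$labels)[1], dim(labels$labels)[2]))
  names(guides) <- labels$classes
  # zero guides: s_re * (1 - p_we) = 0 is never > p_mn = 0.5, same for s_rd
  spec <- cond_morph_spec(p_mn = 0.5, p_we = 0.5, p_wd = 0.5, iterations = 2)
  out <- refine_labels(labels, guides, spec)
  expect_identical(out$labels, labels$labels)
})

test_that("refinement eliminates unclassified pixels and conserves the count", {
  scene <- make_phantom(small_phantom(sigma = 0.01, impulse_density = 5e-4))
  res <- run_pipeline(list(phantom = scene$spec, roi = "phantom",
                           references = "phantom"))
  raw_cnt <- label_counts(res$labels_raw)
  ref_cnt <- label_counts(res$labels)
  expect_gt(raw_cnt$pixels[raw_cnt$class == "unclassified"], 0)
  expect_equal(ref_cnt$pixels[ref_cnt$class == "unclassified"], 0)
  expect_equal(sum(ref_cnt$pixels), prod(dim(res$labels$labels)))
})

test_that("refinement corrects partial-volume boundary loss of the tattoo", {
  scene <- make_phantom(small_phantom(sigma = 0.01, impulse_density = 5e-4,
                                      stripe_jitter = 2L))
  res <- run_pipeline(list(phantom = scene$spec, roi = "phantom",
                           references = "phantom"))
  truth_cnt <- label_counts(scene$truth)
  tattoo_truth <- truth_cnt$pixels[truth_cnt$class == "tattoo"]
  raw <- label_counts(res$labels_raw)
  fin <- label_counts(res$labels)
  err_raw <- delta_w(raw$pixels[raw$class == "tattoo"], tattoo_truth, digits = NULL)
  err_fin <- delta_w(fin$pixels[fin$class == "tattoo"], tattoo_truth, digits = NULL)
  expect_lt(err_fin, err_raw)
})

test_that("invalid morphology parameters are rejected", {
  expect_error(cond_morph_spec(p_mn = 0.1, p_we = 1.5), class = "hs_parameter_error")
  expect_error(cond_morph_spec(p_mn = 0.1, se = matrix(TRUE, 2, 2)),
               class = "hs_parameter_error")
  asym <- matrix(FALSE, 3, 3); asym[1, 1] <- TRUE
  expect_error(cond_morph_spec(p_mn = 0.1, se = asym), class = "hs_parameter_error")
})
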