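test_that("bone exclusion removes exactly the bone-proximal pixels", {
  n <- 40L; px <- 3
  aaa <- matrix(FALSE, n, n); aaa[10:20, 10:20] <- TRUE
  bone <- matrix(FALSE, n, n)

  # bone far away (or absent): ROI unchanged
  bone_far <- bone; bone_far[35:38, 35:38] <- TRUE
  expect_identical(derive_aaa_exc(aaa, bone_far, 8, px), aaa)

  # exclusion 0 with disjoint masks: unchanged
  bone_near <- bone; bone_near[22:25, 10:20] <- TRUE
  expect_identical(derive_aaa_exc(aaa, bone_near, 0, px), aaa)

  # brute-force distance oracle at 8 mm
  exc <- derive_aaa_exc(aaa, bone_near, 8, px)
  bidx <- which(bone_near, arr.ind = TRUE)
  for (k in which(aaa)) {
    i <- (k - 1L) %% n + 1L; j <- (k - 1L) %/% n + 1L
    dmin <- sqrt(min((bidx[, 1] - i)^2 + (bidx[, 2] - j)^2)) * px
    if (dmin <= 8) expect_false(exc[i, j]) else expect_true(exc[i, j])
  }

  # monotone shrinkage in the exclusion distance
  sizes <- sapply(c(0, 3, 6, 9), function(e)
    sum(derive_aaa_exc(aaa, bone_near, e, px)))
  expect_true(all(diff(sizes) <= 0))

  # removing everything is an error
  expect_error(derive_aaa_exc(aaa, bone_near, 200, px), "entire")
})

test_that("ROI max/mean match an exhaustive scan", {
  set.seed(5)
  v <- matrix(rnorm(30 * 30), 30, 30)
  img <- image_grid(v - min(v), 3)
  mask <- matrix(runif(900) < 0.3, 30, 30)
  r <- roi_suv(img, mask)
  # brute-force oracle
  mx <- -Inf; s <- 0; cnt <- 0
  for (i in 1:30) for (j in 1:30) if (mask[i, j]) {
    mx <- max(mx, img$values[i, j]); s <- s + img$values[i, j]; cnt <- cnt + 1
  }
  expect_identical(r$max, mx)
  expect_equal(r$mean, s / cnt, tolerance = 1e-12)

  cimg <- image_grid(matrix(2.5, 4, 4), 1)
  expect_identical(roi_suv(cimg, matrix(TRUE, 4, 4)), list(max = 2.5, mean = 2.5))
  expect_error(roi_suv(cimg, matrix(FALSE, 4, 4)), "empty")
})

test_that("cSUVmax and TBRmax follow their defining identities", {
  # group-mean consistency: SUVmax 3.32 with cSUVmax 2.61 implies blood 0.71
  expect_equal(csuv_max(3.32, 0.71), 2.61, tolerance = 1e-12)
  expect_identical(csuv_max(2, 2), 0)
  expect_identical(tbr_max(4, 4), 1)
  expect_identical(tbr_max(3.18, 1), 3.18)
  expect_error(tbr_max(3, 0), "positive")
  expect_error(tbr_max(3, -1), "positive")

  set.seed(6)
  for (i in 1:20) {
    t_ <- runif(1, 0, 10); b_ <- runif(1, 0.1, 3)
    expect_equal(csuv_max(t_, b_), t_ - b_, tolerance = 1e-15)
    # TBR = (cSUV + blood)/blood ties the two definitions together
    expect_equal(tbr_max(t_, b_), (csuv_max(t_, b_) + b_) / b_,
                 tolerance = 1e-12)
  }
})

test_that("percent difference and the 25% significance rule", {
  expect_identical(percent_difference(3, 3), 0)
  # worked comparison of the two techniques' group means
  expect_equal(round(percent_difference(2.85, 2.73), 2), 4.40)
  expect_identical(percent_difference(1, 2), -50)
  expect_error(percent_difference(1, 0), "nonzero")

  expect_false(classify_significant(25))
  expect_true(classify_significant(26))
  expect_true(classify_significant(70))
  expect_identical(classify_significant(c(10, 30), threshold = 25),
                   c(FALSE, TRUE))
})

test_that("spill-in factor partitions the aneurysm and takes the max ratio", {
  n <- 30L; px <- 3
  aaa <- matrix(FALSE, n, n); aaa[10:20, 10:16] <- TRUE
  bone <- matrix(FALSE, n, n); bone[10:20, 18:22] <- TRUE
  v <- matrix(1, n, n)
  v[15, 16] <- 3.18  # bone-proximal max
  v[15, 10] <- 2.09  # max in the remainder
  rep_ <- spill_in_factor(image_grid(v, px), aaa, bone, prone_mm = 10)
  expect_identical(rep_$max_prone, 3.18)
  expect_identical(rep_$max_rest, 2.09)
  expect_equal(round(rep_$factor, 2), 1.52)
  # sub-regions partition the ROI
  expect_identical(rep_$prone_mask | rep_$rest_mask, aaa)
  expect_false(any(rep_$prone_mask & rep_$rest_mask))

  u <- spill_in_factor(image_grid(matrix(2, n, n), px), aaa, bone, 10)
  expect_identical(u$factor, 1)

  expect_error(spill_in_factor(image_grid(v, px), aaa, bone, 0.1), "prone")
  expect_error(spill_in_factor(image_grid(v, px), aaa, bone, 500), "rest")
})

test_that("line profiles interpolate bilinearly between endpoints", {
  cimg <- image_grid(matrix(7, 20, 20), 2)
  p <- line_profile(cimg, c(2, 2), c(30, 30), 25)
  expect_identical(unique(p), 7)

  # n_samples = 2 returns exactly the endpoint samples
  set.seed(12)
  img <- image_grid(matrix(runif(400), 20, 20), 2)
  p2 <- line_profile(img, c(4, 6), c(20, 16), 2)
  expect_equal(p2, c(img$values[4, 3], img$values[9, 11]), tolerance = 1e-12)

  expect_error(line_profile(img, c(-5, 0), c(10, 10), 5), "inside")

  # profile through the phantom bone peaks inside the bone segment
  fx <- small_fixture()
  fit <- small_psf_fit()
  sp <- fx$spec
  start <- sp$aaa_center_mm - c(0, sp$aaa_outer_radius_mm + 10)
  end <- sp$bone_center_mm + c(0, sp$bone_radius_mm + 10)
  prof <- line_profile(fit$image, start, end, 80)
  tt <- seq(0, 1, length.out = 80)
  ys <- start[2] + tt * (end[2] - start[2])
  in_bone <- abs(ys - sp$bone_center_mm[2]) <= sp$bone_radius_mm
  expect_true(in_bone[which.max(prof)])
})

test_that("SUVmax over the full ROI dominates the excluded ROI", {
  fx <- small_fixture()
  fit <- small_psf_fit()
  m <- fx$phantom$masks
  expect_gte(roi_suv(fit$image, m$aaa)$max, roi_suv(fit$image, m$aaa_exc)$max)
  um <- uptake_metrics(fit$image, m$aaa, m$blood)
  expect_equal(um$csuv_max + um$suv_mean_b, um$suv_max_t, tolerance = 1e-12)
})
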