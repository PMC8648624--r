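make_geom <- function(n = 64L, n_angles = 48L, pixel_mm = 3) {
  n_bins <- 2L * as.integer(ceiling(sqrt(2) * n / 2)) + 1L
  projection_geometry(n_angles, n_bins, pixel_mm)
}

test_that("attenuation factors follow the analytic line integrals", {
  n <- 64L; geom <- make_geom(n)
  # air everywhere: mu = 0, all factors exp(0) = 1
  air <- image_grid(matrix(-1000, n, n), 3)
  m_air <- build_system_model(air, geom, psf_fwhm_mm = NULL)
  expect_equal(m_air$attenuation_factors,
               rep(1, geom$n_angles * geom$n_bins))

  # uniform water disc: central-bin factor = exp(-mu_water * 2r)
  co <- petbc:::pixel_coords(n, 3)
  c0 <- (n - 1) / 2 * 3
  r <- 45
  disc <- (co$x - c0)^2 + (co$y - c0)^2 <= r^2
  ct <- matrix(-1000, n, n); ct[disc] <- 0  # water is 0 HU
  mw <- build_system_model(image_grid(ct, 3), geom, psf_fwhm_mm = NULL)
  central <- (geom$n_bins + 1L) / 2L
  expect_equal(mw$attenuation_factors[central], exp(-0.0096 * 2 * r),
               tolerance = 1e-2)

  # doubling mu squares every factor (exp of a linear operator)
  mw2 <- build_system_model(image_grid(ct, 3), geom, psf_fwhm_mm = NULL,
                            mu_water = 2 * 0.0096,
                            bone_slope_per_hu = 2 * 5.5e-6)
  expect_equal(mw2$attenuation_factors, mw$attenuation_factors^2,
               tolerance = 1e-12)

  # HU below -1000 implies negative attenuation: rejected
  bad <- matrix(-1500, n, n)
  expect_error(build_system_model(image_grid(bad, 3), geom), "negative")
})

test_that("forward projection is linear and mass preserving", {
  n <- 64L; geom <- make_geom(n)
  m0 <- build_system_model(NULL, geom, psf_fwhm_mm = NULL,
                           grid_n = n, pixel_mm = 3)
  zero <- image_grid(matrix(0, n, n), 3)
  expect_identical(unique(as.vector(forward_project(zero, m0)$values)), 0)

  # single hot pixel: per-angle sums identical, mass at the projected bin
  img <- matrix(0, n, n); img[20, 41] <- 1
  s <- forward_project(image_grid(img, 3), m0)
  sums <- rowSums(s$values)
  expect_equal(max(sums) - min(sums), 0, tolerance = 1e-12 * max(sums))
  c0 <- (n - 1) / 2 * 3
  px <- (41 - 1) * 3 - c0; py <- (20 - 1) * 3 - c0
  for (a in c(1L, 13L, 25L, 37L)) {
    t_true <- px * cos(geom$angles[a]) + py * sin(geom$angles[a])
    prof <- s$values[a, ]
    t_axis <- ((seq_len(geom$n_bins)) - (geom$n_bins + 1) / 2) * geom$bin_mm
    t_hat <- sum(prof * t_axis) / sum(prof)
    expect_lte(abs(t_hat - t_true), geom$bin_mm)
    expect_lte(sum(prof > 0), 2L)  # translated delta: at most two bins
  }

  # linearity under PSF + attenuation
  fx <- small_fixture()
  set.seed(7)
  x1 <- matrix(runif(64^2), 64, 64); x2 <- matrix(runif(64^2), 64, 64)
  s1 <- forward_project(image_grid(x1, 3), fx$model)$values
  s2 <- forward_project(image_grid(x2, 3), fx$model)$values
  s12 <- forward_project(image_grid(2 * x1 + x2, 3), fx$model)$values
  expect_equal(s12, 2 * s1 + s2, tolerance = 1e-12)
})

test_that("back projection is the exact adjoint of forward projection", {
  fx <- small_fixture()
  geom <- fx$geom
  for (s in 1:5) {
    set.seed(s)
    x <- matrix(runif(64^2), 64, 64)
    y <- matrix(runif(geom$n_angles * geom$n_bins),
                geom$n_angles, geom$n_bins)
    Ax <- forward_project(image_grid(x, 3), fx$model)$values
    Aty <- back_project(sinogram(y, geom), fx$model)$values
    lhs <- sum(Ax * y); rhs <- sum(x * Aty)
    expect_lte(abs(lhs - rhs) / abs(lhs), 1e-6)
  }
})

test_that("uniform disc projects to the analytic chord profile", {
  n <- 64L; geom <- make_geom(n)
  m0 <- build_system_model(NULL, geom, psf_fwhm_mm = NULL,
                           grid_n = n, pixel_mm = 3)
  co <- petbc:::pixel_coords(n, 3)
  c0 <- (n - 1) / 2 * 3
  r <- 45
  disc <- 1.0 * ((co$x - c0)^2 + (co$y - c0)^2 <= r^2)
  s <- forward_project(image_grid(disc, 3), m0)
  t_axis <- ((seq_len(geom$n_bins)) - (geom$n_bins + 1) / 2) * geom$bin_mm
  chord <- ifelse(abs(t_axis) < r, 2 * sqrt(pmax(r^2 - t_axis^2, 0)), 0)
  central <- (geom$n_bins + 1L) / 2L
  expect_equal(s$values[1, central], 2 * r, tolerance = 1e-2)
  # interior bins (away from the tangent) within discretization error
  interior <- abs(t_axis) < 0.8 * r
  expect_lt(max(abs(s$values[1, interior] - chord[interior])), 2 * 3)
})

test_that("uniform sinogram backprojects to a rotationally symmetric image", {
  n <- 64L; geom <- make_geom(n)
  m0 <- build_system_model(NULL, geom, psf_fwhm_mm = NULL,
                           grid_n = n, pixel_mm = 3)
  ones <- sinogram(matrix(1, geom$n_angles, geom$n_bins), geom)
  b <- back_project(ones, m0)$values
  # pixel-driven splatting spreads every pixel's unit weight over the
  # detector at every angle, so the result is exactly flat
  expect_lt(diff(range(b)) / mean(b), 1e-9)
})

test_that("gaussian blur conserves mass for interior-supported images", {
  n <- 64L
  img <- matrix(0, n, n)
  img[25:40, 25:40] <- runif(16 * 16)
  out <- petbc:::gauss_blur_matrix(img, 4.4, 3)
  expect_equal(sum(out), sum(img), tolerance = 1e-9)
})

test_that("poisson acquisition simulation is seeded and calibrated", {
  fx <- small_fixture()
  y1 <- simulate_counts(fx$clean, 5e5, seed = 11)
  y2 <- simulate_counts(fx$clean, 5e5, seed = 11)
  expect_identical(y1$values, y2$values)
  y3 <- simulate_counts(fx$clean, 5e5, seed = 12)
  expect_false(identical(y1$values, y3$values))

  # zero expectation bins stay exactly zero
  expect_true(all(y1$values[fx$clean$values == 0] == 0))
  # Poisson concentration: realized total within 4*sqrt(N)
  expect_lte(abs(sum(y1$values) - 5e5), 4 * sqrt(5e5))
  # scale attribute reproduces the calibration
  expect_equal(attr(y1, "scale"), 5e5 / sum(fx$clean$values))

  zero_s <- sinogram(matrix(0, fx$geom$n_angles, fx$geom$n_bins), fx$geom)
  expect_error(simulate_counts(zero_s, 1e5, 1), "zero")

  # caller's RNG state is untouched
  set.seed(99); before <- .Random.seed
  invisible(simulate_counts(fx$clean, 1e4, seed = 5))
  expect_identical(.Random.seed, before)
})
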