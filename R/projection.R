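#' Parallel-beam projection geometry
#'
#' @param n_angles number of projection angles, evenly spaced on `[0, pi)`
#'   unless `angles` is given.
#' @param n_bins number of detector bins (use [default_geometry()] to size
#'   the detector to an image diagonal).
#' @param bin_mm detector bin width in mm.
#' @param angles optional explicit angles in radians.
#' @return An object of class `projection_geometry`.
#' @export
projection_geometry <- function(n_angles, n_bins, bin_mm, angles = NULL) {
  n_angles <- as.integer(n_angles); n_bins <- as.integer(n_bins)
  if (n_angles < 1L) stop("n_angles must be >= 1")
  if (is.null(angles))
    angles <- seq(0, pi, length.out = n_angles + 1L)[seq_len(n_angles)]
  if (length(angles) != n_angles) stop("angles length must equal n_angles")
  structure(list(n_angles = n_angles, angles = angles,
                 n_bins = n_bins, bin_mm = bin_mm),
            class = "projection_geometry")
}

#' Default geometry for an image
#'
#' Detector bins match the pixel size and cover the image diagonal.
#'
#' @param image an [image_grid()].
#' @param n_angles number of angles (default 96).
#' @return A [projection_geometry()].
#' @export
default_geometry <- function(image, n_angles = 96L) {
  n <- max(dim(image$values))
  n_bins <- 2L * as.integer(ceiling(sqrt(2) * n / 2)) + 1L
  projection_geometry(n_angles, n_bins, image$pixel_mm)
}

#' Sinogram container
#'
#' @param values numeric `n_angles x n_bins` matrix of counts or expected
#'   counts; must be nonnegative.
#' @param geometry the [projection_geometry()] the values live on.
#' @return An object of class `sinogram`.
#' @export
sinogram <- function(values, geometry) {
  values <- as.matrix(values)
  stopifnot(inherits(geometry, "projection_geometry"))
  if (!identical(dim(values), c(geometry$n_angles, geometry$n_bins)))
    stop("sinogram shape does not match geometry")
  if (any(!is.finite(values)) || any(values < 0))
    stop("sinogram values must be finite and nonnegative")
  structure(list(values = values, geometry = geometry), class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("<sinogram> %d angles x %d bins (bin %.3g mm), total %.4g\n",
              x$geometry$n_angles, x$geometry$n_bins, x$geometry$bin_mm,
              sum(x$values)))
  invisible(x)
}

# Flatten angle-major (bin fastest): index (a, b) -> (a-1)*n_bins + b.
sino_vec <- function(s) as.vector(t(s$values))
vec_sino <- function(v, geometry)
  sinogram(matrix(v, geometry$n_angles, geometry$n_bins, byrow = TRUE),
           geometry)

# Pixel-driven linear-splatting projection matrix, (n_angles*n_bins) x n^2,
# in line-integral units (mm): each pixel projects its centre onto the
# detector axis and splits mass pixel_mm^2/bin_mm between the two nearest
# bins. The two weights always sum to 1, so per-angle mass is preserved
# exactly and the transpose is an exact adjoint backprojector.
projector_matrix <- function(geometry, grid_n, pixel_mm) {
  n2 <- grid_n * grid_n
  ax <- (seq_len(grid_n) - 1 - (grid_n - 1) / 2) * pixel_mm
  px <- rep(ax, each = grid_n)   # column-major: x varies with column
  py <- rep(ax, times = grid_n)  # y varies with row
  half <- (geometry$n_bins + 1) / 2
  w_px <- pixel_mm^2 / geometry$bin_mm
  trip_i <- vector("list", geometry$n_angles)
  trip_j <- vector("list", geometry$n_angles)
  trip_x <- vector("list", geometry$n_angles)
  for (a in seq_len(geometry$n_angles)) {
    th <- geometry$angles[a]
    t_mm <- px * cos(th) + py * sin(th)
    cpos <- t_mm / geometry$bin_mm + half
    b0 <- floor(cpos)
    w1 <- cpos - b0
    keep0 <- b0 >= 1 & b0 <= geometry$n_bins
    keep1 <- (b0 + 1) >= 1 & (b0 + 1) <= geometry$n_bins
    row0 <- (a - 1L) * geometry$n_bins + b0
    trip_i[[a]] <- c(row0[keep0], row0[keep1] + 1L)
    trip_j[[a]] <- c(which(keep0), which(keep1))
    trip_x[[a]] <- c((1 - w1)[keep0], w1[keep1]) * w_px
  }
  Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                       x = unlist(trip_x),
                       dims = c(geometry$n_angles * geometry$n_bins, n2))
}

# Two-segment (bilinear) HU -> mu(511 keV) map in 1/mm. Soft segment scales
# water linearly with HU; bone segment adds a shallower slope above 0 HU.
hu_to_mu <- function(hu, mu_water = 0.0096, bone_slope_per_hu = 5.5e-6) {
  if (any(hu < -1000))
    stop("HU below -1000 would give negative attenuation; rejecting")
  mu <- ifelse(hu <= 0, mu_water * (1 + hu / 1000),
               mu_water + hu * bone_slope_per_hu)
  pmax(mu, 0)
}

#' Build a system model
#'
#' Combines the projection geometry, CT-derived attenuation factors, the
#' image-space Gaussian PSF and a global count calibration into the linear
#' acquisition operator `A`. Attenuation factors are
#' `exp(-line integral of mu)` per (angle, bin), with `mu` at 511 keV from a
#' two-segment HU map (`mu_water` for soft tissue, a shallower slope above
#' 0 HU for bone).
#'
#' @param ct CT [image_grid()] in HU, or `NULL` for no attenuation.
#' @param geometry a [projection_geometry()].
#' @param psf_fwhm_mm Gaussian PSF FWHM in mm (default 4.4), or `NULL`/0 for
#'   no resolution modelling.
#' @param count_scale global multiplicative calibration applied by the
#'   forward model (expected counts per unit line integral).
#' @param mu_water linear attenuation of water at 511 keV, 1/mm.
#' @param bone_slope_per_hu slope of the bone segment of the HU map, 1/mm/HU.
#' @param grid_n,pixel_mm image raster the model operates on; defaults are
#'   taken from `ct`.
#' @param projector optional precomputed projection matrix (reused across
#'   models sharing a geometry and raster).
#' @return An object of class `system_model`.
#' @export
build_system_model <- function(ct = NULL, geometry, psf_fwhm_mm = 4.4,
                               count_scale = 1, mu_water = 0.0096,
                               bone_slope_per_hu = 5.5e-6,
                               grid_n = NULL, pixel_mm = NULL,
                               projector = NULL) {
  if (is.null(ct)) {
    if (is.null(grid_n) || is.null(pixel_mm))
      stop("grid_n and pixel_mm are required when no CT is supplied")
  } else {
    stopifnot(inherits(ct, "image_grid"))
    grid_n <- nrow(ct$values); pixel_mm <- ct$pixel_mm
    if (nrow(ct$values) != ncol(ct$values)) stop("square grids only")
  }
  if (count_scale <= 0) stop("count_scale must be positive")
  if (!is.null(psf_fwhm_mm) && psf_fwhm_mm < 0) stop("psf_fwhm_mm must be >= 0")
  P <- if (is.null(projector)) projector_matrix(geometry, grid_n, pixel_mm)
       else projector
  att <- if (is.null(ct)) rep(1, geometry$n_angles * geometry$n_bins)
         else as.numeric(exp(-(P %*% as.vector(hu_to_mu(
           ct$values, mu_water, bone_slope_per_hu)))))
  structure(list(geometry = geometry, projector = P,
                 attenuation_factors = att,
                 psf_fwhm_mm = psf_fwhm_mm, count_scale = count_scale,
                 grid_n = grid_n, pixel_mm = pixel_mm),
            class = "system_model")
}

# Swap the resolution model of an existing system model (shares the
# projector and attenuation).
with_psf <- function(model, psf_fwhm_mm) {
  model$psf_fwhm_mm <- psf_fwhm_mm
  model
}

with_count_scale <- function(model, count_scale) {
  stopifnot(count_scale > 0)
  model$count_scale <- count_scale
  model
}

# Forward/back projection restricted to a subset of sinogram rows
# (angle-major flat indices); used by OSEM subsets.
fp_rows <- function(values, model, rows = NULL) {
  blurred <- gauss_blur_matrix(values, model$psf_fwhm_mm, model$pixel_mm)
  if (is.null(rows)) {
    as.numeric(model$projector %*% as.vector(blurred)) *
      model$attenuation_factors * model$count_scale
  } else {
    as.numeric(model$projector[rows, , drop = FALSE] %*% as.vector(blurred)) *
      model$attenuation_factors[rows] * model$count_scale
  }
}

bp_rows <- function(yvec, model, rows = NULL) {
  if (is.null(rows)) {
    v <- as.numeric(Matrix::crossprod(
      model$projector, yvec * model$attenuation_factors)) * model$count_scale
  } else {
    v <- as.numeric(Matrix::crossprod(
      model$projector[rows, , drop = FALSE],
      yvec * model$attenuation_factors[rows])) * model$count_scale
  }
  gauss_blur_matrix(matrix(v, model$grid_n, model$grid_n),
                    model$psf_fwhm_mm, model$pixel_mm)
}

#' Forward project an image
#'
#' Applies the system operator: Gaussian PSF blur in image space, parallel-
#' beam line-integral projection, attenuation, and the count calibration.
#' Linear in the image.
#'
#' @param image an [image_grid()]; must be nonnegative.
#' @param model a [build_system_model()].
#' @return A [sinogram()] of expected counts.
#' @export
forward_project <- function(image, model) {
  stopifnot(inherits(image, "image_grid"), inherits(model, "system_model"))
  if (nrow(image$values) != model$grid_n || ncol(image$values) != model$grid_n)
    stop("image size does not match the system model")
  if (any(image$values < 0)) stop("activity image must be nonnegative")
  vec_sino(fp_rows(image$values, model), model$geometry)
}

#' Back project a sinogram
#'
#' The exact adjoint of [forward_project()]: attenuation weighting, transpose
#' projection, then the (symmetric) PSF convolution.
#'
#' @param sino a [sinogram()].
#' @param model a [build_system_model()].
#' @return An [image_grid()].
#' @export
back_project <- function(sino, model) {
  stopifnot(inherits(sino, "sinogram"), inherits(model, "system_model"))
  if (!identical(dim(sino$values),
                 c(model$geometry$n_angles, model$geometry$n_bins)))
    stop("sinogram shape does not match the system model geometry")
  image_grid(bp_rows(sino_vec(sino), model), model$pixel_mm)
}

#' Simulate a Poisson acquisition
#'
#' Rescales an expected sinogram to a target total count and draws
#' independent Poisson counts per bin. Deterministic for a fixed seed; the
#' caller's RNG state is left untouched.
#'
#' @param expected a [sinogram()] of nonnegative expectations.
#' @param total_counts target expected total counts (> 0).
#' @param seed integer seed.
#' @return A [sinogram()] of counts, with attributes `scale` (the factor the
#'   expectations were multiplied by) and `seed`.
#' @export
simulate_counts <- function(expected, total_counts, seed) {
  stopifnot(inherits(expected, "sinogram"))
  if (total_counts <= 0) stop("total_counts must be positive")
  tot <- sum(expected$values)
  if (tot == 0) stop("expected sinogram is identically zero")
  scale <- total_counts / tot
  lambda <- expected$values * scale
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))
  counts <- matrix(stats::rpois(length(lambda), as.vector(lambda)),
                   nrow(lambda), ncol(lambda))
  out <- sinogram(counts, expected$geometry)
  attr(out, "scale") <- scale
  attr(out, "seed") <- as.integer(seed)
  out
}
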