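#' Construct an image grid
#'
#' The common currency of the package: a 2D array of voxel values on a square
#' pixel raster with a physical pixel size. Values are either activity in
#' SUV-like (unitless) units or CT numbers in Hounsfield units (HU).
#'
#' Physical coordinates are 0-based pixel indices scaled by `pixel_mm`:
#' column `j` has `x = (j - 1) * pixel_mm`, row `i` has
#' `y = (i - 1) * pixel_mm`.
#'
#' @param values numeric matrix of voxel values; must be finite.
#' @param pixel_mm side length of a pixel in millimetres.
#' @return An object of class `image_grid` with elements `values` and
#'   `pixel_mm`.
#' @export
image_grid <- function(values, pixel_mm) {
  values <- as.matrix(values)
  if (!is.numeric(values) || !all(is.finite(values)))
    stop("image values must be finite numerics")
  if (length(pixel_mm) != 1L || !is.finite(pixel_mm) || pixel_mm <= 0)
    stop("pixel_mm must be a single positive number")
  structure(list(values = values, pixel_mm = as.numeric(pixel_mm)),
            class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("<image_grid> %d x %d pixels @ %.3g mm  [%.4g, %.4g]\n",
              nrow(x$values), ncol(x$values), x$pixel_mm,
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
plot.image_grid <- function(x, main = "", ...) {
  n <- dim(x$values)
  graphics::image(x = (seq_len(n[2]) - 1) * x$pixel_mm,
                  y = (seq_len(n[1]) - 1) * x$pixel_mm,
                  z = t(x$values)[, rev(seq_len(n[1])), drop = FALSE],
                  asp = 1, xlab = "x (mm)", ylab = "y (mm)", main = main,
                  col = grDevices::gray.colors(256, start = 0, end = 1), ...)
  invisible(x)
}

# FWHM -> sigma for a Gaussian: sigma = FWHM / (2*sqrt(2*log(2))) = FWHM/2.3548
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# Normalized 1D Gaussian kernel sampled at pixel centres. Returns 1 (identity)
# for fwhm <= 0. Radius 4 sigma so truncation error is negligible.
gauss_kernel_1d <- function(fwhm_mm, pixel_mm) {
  if (is.null(fwhm_mm) || fwhm_mm <= 0) return(1)
  sigma_px <- fwhm_to_sigma(fwhm_mm) / pixel_mm
  r <- max(1L, as.integer(ceiling(4 * sigma_px)))
  k <- exp(-((-r):r)^2 / (2 * sigma_px^2))
  k / sum(k)
}

# Sparse symmetric banded convolution matrix (zero boundary padding).
conv_matrix <- function(n, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  if (r == 0L) return(Matrix::Diagonal(n))
  ii <- jj <- integer(0); xx <- numeric(0)
  for (o in -r:r) {
    i <- seq.int(max(1L, 1L - o), min(n, n - o))
    ii <- c(ii, i); jj <- c(jj, i + o)
    xx <- c(xx, rep(kernel[o + r + 1L], length(i)))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
}

# Separable Gaussian blur of a plain matrix; symmetric operator (C X C with
# C = C^T), which keeps the matched PSF projector/backprojector an exact
# adjoint pair.
gauss_blur_matrix <- function(values, fwhm_mm, pixel_mm) {
  k <- gauss_kernel_1d(fwhm_mm, pixel_mm)
  if (length(k) == 1L) return(values)
  Cr <- conv_matrix(nrow(values), k)
  Cc <- conv_matrix(ncol(values), k)
  as.matrix(Cr %*% values %*% Matrix::t(Cc))
}

#' Gaussian post-filter
#'
#' Convolve an image with a normalized isotropic Gaussian kernel of the given
#' full width at half maximum. With `fwhm_mm = 0` the image is returned
#' unchanged. The kernel is normalized, so total image mass is conserved for
#' images whose support is away from the grid boundary.
#'
#' @param image an [image_grid()].
#' @param fwhm_mm kernel full width at half maximum in mm (default 3, the
#'   clinical post-reconstruction filter width).
#' @return The filtered `image_grid`.
#' @export
gaussian_postfilter <- function(image, fwhm_mm = 3) {
  stopifnot(inherits(image, "image_grid"))
  if (length(fwhm_mm) != 1L || !is.finite(fwhm_mm) || fwhm_mm < 0)
    stop("fwhm_mm must be a single nonnegative number")
  image_grid(gauss_blur_matrix(image$values, fwhm_mm, image$pixel_mm),
             image$pixel_mm)
}
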