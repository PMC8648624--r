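#' Reconstruction configuration
#'
#' Defaults mirror routine clinical practice for [18F]-NaF imaging: 21
#' subsets, 3 iterations, a 4.4 mm FWHM Gaussian resolution model and a 3 mm
#' FWHM Gaussian post-filter.
#'
#' @param n_subsets number of ordered subsets (>= 1; 1 gives plain MLEM).
#' @param n_iterations full passes over all subsets.
#' @param psf_fwhm_mm Gaussian PSF modelled during reconstruction, in mm;
#'   `NULL` or 0 disables resolution modelling.
#' @param postfilter_fwhm_mm Gaussian post-filter FWHM in mm (applied by
#'   [gaussian_postfilter()], not inside the iterations).
#' @param epsilon small positive guard added to the ratio denominator.
#' @param init_value uniform initial activity inside the support.
#' @return An object of class `recon_config`.
#' @export
recon_config <- function(n_subsets = 21L, n_iterations = 3L,
                         psf_fwhm_mm = 4.4, postfilter_fwhm_mm = 3,
                         epsilon = 1e-10, init_value = 1) {
  n_subsets <- as.integer(n_subsets); n_iterations <- as.integer(n_iterations)
  if (n_subsets < 1L || n_iterations < 1L)
    stop("n_subsets and n_iterations must be >= 1")
  if (epsilon <= 0) stop("epsilon must be positive")
  if (init_value <= 0) stop("init_value must be positive")
  structure(list(n_subsets = n_subsets, n_iterations = n_iterations,
                 psf_fwhm_mm = psf_fwhm_mm,
                 postfilter_fwhm_mm = postfilter_fwhm_mm,
                 epsilon = epsilon, init_value = init_value),
            class = "recon_config")
}

# Bit-reversal permutation of 0:(n-1) (padded to the next power of two),
# used to order angles before round-robin subset assignment. Standard OSEM
# practice: consecutive subsets see maximally different view directions.
bit_reversal_order <- function(n) {
  bits <- max(1L, as.integer(ceiling(log2(n))))
  m <- 2L^bits
  rev_idx <- integer(m)
  v <- 0:(m - 1L)
  for (b in seq_len(bits)) {
    rev_idx <- rev_idx * 2L + v %% 2L
    v <- v %/% 2L
  }
  rev_idx[rev_idx < n]
}

# Partition angle indices 1..n_angles into n_subsets: angles taken in
# bit-reversed order and dealt round-robin. Subsets may differ in size by one
# when n_subsets does not divide n_angles.
angle_subsets <- function(n_angles, n_subsets) {
  if (n_subsets > n_angles)
    stop("n_subsets cannot exceed the number of angles")
  ord <- bit_reversal_order(n_angles) + 1L
  split(ord, rep_len(seq_len(n_subsets), n_angles))
}

# Flat sinogram row indices (angle-major) for a set of angle indices.
rows_for_angles <- function(angles_idx, n_bins)
  as.vector(outer(seq_len(n_bins), (angles_idx - 1L) * n_bins, `+`))

# Poisson log-likelihood sum(y log lambda - lambda), with the y = 0 bins
# contributing -lambda and y > 0 against lambda = 0 giving -Inf.
poisson_loglik <- function(y, lambda) {
  ll <- -sum(lambda)
  pos <- y > 0
  if (any(pos & lambda <= 0)) return(-Inf)
  ll + sum(y[pos] * log(lambda[pos]))
}

#' Fit an OSEM reconstruction
#'
#' Ordered-subset expectation maximization for the Poisson emission model
#' `y ~ Poisson(A x + r)`: the maximum-likelihood image estimate under the
#' system operator `A` (projection, attenuation, optional Gaussian PSF) with
#' a known additive term `r` and an optional support constraint. Each subset
#' update is multiplicative,
#' `x <- x * A_s^T( y_s / (A_s x + r_s + eps) ) / A_s^T 1`,
#' so nonnegativity is preserved; with one subset this is exactly MLEM.
#' Pixels outside the support, and pixels with zero sensitivity, are fixed
#' at 0. The post-filter is *not* applied here; use
#' [gaussian_postfilter()] on the result.
#'
#' @param data a [sinogram()] of counts.
#' @param model a [build_system_model()]. The resolution model actually used
#'   is `config$psf_fwhm_mm` (so the same measured data can be reconstructed
#'   with and without PSF modelling).
#' @param config a [recon_config()].
#' @param additive optional [sinogram()] of known additive expected counts
#'   (e.g. a background term); zero if omitted.
#' @param support optional logical matrix; reconstruction is restricted to
#'   `TRUE` pixels, all others are fixed at 0.
#' @param init optional nonnegative numeric matrix used as the starting
#'   image instead of the uniform `config$init_value` (useful for warm
#'   starts and fixed-point checks). Zeros in `init` stay zero.
#' @return An object of class `osem_fit` with the reconstructed
#'   [image_grid()] in `$image`, the fitted expected sinogram, the data, the
#'   per-iteration Poisson log-likelihood trace, and the configuration.
#'   Methods: `print`, `summary`, `coef`, `fitted`, `residuals`, `logLik`,
#'   `plot`.
#' @export
osem <- function(data, model, config = recon_config(), additive = NULL,
                 support = NULL, init = NULL) {
  stopifnot(inherits(data, "sinogram"), inherits(model, "system_model"),
            inherits(config, "recon_config"))
  geom <- model$geometry
  if (!identical(dim(data$values), c(geom$n_angles, geom$n_bins)))
    stop("data shape does not match the system model geometry")
  y <- sino_vec(data)
  r <- if (is.null(additive)) numeric(length(y)) else {
    stopifnot(inherits(additive, "sinogram"))
    if (!identical(dim(additive$values), dim(data$values)))
      stop("additive term shape does not match the data")
    sino_vec(additive)
  }
  if (any(r < 0)) stop("additive term must be nonnegative")
  n <- model$grid_n
  if (is.null(support)) support <- matrix(TRUE, n, n)
  if (!is.logical(support) || !identical(dim(support), c(n, n)))
    stop("support must be a logical matrix matching the image grid")
  if (!any(support)) stop("support must contain at least one pixel")

  op <- with_psf(model, config$psf_fwhm_mm)
  subsets <- angle_subsets(geom$n_angles, config$n_subsets)
  rows <- lapply(subsets, rows_for_angles, n_bins = geom$n_bins)
  # Precompute per-subset operators once: row subsetting of the sparse
  # projector is far more expensive than the matvecs themselves.
  Ps <- lapply(rows, function(rr) op$projector[rr, , drop = FALSE])
  Pts <- lapply(Ps, Matrix::t)
  att_s <- lapply(rows, function(rr) op$attenuation_factors[rr])
  fp_sub <- function(x, s) {
    blurred <- gauss_blur_matrix(x, op$psf_fwhm_mm, op$pixel_mm)
    as.numeric(Ps[[s]] %*% as.vector(blurred)) * att_s[[s]] * op$count_scale
  }
  bp_sub <- function(v, s) {
    vv <- as.numeric(Pts[[s]] %*% (v * att_s[[s]])) * op$count_scale
    gauss_blur_matrix(matrix(vv, op$grid_n, op$grid_n),
                      op$psf_fwhm_mm, op$pixel_mm)
  }
  sens <- lapply(seq_along(rows), function(s)
    bp_sub(rep(1, length(rows[[s]])), s))
  total_sens <- Reduce(`+`, sens)
  frozen <- total_sens <= 0
  if (any(frozen & support))
    message(sprintf("osem: %d zero-sensitivity pixel(s) frozen at 0",
                    sum(frozen & support)))
  active <- support & !frozen

  x <- matrix(0, n, n)
  if (is.null(init)) {
    x[active] <- config$init_value
  } else {
    if (!is.numeric(init) || !identical(dim(init), c(n, n)) || any(init < 0))
      stop("init must be a nonnegative numeric matrix matching the grid")
    x[active] <- init[active]
  }
  eps <- config$epsilon
  ll_trace <- numeric(config$n_iterations)
  for (it in seq_len(config$n_iterations)) {
    for (s in seq_along(rows)) {
      rr <- rows[[s]]
      lam <- fp_sub(x, s) + r[rr]
      back <- bp_sub(y[rr] / (lam + eps), s)
      upd <- active & sens[[s]] > 0
      x[upd] <- x[upd] * back[upd] / sens[[s]][upd]
    }
    ll_trace[it] <- poisson_loglik(y, fp_rows(x, op) + r)
  }
  lam_final <- fp_rows(x, op) + r
  structure(list(image = image_grid(x, model$pixel_mm),
                 config = config,
                 algorithm = if (is.null(config$psf_fwhm_mm) ||
                                 config$psf_fwhm_mm == 0) "osem"
                             else "osem-psf",
                 data = data,
                 additive = additive,
                 support = support,
                 fitted_sino = vec_sino(lam_final, geom),
                 loglik_trace = ll_trace,
                 n_active = sum(active)),
            class = "osem_fit")
}

#' @export
print.osem_fit <- function(x, ...) {
  cat(sprintf(paste0("<osem_fit> algorithm %s: %d subsets x %d iterations",
                     " (PSF %s mm)\n  image %d x %d @ %g mm,",
                     " max %.4g; logLik %.6g\n"),
              x$algorithm, x$config$n_subsets, x$config$n_iterations,
              if (is.null(x$config$psf_fwhm_mm)) "off"
              else format(x$config$psf_fwhm_mm),
              nrow(x$image$values), ncol(x$image$values),
              x$image$pixel_mm, max(x$image$values),
              x$loglik_trace[length(x$loglik_trace)]))
  invisible(x)
}

#' @export
summary.osem_fit <- function(object, ...) {
  v <- object$image$values
  res <- list(algorithm = object$algorithm,
              config = object$config,
              image_range = range(v),
              image_total = sum(v),
              n_active = object$n_active,
              loglik_trace = object$loglik_trace,
              data_total = sum(object$data$values),
              fitted_total = sum(object$fitted_sino$values))
  class(res) <- "summary.osem_fit"
  res
}

#' @export
print.summary.osem_fit <- function(x, ...) {
  cat(sprintf("OSEM fit (%s)\n", x$algorithm))
  cat(sprintf("  %d subsets x %d iterations, %d active pixels\n",
              x$config$n_subsets, x$config$n_iterations, x$n_active))
  cat(sprintf("  image range [%.4g, %.4g], total %.6g\n",
              x$image_range[1], x$image_range[2], x$image_total))
  cat(sprintf("  counts: data %.6g, fitted %.6g\n",
              x$data_total, x$fitted_total))
  cat("  logLik per iteration:", format(x$loglik_trace, digits = 8), "\n")
  invisible(x)
}

#' @export
coef.osem_fit <- function(object, ...) object$image$values

#' @export
fitted.osem_fit <- function(object, ...) object$fitted_sino

#' Residuals of an OSEM fit
#'
#' @param object an `osem_fit`.
#' @param type `"raw"` for `y - lambda` or `"pearson"` for
#'   `(y - lambda)/sqrt(lambda)` (bins with `lambda = 0` give 0).
#' @param ... unused.
#' @export
residuals.osem_fit <- function(object, type = c("raw", "pearson"), ...) {
  type <- match.arg(type)
  d <- object$data$values - object$fitted_sino$values
  if (type == "pearson") {
    lam <- object$fitted_sino$values
    d <- ifelse(lam > 0, d / sqrt(lam), 0)
  }
  d
}

#' @export
logLik.osem_fit <- function(object, ...) {
  ll <- object$loglik_trace[length(object$loglik_trace)]
  attr(ll, "df") <- object$n_active
  class(ll) <- "logLik"
  ll
}

#' @export
plot.osem_fit <- function(x, ...) plot(x$image, main = x$algorithm, ...)
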