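#' Distance from each pixel to the nearest mask pixel
#'
#' Euclidean distances between pixel centres, in mm. Pixels inside the mask
#' have distance 0.
#'
#' @param mask logical matrix.
#' @param pixel_mm pixel size in mm.
#' @return Numeric matrix of distances (Inf when the mask is empty).
#' @export
dist_to_mask <- function(mask, pixel_mm) {
  stopifnot(is.logical(mask))
  n <- nrow(mask); m <- ncol(mask)
  if (!any(mask)) return(matrix(Inf, n, m))
  idx <- which(mask, arr.ind = TRUE)
  ri <- matrix(seq_len(n), n, m)
  ci <- matrix(seq_len(m), n, m, byrow = TRUE)
  d2 <- matrix(Inf, n, m)
  for (k in seq_len(nrow(idx))) {
    dk <- (ri - idx[k, 1])^2 + (ci - idx[k, 2])^2
    d2 <- pmin(d2, dk)
  }
  sqrt(d2) * pixel_mm
}

# Minimum centre-to-centre distance between two masks, in mm.
mask_min_distance <- function(mask_a, mask_b, pixel_mm) {
  a <- which(mask_a, arr.ind = TRUE)
  b <- which(mask_b, arr.ind = TRUE)
  if (nrow(a) == 0L || nrow(b) == 0L) return(Inf)
  d2 <- outer(a[, 1], b[, 1], `-`)^2 + outer(a[, 2], b[, 2], `-`)^2
  sqrt(min(d2)) * pixel_mm
}

#' Derive the bone-excluded aneurysm ROI
#'
#' The conventional spill-in workaround: remove from the aneurysm ROI every
#' pixel whose centre lies within `exclusion_mm` (Euclidean) of the bone
#' mask. With `exclusion_mm = 0` only pixels inside the bone itself would be
#' removed, so for disjoint masks the ROI is unchanged.
#'
#' @param aaa_mask,bone_mask logical matrices of identical shape.
#' @param exclusion_mm exclusion distance in mm (>= 0).
#' @param pixel_mm pixel size in mm.
#' @return Logical matrix, a subset of `aaa_mask`. Errors if the result is
#'   empty (the ROI would be unusable).
#' @export
derive_aaa_exc <- function(aaa_mask, bone_mask, exclusion_mm, pixel_mm) {
  if (!identical(dim(aaa_mask), dim(bone_mask)))
    stop("masks must have the same shape")
  if (exclusion_mm < 0) stop("exclusion_mm must be >= 0")
  d <- dist_to_mask(bone_mask, pixel_mm)
  out <- aaa_mask & (d > exclusion_mm)
  if (!any(out))
    stop("bone exclusion removed the entire aneurysm ROI")
  out
}

#' Maximum and mean uptake over an ROI
#'
#' @param image an [image_grid()].
#' @param mask nonempty logical matrix.
#' @return List with `max` and `mean` of the masked voxel values.
#' @export
roi_suv <- function(image, mask) {
  stopifnot(inherits(image, "image_grid"))
  if (!is.logical(mask) || !identical(dim(mask), dim(image$values)))
    stop("mask must be a logical matrix matching the image")
  if (!any(mask)) stop("ROI mask is empty")
  v <- image$values[mask]
  list(max = max(v), mean = mean(v))
}

#' Corrected maximum SUV
#'
#' `cSUVmax = SUVmax(T) - SUVmean(B)`: the target maximum minus the mean
#' blood-pool uptake. May be negative; the sign is preserved.
#'
#' @param suv_max_t maximum SUV in the target ROI.
#' @param suv_mean_b mean SUV in the blood-pool ROI.
#' @export
csuv_max <- function(suv_max_t, suv_mean_b) {
  stopifnot(is.finite(suv_max_t), is.finite(suv_mean_b))
  suv_max_t - suv_mean_b
}

#' Maximum target-to-blood ratio
#'
#' `TBRmax = SUVmax(T) / SUVmean(B)`.
#'
#' @inheritParams csuv_max
#' @export
tbr_max <- function(suv_max_t, suv_mean_b) {
  if (!is.finite(suv_mean_b) || suv_mean_b <= 0)
    stop("blood-pool mean must be positive")
  suv_max_t / suv_mean_b
}

#' ROI uptake metrics
#'
#' Computes SUVmax over the target, SUVmean over the blood pool, and the
#' derived cSUVmax and TBRmax.
#'
#' @param image an [image_grid()].
#' @param target_mask,blood_mask nonempty logical matrices.
#' @return An object of class `uptake_metrics` (a list with `suv_max_t`,
#'   `suv_mean_b`, `csuv_max`, `tbr_max`).
#' @export
uptake_metrics <- function(image, target_mask, blood_mask) {
  t_ <- roi_suv(image, target_mask)
  b_ <- roi_suv(image, blood_mask)
  structure(list(suv_max_t = t_$max, suv_mean_b = b_$mean,
                 csuv_max = csuv_max(t_$max, b_$mean),
                 tbr_max = tbr_max(t_$max, b_$mean)),
            class = "uptake_metrics")
}

#' @export
print.uptake_metrics <- function(x, ...) {
  cat(sprintf("SUVmax(T) %.3f  SUVmean(B) %.3f  cSUVmax %.3f  TBRmax %.3f\n",
              x$suv_max_t, x$suv_mean_b, x$csuv_max, x$tbr_max))
  invisible(x)
}

#' Relative percent difference between two uptake values
#'
#' `100 * (a - b) / b`, the convention used when comparing a candidate
#' technique `a` against a reference `b`.
#'
#' @param a,b numeric values; `b` must be nonzero.
#' @export
percent_difference <- function(a, b) {
  if (!is.finite(b) || b == 0) stop("reference value must be nonzero")
  100 * (a - b) / b
}

#' Classify a percent difference as clinically significant
#'
#' Strict comparison against the EORTC-style threshold: differences *greater
#' than* 25% count as significant.
#'
#' @param percent_diff percent difference.
#' @param threshold significance threshold in percent (default 25).
#' @export
classify_significant <- function(percent_diff, threshold = 25) {
  stopifnot(all(is.finite(percent_diff)))
  percent_diff > threshold
}

#' Spill-in factor of an aneurysm ROI
#'
#' Partitions the aneurysm mask into the bone-proximal ("prone") sub-region
#' (pixel centres within `prone_mm` of the bone) and the remainder, and
#' reports `max(prone) / max(rest)` — the factor by which bone spill-in can
#' inflate the apparent SUVmax.
#'
#' @param image an [image_grid()].
#' @param aaa_mask,bone_mask logical matrices.
#' @param prone_mm proximity distance in mm (default 8).
#' @return An object of class `spill_in_report` with `max_prone`,
#'   `max_rest`, `factor` and the two sub-masks.
#' @export
spill_in_factor <- function(image, aaa_mask, bone_mask, prone_mm = 8) {
  stopifnot(inherits(image, "image_grid"))
  d <- dist_to_mask(bone_mask, image$pixel_mm)
  prone <- aaa_mask & d <= prone_mm
  rest <- aaa_mask & !prone
  if (!any(prone))
    stop("no aneurysm pixels within prone_mm of the bone (prone region empty)")
  if (!any(rest))
    stop("the whole aneurysm lies within prone_mm of the bone (rest empty)")
  mp <- max(image$values[prone]); mr <- max(image$values[rest])
  structure(list(max_prone = mp, max_rest = mr, factor = mp / mr,
                 prone_mask = prone, rest_mask = rest),
            class = "spill_in_report")
}

#' @export
print.spill_in_report <- function(x, ...) {
  cat(sprintf("spill-in: max %.3f (bone-proximal) vs %.3f (rest) -> factor %.2f\n",
              x$max_prone, x$max_rest, x$factor))
  invisible(x)
}

#' Sample a line profile through an image
#'
#' Bilinear interpolation at `n_samples` evenly spaced points between two
#' physical positions (mm, 0-based pixel-centre coordinates: x along
#' columns, y along rows).
#'
#' @param image an [image_grid()].
#' @param start_mm,end_mm numeric length-2 vectors `(x, y)` in mm; both must
#'   lie inside the grid.
#' @param n_samples number of samples (>= 2).
#' @return Numeric vector of sampled values.
#' @export
line_profile <- function(image, start_mm, end_mm, n_samples = 100L) {
  stopifnot(inherits(image, "image_grid"), n_samples >= 2)
  n <- nrow(image$values); m <- ncol(image$values); p <- image$pixel_mm
  tt <- seq(0, 1, length.out = n_samples)
  xs <- start_mm[1] + tt * (end_mm[1] - start_mm[1])
  ys <- start_mm[2] + tt * (end_mm[2] - start_mm[2])
  cx <- xs / p + 1  # fractional column index
  cy <- ys / p + 1  # fractional row index
  if (any(cx < 1 | cx > m | cy < 1 | cy > n))
    stop("profile endpoints must lie inside the image grid")
  j0 <- pmin(floor(cx), m - 1); i0 <- pmin(floor(cy), n - 1)
  fx <- cx - j0; fy <- cy - i0
  v00 <- image$values[cbind(i0, j0)]
  v01 <- image$values[cbind(i0, j0 + 1)]
  v10 <- image$values[cbind(i0 + 1, j0)]
  v11 <- image$values[cbind(i0 + 1, j0 + 1)]
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}
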