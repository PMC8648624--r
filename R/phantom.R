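#' Specify a digital bone/aneurysm phantom
#'
#' Defines a single-slice abdominal phantom: an elliptical soft-tissue body
#' containing a circular vertebral bone, an aneurysmal aorta (a hot wall
#' annulus around a blood-filled lumen) at a configurable surface-to-surface
#' distance from the bone, a normal (non-aneurysmal) aorta segment, and a
#' blood-pool reference region. All regions are piecewise constant; edge
#' pixels are assigned by pixel-centre membership so region means are exact.
#'
#' The aneurysm centre is placed on the line through the bone centre in the
#' anterior (decreasing y) direction, at centre distance
#' `bone_radius_mm + gap_mm + aaa_outer_radius_mm`, so `gap_mm = 0` puts the
#' two surfaces in contact.
#'
#' @param grid_n pixels per side (square grid).
#' @param pixel_mm pixel size in mm.
#' @param body_radius_mm semi-axes (x, y) of the body ellipse in mm.
#' @param bone_center_mm bone centre (x, y) in mm; default is 60 mm posterior
#'   of the grid centre.
#' @param bone_radius_mm bone radius in mm.
#' @param aaa_center_mm aneurysm centre (x, y) in mm, or `NULL` to derive it
#'   from `gap_mm` (the default). If supplied it must not overlap the bone.
#' @param aaa_outer_radius_mm outer radius of the aneurysm in mm.
#' @param aaa_wall_thickness_mm thickness of the hot aneurysm wall in mm.
#' @param gap_mm bone-surface-to-aneurysm-surface distance in mm
#'   (0 = contact).
#' @param exclusion_mm bone-proximity distance used to derive the AAAexc mask
#'   (see [derive_aaa_exc()]).
#' @param uptake named list of SUV-like activity levels: `blood`,
#'   `normal_aorta`, `aaa_wall`, `bone`, `soft_tissue`. Must satisfy
#'   `bone > aaa_wall > blood > 0`.
#' @param hu named list of CT levels in HU: `bone`, `soft`, `blood`.
#' @param blood_pool_area_mm2 area of the circular blood-pool reference
#'   region (default 200 mm^2, i.e. 2 cm^2).
#' @param non_aaa_radius_mm radius of the normal-aorta disc in mm.
#' @param seed integer recorded with the spec (the phantom itself is
#'   deterministic; the seed is provenance for downstream noise simulation).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_n = 128L,
                         pixel_mm = 3,
                         body_radius_mm = c(150, 110),
                         bone_center_mm = NULL,
                         bone_radius_mm = 15,
                         aaa_center_mm = NULL,
                         aaa_outer_radius_mm = 25,
                         aaa_wall_thickness_mm = 6,
                         gap_mm = 0,
                         exclusion_mm = 8,
                         uptake = list(blood = 1, normal_aorta = 1.2,
                                       aaa_wall = 3, bone = 6,
                                       soft_tissue = 0.3),
                         hu = list(bone = 1000, soft = 40, blood = 30),
                         blood_pool_area_mm2 = 200,
                         non_aaa_radius_mm = 9,
                         seed = 1L) {
  grid_n <- as.integer(grid_n)
  centre <- (grid_n - 1) / 2 * pixel_mm
  if (is.null(bone_center_mm))
    bone_center_mm <- c(centre, centre + 0.31 * grid_n * pixel_mm / 2)
  if (is.null(aaa_center_mm)) {
    sep <- bone_radius_mm + gap_mm + aaa_outer_radius_mm
    aaa_center_mm <- c(bone_center_mm[1], bone_center_mm[2] - sep)
  }
  spec <- structure(list(
    grid_n = grid_n, pixel_mm = pixel_mm,
    body_center_mm = c(centre, centre), body_radius_mm = body_radius_mm,
    bone_center_mm = bone_center_mm, bone_radius_mm = bone_radius_mm,
    aaa_center_mm = aaa_center_mm,
    aaa_outer_radius_mm = aaa_outer_radius_mm,
    aaa_wall_thickness_mm = aaa_wall_thickness_mm,
    gap_mm = gap_mm, exclusion_mm = exclusion_mm,
    uptake = uptake, hu = hu,
    blood_pool_area_mm2 = blood_pool_area_mm2,
    non_aaa_center_mm = c(centre, centre - 0.36 * grid_n * pixel_mm / 2),
    non_aaa_radius_mm = non_aaa_radius_mm,
    blood_center_mm = c(centre - 0.31 * grid_n * pixel_mm / 2,
                        centre - 0.31 * grid_n * pixel_mm / 2),
    seed = as.integer(seed)), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  u <- spec$uptake
  radii <- c(spec$body_radius_mm, spec$bone_radius_mm,
             spec$aaa_outer_radius_mm, spec$aaa_wall_thickness_mm,
             spec$non_aaa_radius_mm)
  if (any(radii <= 0)) stop("all radii and thicknesses must be positive")
  if (spec$gap_mm < 0) stop("gap_mm must be >= 0")
  if (!(u$bone > u$aaa_wall && u$aaa_wall > u$blood && u$blood > 0))
    stop("uptake levels must satisfy bone > aaa_wall > blood > 0")
  if (spec$aaa_wall_thickness_mm >= spec$aaa_outer_radius_mm)
    stop("wall thickness must be smaller than the outer radius")
  sep <- sqrt(sum((spec$bone_center_mm - spec$aaa_center_mm)^2))
  if (sep < spec$bone_radius_mm + spec$aaa_outer_radius_mm - 1e-9)
    stop("bone and aneurysm overlap beyond tangency; rejecting spec")
  inside_body <- function(p, margin = 0) {
    d <- (p - spec$body_center_mm) / (spec$body_radius_mm - margin)
    sum(d^2) <= 1
  }
  blood_r <- sqrt(spec$blood_pool_area_mm2 / pi)
  ok <- inside_body(spec$bone_center_mm, spec$bone_radius_mm) &&
    inside_body(spec$aaa_center_mm, spec$aaa_outer_radius_mm) &&
    inside_body(spec$non_aaa_center_mm, spec$non_aaa_radius_mm) &&
    inside_body(spec$blood_center_mm, blood_r)
  if (!ok) stop("structures do not fit inside the body ellipse")
  fov <- (spec$grid_n - 1) * spec$pixel_mm
  ext <- spec$body_center_mm + spec$body_radius_mm
  if (any(ext > fov) || any(spec$body_center_mm - spec$body_radius_mm < 0))
    stop("body ellipse does not fit inside the pixel grid")
  invisible(spec)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(paste0("<phantom_spec> %d x %d @ %g mm, gap %g mm (%s)\n",
                     "  bone r=%g mm @ (%g, %g); AAA outer r=%g mm, wall %g mm @ (%g, %g)\n"),
              x$grid_n, x$grid_n, x$pixel_mm, x$gap_mm,
              if (x$gap_mm == 0) "contact" else "detached",
              x$bone_radius_mm, x$bone_center_mm[1], x$bone_center_mm[2],
              x$aaa_outer_radius_mm, x$aaa_wall_thickness_mm,
              x$aaa_center_mm[1], x$aaa_center_mm[2]))
  invisible(x)
}

# Pixel-centre coordinate matrices in mm (x along columns, y along rows).
pixel_coords <- function(grid_n, pixel_mm) {
  ax <- (seq_len(grid_n) - 1) * pixel_mm
  list(x = matrix(ax, grid_n, grid_n, byrow = TRUE),
       y = matrix(ax, grid_n, grid_n))
}

disc_mask <- function(coords, center, radius)
  (coords$x - center[1])^2 + (coords$y - center[2])^2 <= radius^2

#' ROI mask set
#'
#' Bundle the five analysis masks and check their set invariants:
#' `aaa_exc` is a subset of `aaa`, `bone` is disjoint from `aaa`, and
#' `blood` is disjoint from `bone`.
#'
#' @param aaa,aaa_exc,non_aaa,blood,bone logical matrices of identical shape.
#' @return An object of class `roi_mask_set`.
#' @export
roi_mask_set <- function(aaa, aaa_exc, non_aaa, blood, bone) {
  ms <- list(aaa = aaa, aaa_exc = aaa_exc, non_aaa = non_aaa,
             blood = blood, bone = bone)
  dm <- dim(aaa)
  for (nm in names(ms)) {
    if (!is.logical(ms[[nm]]) || !identical(dim(ms[[nm]]), dm))
      stop("masks must be logical matrices of identical shape")
  }
  if (any(aaa_exc & !aaa)) stop("aaa_exc must be a subset of aaa")
  if (any(bone & aaa)) stop("bone and aaa masks must be disjoint")
  if (any(blood & bone)) stop("blood and bone masks must be disjoint")
  structure(ms, class = "roi_mask_set")
}

#' Generate a phantom
#'
#' Render a [phantom_spec()] into a piecewise-constant activity image, a
#' CT-like HU image, and the analysis mask set. Deterministic: the same spec
#' always yields bit-identical outputs.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `activity` and `ct` (both [image_grid()])
#'   and `masks` (a [roi_mask_set()]).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  co <- pixel_coords(spec$grid_n, spec$pixel_mm)
  d <- (co$x - spec$body_center_mm[1])^2 / spec$body_radius_mm[1]^2 +
       (co$y - spec$body_center_mm[2])^2 / spec$body_radius_mm[2]^2
  body <- d <= 1
  bone <- disc_mask(co, spec$bone_center_mm, spec$bone_radius_mm)
  aaa_outer <- disc_mask(co, spec$aaa_center_mm, spec$aaa_outer_radius_mm)
  lumen <- disc_mask(co, spec$aaa_center_mm,
                     spec$aaa_outer_radius_mm - spec$aaa_wall_thickness_mm)
  wall <- aaa_outer & !lumen & !bone
  non_aaa <- disc_mask(co, spec$non_aaa_center_mm, spec$non_aaa_radius_mm)
  blood_r <- sqrt(spec$blood_pool_area_mm2 / pi)
  blood <- disc_mask(co, spec$blood_center_mm, blood_r)

  u <- spec$uptake
  act <- matrix(0, spec$grid_n, spec$grid_n)
  act[body] <- u$soft_tissue
  act[non_aaa] <- u$normal_aorta
  act[blood] <- u$blood
  act[wall] <- u$aaa_wall
  act[lumen] <- u$blood
  act[bone] <- u$bone

  h <- spec$hu
  ct <- matrix(-1000, spec$grid_n, spec$grid_n)
  ct[body] <- h$soft
  ct[non_aaa | blood | lumen] <- h$blood
  ct[bone] <- h$bone

  aaa_exc <- derive_aaa_exc(wall, bone, spec$exclusion_mm, spec$pixel_mm)
  list(activity = image_grid(act, spec$pixel_mm),
       ct = image_grid(ct, spec$pixel_mm),
       masks = roi_mask_set(aaa = wall, aaa_exc = aaa_exc,
                            non_aaa = non_aaa, blood = blood, bone = bone))
}
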