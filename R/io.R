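#' Write an image or mask to NIfTI
#'
#' Activity/CT images are written as float32, masks (logical matrices) as
#' 0/1 uint8. The pixel size is stored in the NIfTI `pixdim` header.
#'
#' @param x an [image_grid()] or a logical matrix.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param pixel_mm pixel size when writing a bare mask matrix.
#' @return `path`, invisibly.
#' @export
write_image <- function(x, path, pixel_mm = NULL) {
  if (inherits(x, "image_grid")) {
    arr <- x$values
    pix <- x$pixel_mm
    dt <- "float"
  } else if (is.logical(x)) {
    if (is.null(pixel_mm)) stop("pixel_mm is required when writing a mask")
    arr <- matrix(as.integer(x), nrow(x), ncol(x))
    pix <- pixel_mm
    dt <- "uint8"
  } else stop("x must be an image_grid or a logical mask")
  img <- RNifti::asNifti(structure(arr, pixdim = c(pix, pix)), datatype = dt)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read an image or mask from NIfTI
#'
#' @param path file path.
#' @param mask if `TRUE`, return a logical matrix (values must be 0/1);
#'   otherwise an [image_grid()] with the pixel size from the header.
#' @export
read_image <- function(path, mask = FALSE) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  img <- RNifti::readNifti(path)
  arr <- drop(as.array(img))
  vals <- matrix(as.numeric(arr), nrow(arr), ncol(arr))
  if (mask) {
    if (!all(vals %in% c(0, 1)))
      stop("mask file contains values other than 0/1")
    return(vals == 1)
  }
  image_grid(vals, RNifti::pixdim(img)[1])
}

#' Write a sinogram as plain text with a JSON sidecar
#'
#' Values go to a tab-separated text file; the geometry (and any `scale` /
#' `seed` attributes from [simulate_counts()]) goes to `<path>.json`.
#'
#' @param sino a [sinogram()].
#' @param path output path for the TSV values.
#' @return `path`, invisibly.
#' @export
write_sinogram <- function(sino, path) {
  stopifnot(inherits(sino, "sinogram"))
  utils::write.table(sino$values, path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  meta <- list(n_angles = sino$geometry$n_angles,
               n_bins = sino$geometry$n_bins,
               bin_mm = sino$geometry$bin_mm,
               angles = sino$geometry$angles,
               scale = attr(sino, "scale"),
               seed = attr(sino, "seed"))
  jsonlite::write_json(meta[!vapply(meta, is.null, logical(1))],
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a sinogram written by [write_sinogram()]
#'
#' @param path path to the TSV values (the sidecar is `<path>.json`).
#' @export
read_sinogram <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(sidecar))
    stop("sinogram file or JSON sidecar missing for: ", path)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  geom <- projection_geometry(meta$n_angles, meta$n_bins, meta$bin_mm,
                              angles = meta$angles)
  vals <- as.matrix(utils::read.table(path, sep = "\t"))
  dimnames(vals) <- NULL
  out <- sinogram(vals, geom)
  if (!is.null(meta$scale)) attr(out, "scale") <- meta$scale
  if (!is.null(meta$seed)) attr(out, "seed") <- meta$seed
  out
}
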