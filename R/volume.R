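#' 3D intensity volume with physical voxel spacing
#'
#' `volume_grid()` wraps a 3D numeric array together with its per-axis voxel
#' spacing in millimetres. It is the unit every pipeline stage consumes and
#' produces. Axis order is `(x, y, z)` with `z` the slice axis, so
#' `spacing[3]` is the slice thickness.
#'
#' @param data 3D numeric array of voxel intensities (finite values).
#' @param spacing Numeric length-3 vector of strictly positive voxel sizes in
#'   mm, ordered `(sx, sy, sz)`.
#' @return An object of class `volume_grid`.
#' @examples
#' v <- volume_grid(array(rnorm(8 * 8 * 4), c(8, 8, 4)), spacing = c(1, 1, 5))
#' dim(v)
#' @export
volume_grid <- function(data, spacing = c(1, 1, 1)) {
  data <- unclass(data)
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3D array", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be three strictly positive values (mm)", call. = FALSE)
  }
  if (any(!is.finite(data))) {
    stop("volume intensities must be finite", call. = FALSE)
  }
  structure(list(data = data, spacing = spacing), class = "volume_grid")
}

#' Binary mask on the grid of a companion volume
#'
#' @param data 3D array coercible to 0/1.
#' @param spacing Voxel spacing in mm, as in [volume_grid()].
#' @return An object of class `mask_volume`.
#' @export
mask_volume <- function(data, spacing = c(1, 1, 1)) {
  data <- unclass(data)
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3D array", call. = FALSE)
  }
  vals <- as.numeric(data)
  if (any(!is.finite(vals)) || !all(vals %in% c(0, 1))) {
    stop("mask values must be 0/1", call. = FALSE)
  }
  storage.mode(data) <- "integer"
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("`spacing` must be three strictly positive values (mm)", call. = FALSE)
  }
  structure(list(data = data, spacing = spacing), class = "mask_volume")
}

#' @export
dim.volume_grid <- function(x) dim(x$data)

#' @export
dim.mask_volume <- function(x) dim(x$data)

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf(
    "<volume_grid> %s voxels, spacing %s mm, range [%.4g, %.4g]\n",
    paste(dim(x$data), collapse = "x"),
    paste(signif(x$spacing, 3), collapse = "x"),
    min(x$data), max(x$data)
  ))
  invisible(x)
}

#' @export
print.mask_volume <- function(x, ...) {
  cat(sprintf(
    "<mask_volume> %s voxels, spacing %s mm, %d foreground\n",
    paste(dim(x$data), collapse = "x"),
    paste(signif(x$spacing, 3), collapse = "x"),
    sum(x$data)
  ))
  invisible(x)
}

is_volume_grid <- function(x) inherits(x, "volume_grid")
is_mask_volume <- function(x) inherits(x, "mask_volume")

stopifnot_same_grid <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data))) {
    stop("volume and mask are on different grids (shape mismatch)", call. = FALSE)
  }
  if (max(abs(a$spacing - b$spacing)) > 1e-8) {
    stop("volume and mask are on different grids (spacing mismatch)", call. = FALSE)
  }
  invisible(TRUE)
}

#' Read and write volumes as NIfTI
#'
#' Thin wrappers around RNifti keeping the mm spacing in the `pixdim` header
#' fields. Masks are re-binarised on read.
#'
#' @param x A [volume_grid()] or [mask_volume()].
#' @param path File path, conventionally ending in `.nii.gz`.
#' @return `write_volume_nifti()` returns `path` invisibly;
#'   `read_volume_nifti()` a `volume_grid`; `read_mask_nifti()` a
#'   `mask_volume`.
#' @export
write_volume_nifti <- function(x, path) {
  img <- RNifti::asNifti(x$data)
  RNifti::pixdim(img) <- x$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  volume_grid(array(as.numeric(img), dim(img)[1:3]), RNifti::pixdim(img)[1:3])
}

#' @rdname write_volume_nifti
#' @export
read_mask_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  mask_volume(array(as.integer(as.numeric(img) > 0.5), dim(img)[1:3]),
              RNifti::pixdim(img)[1:3])
}
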