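#' Construct a 3D scalar PET volume in SUV units
#'
#' A `scalar_volume` is a plain 3D array of standardized uptake values (SUV,
#' unitless) together with its voxel spacing and world origin. Axis order is
#' (x, y, z) with z the axial (slice) direction. World coordinates are in mm;
#' voxel indices are 0-based in world math (R arrays remain 1-based); the
#' origin is the world coordinate of the centre of voxel (0, 0, 0).
#'
#' @param values 3D numeric array of SUV values (finite, non-negative).
#' @param spacing numeric length-3, voxel edge lengths in mm (all > 0).
#' @param origin numeric length-3, world coordinate (mm) of the centre of
#'   voxel (0, 0, 0).
#' @return An object of class `scalar_volume` with fields `values`,
#'   `spacing`, `origin`.
#' @examples
#' vol <- scalar_volume(array(1, c(4, 4, 4)), spacing = c(2, 2, 2))
#' voxel_volume_ml(vol)
#' @export
scalar_volume <- function(values, spacing = c(2, 2, 2), origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite numbers (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers (mm)", call. = FALSE)
  storage.mode(values) <- "double"
  if (any(!is.finite(values)))
    stop("SUV values must be finite", call. = FALSE)
  if (any(values < 0))
    stop("SUV values must be non-negative", call. = FALSE)
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "scalar_volume")
}

#' @export
print.scalar_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<scalar_volume> %d x %d x %d voxels, spacing %s mm, origin %s mm\n",
              d[1], d[2], d[3],
              paste(format(x$spacing), collapse = " x "),
              paste(format(x$origin), collapse = ", ")))
  cat(sprintf("  SUV range [%.3f, %.3f], voxel volume %.4f ml\n",
              min(x$values), max(x$values), voxel_volume_ml(x)))
  invisible(x)
}

#' Voxel volume in millilitres
#'
#' @param vol a `scalar_volume`.
#' @return Product of the three spacings divided by 1000 (mm^3 to ml).
#' @examples
#' voxel_volume_ml(scalar_volume(array(0, c(2, 2, 2)), spacing = c(10, 10, 10)))
#' @export
voxel_volume_ml <- function(vol) {
  stopifnot(inherits(vol, "scalar_volume"))
  prod(vol$spacing) / 1000
}

#' World coordinates of voxel centres along one axis
#'
#' @param vol a `scalar_volume`.
#' @param axis 1, 2 or 3 (x, y, z).
#' @return Numeric vector of world coordinates (mm) of voxel centres.
#' @keywords internal
axis_coords <- function(vol, axis) {
  n <- dim(vol$values)[axis]
  vol$origin[axis] + vol$spacing[axis] * (seq_len(n) - 1)
}

#' Read a 3D scalar volume from a NIfTI-1 file
#'
#' Spacing is taken from the header pixdim, the origin from the qform offset
#' (the world coordinate of voxel (0,0,0)). Values written by
#' [write_volume()] round-trip bitwise (float64 storage).
#'
#' @param path path to a `.nii` or `.nii.gz` file holding a 3D scalar image.
#' @return A [scalar_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stop("expected a 3D image, got ", length(dim(arr)), "D: ", path,
         call. = FALSE)
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("non-positive voxel spacing in header: ", path, call. = FALSE)
  org <- RNifti::xform(img)[1:3, 4]
  attributes(arr) <- list(dim = dim(arr))
  scalar_volume(arr, spacing = sp, origin = as.numeric(org))
}

#' Write a scalar volume to a NIfTI-1 file
#'
#' @param vol a `scalar_volume`.
#' @param path output path (`.nii` or `.nii.gz`); overwritten if present.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "scalar_volume"))
  hdr <- RNifti::niftiHeader(list(
    pixdim = c(1, vol$spacing, 0, 0, 0, 0),
    qform_code = 2,
    qoffset_x = vol$origin[1],
    qoffset_y = vol$origin[2],
    qoffset_z = vol$origin[3]))
  img <- RNifti::asNifti(vol$values, reference = hdr, datatype = "double")
  RNifti::writeNifti(img, path)
  invisible(path)
}
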