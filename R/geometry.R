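#' Ellipsoid volume of interest (VOI)
#'
#' Axis-aligned ellipsoid in world coordinates, used to enclose a lesion
#' while excluding off-target avid structures.
#'
#' @param center numeric length-3, world centre in mm.
#' @param semi_axes numeric length-3, semi-axis lengths in mm (all > 0).
#' @return An object of class `ellipsoid_voi`.
#' @export
ellipsoid_voi <- function(center, semi_axes) {
  center <- as.numeric(center); semi_axes <- as.numeric(semi_axes)
  stopifnot(length(center) == 3L, length(semi_axes) == 3L)
  if (any(!is.finite(semi_axes)) || any(semi_axes <= 0))
    stop("semi_axes must be positive", call. = FALSE)
  structure(list(center = center, semi_axes = semi_axes),
            class = c("ellipsoid_voi", "roi_geometry"))
}

#' Cubic/box reference region of interest
#'
#' Axis-aligned box, e.g. the 10x10x10 mm parotid and 30x30x30 mm spleen
#' reference ROIs.
#'
#' @param center numeric length-3, world centre in mm.
#' @param edge_lengths numeric length-3 (or scalar, recycled), edge lengths
#'   in mm (all > 0).
#' @return An object of class `box_roi`.
#' @export
box_roi <- function(center, edge_lengths) {
  center <- as.numeric(center)
  edge_lengths <- rep_len(as.numeric(edge_lengths), 3L)
  stopifnot(length(center) == 3L)
  if (any(!is.finite(edge_lengths)) || any(edge_lengths <= 0))
    stop("edge_lengths must be positive", call. = FALSE)
  structure(list(center = center, edge_lengths = edge_lengths),
            class = c("box_roi", "roi_geometry"))
}

#' Circular single-slice reference region of interest
#'
#' Axial-plane disc, e.g. the 30 mm-diameter liver reference ROI. Rasterizes
#' onto exactly one axial slice: the slice whose voxel-centre z is nearest
#' the disc centre.
#'
#' @param center numeric length-3, world centre in mm.
#' @param diameter disc diameter in mm (> 0).
#' @return An object of class `disc_roi`.
#' @export
disc_roi <- function(center, diameter) {
  center <- as.numeric(center); diameter <- as.numeric(diameter)
  stopifnot(length(center) == 3L, length(diameter) == 1L)
  if (!is.finite(diameter) || diameter <= 0)
    stop("diameter must be positive", call. = FALSE)
  structure(list(center = center, diameter = diameter),
            class = c("disc_roi", "roi_geometry"))
}

#' Analytic ellipsoid volume in millilitres
#'
#' @param semi_axes numeric length-3 semi-axes in mm.
#' @return (4/3) * pi * a * b * c / 1000.
#' @examples
#' ellipsoid_volume_ml(c(10, 10, 10))  # 4.18879 ml sphere
#' @export
ellipsoid_volume_ml <- function(semi_axes) {
  semi_axes <- as.numeric(semi_axes)
  stopifnot(length(semi_axes) == 3L)
  if (any(!is.finite(semi_axes)) || any(semi_axes <= 0))
    stop("semi_axes must be positive", call. = FALSE)
  (4 / 3) * pi * prod(semi_axes) / 1000
}

#' Rasterize a geometry onto a volume's voxel grid
#'
#' A voxel belongs to the mask iff its centre (world coordinates) lies inside
#' the geometry (voxel-centre inclusion; no partial-volume fractions). For a
#' [disc_roi()] only voxels of the single axial slice nearest the disc centre
#' are eligible.
#'
#' @param vol a [scalar_volume()] providing the grid.
#' @param geom an [ellipsoid_voi()], [box_roi()] or [disc_roi()].
#' @return Logical 3D array with the same dimensions as `vol$values`.
#'   Errors if the mask would be empty (geometry does not cover any voxel
#'   centre).
#' @export
rasterize <- function(vol, geom) {
  stopifnot(inherits(vol, "scalar_volume"))
  UseMethod("rasterize", geom)
}

#' @export
rasterize.ellipsoid_voi <- function(vol, geom) {
  x <- (axis_coords(vol, 1) - geom$center[1]) / geom$semi_axes[1]
  y <- (axis_coords(vol, 2) - geom$center[2]) / geom$semi_axes[2]
  z <- (axis_coords(vol, 3) - geom$center[3]) / geom$semi_axes[3]
  d <- dim(vol$values)
  m <- outer(outer(x^2, y^2, `+`), z^2, `+`) <= 1
  dim(m) <- d
  check_nonempty_mask(m, "ellipsoid_voi")
}

#' @export
rasterize.box_roi <- function(vol, geom) {
  half <- geom$edge_lengths / 2
  inx <- abs(axis_coords(vol, 1) - geom$center[1]) <= half[1]
  iny <- abs(axis_coords(vol, 2) - geom$center[2]) <= half[2]
  inz <- abs(axis_coords(vol, 3) - geom$center[3]) <= half[3]
  m <- outer(outer(inx, iny, `&`), inz, `&`)
  dim(m) <- dim(vol$values)
  check_nonempty_mask(m, "box_roi")
}

#' @export
rasterize.disc_roi <- function(vol, geom) {
  zc <- axis_coords(vol, 3)
  k <- which.min(abs(zc - geom$center[3]))
  r2 <- (geom$diameter / 2)^2
  dx2 <- (axis_coords(vol, 1) - geom$center[1])^2
  dy2 <- (axis_coords(vol, 2) - geom$center[2])^2
  slice <- outer(dx2, dy2, `+`) <= r2
  m <- array(FALSE, dim(vol$values))
  m[, , k] <- slice
  check_nonempty_mask(m, "disc_roi")
}

check_nonempty_mask <- function(m, what) {
  if (!any(m))
    stop("geometry (", what, ") covers no voxel centre on this grid",
         call. = FALSE)
  m
}
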