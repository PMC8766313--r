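#' Construct a CT volume
#'
#' A `ct_volume` is a calibrated 3D intensity grid in Hounsfield units (HU)
#' together with its patient-space pose. World coordinates follow the
#' DICOM-native LPS convention: X towards patient-left, Y towards
#' patient-posterior, Z towards patient-superior, all in mm. Voxel indices
#' are 0-based; the axial slice index runs along the third array dimension.
#'
#' @param voxels 3D numeric array of HU values (dim = c(nx, ny, nz)).
#' @param spacing numeric length-3, mm per voxel along each axis; all > 0.
#' @param origin numeric length-3, world position (mm) of voxel (0,0,0).
#' @param orientation 3x3 direction-cosine matrix (orthonormal, det +1)
#'   whose columns are the world directions of the voxel axes.
#' @param scan_id character label for the scan.
#' @param days_after_surgery integer days after surgery, or `NA`.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing, origin = c(0, 0, 0),
                      orientation = diag(3), scan_id = "scan",
                      days_after_surgery = NA_integer_) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  orientation <- matrix(as.numeric(orientation), 3, 3)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive finite values", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be three finite values", call. = FALSE)
  if (max(abs(crossprod(orientation) - diag(3))) > 1e-6 ||
      abs(det(orientation) - 1) > 1e-6)
    stop("orientation must be orthonormal with determinant +1", call. = FALSE)
  if (any(!is.finite(voxels)))
    stop("HU values must be finite", call. = FALSE)
  structure(
    list(voxels = voxels, spacing = spacing, origin = origin,
         orientation = orientation, scan_id = as.character(scan_id),
         days_after_surgery = as.integer(days_after_surgery)),
    class = "ct_volume")
}

#' Construct a binary mask sharing a volume's geometry
#'
#' @param voxels 3D logical array.
#' @param geometry a `ct_volume` or `ct_mask` providing spacing, origin and
#'   orientation, or a list with those fields.
#' @param label structure name (e.g. "implant", "pelvis", "bone").
#' @param allow_empty if `FALSE` (default), an all-FALSE mask is an error.
#' @return An object of class `ct_mask`.
#' @export
ct_mask <- function(voxels, geometry, label = "mask", allow_empty = TRUE) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L)
  voxels <- array(as.logical(voxels), dim(voxels))
  if (!allow_empty && !any(voxels))
    stop("mask is empty", call. = FALSE)
  structure(
    list(voxels = voxels, spacing = geometry$spacing, origin = geometry$origin,
         orientation = geometry$orientation, label = as.character(label)),
    class = "ct_mask")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<ct_volume '%s'> %s voxels, spacing %s mm, HU [%g, %g]\n",
              x$scan_id, paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
print.ct_mask <- function(x, ...) {
  cat(sprintf("<ct_mask '%s'> %s voxels, %d foreground\n", x$label,
              paste(dim(x$voxels), collapse = "x"), sum(x$voxels)))
  invisible(x)
}

same_geometry <- function(a, b, tol = 1e-6) {
  all(dim(a$voxels) == dim(b$voxels)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol &&
    max(abs(a$orientation - b$orientation)) < tol
}

#' Map 0-based voxel indices to world coordinates (mm, LPS)
#'
#' world = origin + orientation %*% (index * spacing). Accepts a single
#' index triple or an n x 3 matrix; continuous (fractional) indices are
#' allowed for sub-voxel positions such as cell corners.
#'
#' @param geom a `ct_volume` or `ct_mask` (or list with spacing/origin/
#'   orientation).
#' @param index numeric length-3 or n x 3 matrix of 0-based indices.
#' @param check if `TRUE`, error when an integer index lies outside the grid.
#' @return n x 3 matrix of world points (mm).
#' @export
voxel_to_world <- function(geom, index, check = FALSE) {
  index <- rbind_points(index)
  if (check) {
    d <- dim(geom$voxels)
    bad <- index[, 1] < 0 | index[, 1] > d[1] - 1 |
      index[, 2] < 0 | index[, 2] > d[2] - 1 |
      index[, 3] < 0 | index[, 3] > d[3] - 1
    if (any(bad)) stop("voxel index out of grid", call. = FALSE)
  }
  scaled <- sweep(index, 2, geom$spacing, `*`)
  sweep(scaled %*% t(geom$orientation), 2, geom$origin, `+`)
}

#' Map world coordinates (mm) to continuous 0-based voxel indices
#'
#' Exact inverse of [voxel_to_world()]; the two compose to the identity.
#'
#' @inheritParams voxel_to_world
#' @param world numeric length-3 or n x 3 matrix of world points.
#' @return n x 3 matrix of continuous voxel indices.
#' @export
world_to_voxel <- function(geom, world) {
  world <- rbind_points(world)
  centered <- sweep(world, 2, geom$origin, `-`)
  sweep(centered %*% geom$orientation, 2, geom$spacing, `/`)
}

rbind_points <- function(p) {
  if (is.null(dim(p))) p <- matrix(as.numeric(p), ncol = 3)
  else p <- matrix(as.numeric(p), ncol = 3, nrow = nrow(p))
  p
}

#' Extract the axial slice nearest a world z coordinate
#'
#' Returns the slice whose center is nearest `z_mm` and reports the realized
#' z. The slice axis is the third voxel axis.
#'
#' @param vol a `ct_volume`.
#' @param z_mm requested world z (mm).
#' @return list with `values` (2D HU matrix), `index` (0-based slice index),
#'   `z_realized` (mm), and `geometry` (the source volume's geometry with the
#'   slice origin).
#' @export
extract_axial_slice <- function(vol, z_mm) {
  nz <- dim(vol$voxels)[3]
  zc <- voxel_to_world(vol, cbind(0, 0, seq_len(nz) - 1))[, 3]
  dz <- vol$spacing[3]
  if (z_mm < min(zc) - dz / 2 || z_mm > max(zc) + dz / 2)
    stop(sprintf("requested z %.3f mm outside volume extent [%.3f, %.3f]",
                 z_mm, min(zc) - dz / 2, max(zc) + dz / 2), call. = FALSE)
  k <- which.min(abs(zc - z_mm))
  list(values = vol$voxels[, , k],
       index = k - 1L,
       z_realized = zc[k],
       geometry = list(spacing = vol$spacing,
                       origin = as.numeric(voxel_to_world(vol, c(0, 0, k - 1))),
                       orientation = vol$orientation))
}

#' Timepoint table for a follow-up series
#'
#' @param scan_id character vector of scan labels.
#' @param days_after_surgery integer days; must be strictly increasing.
#' @return data.frame with class `scan_timepoints`.
#' @export
scan_timepoints <- function(scan_id, days_after_surgery) {
  days <- as.integer(days_after_surgery)
  if (any(diff(days) <= 0))
    stop("days_after_surgery must be strictly increasing", call. = FALSE)
  structure(data.frame(scan_id = as.character(scan_id),
                       days_after_surgery = days,
                       stringsAsFactors = FALSE),
            class = c("scan_timepoints", "data.frame"))
}
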