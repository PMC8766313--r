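#' Default BMD category binning
#'
#' Ten representative BMD values (g/cm^3): 0.00, 0.12, 0.25, 0.37, 0.50,
#' 0.62, 0.75, 0.87, 1.00, 1.12. Bin edges sit at midpoints between
#' consecutive representatives; bins are half-open `[low, high)` so a
#' value exactly on an edge falls in the higher category; everything
#' below the first edge is category 1 and at/above the last edge is
#' category 10.
#'
#' @param representatives strictly increasing numeric vector (default the
#'   ten standard values).
#' @return object of class `category_binning` with `representatives` and
#'   `edges` (length one less).
#' @export
category_binning <- function(representatives = c(0.00, 0.12, 0.25, 0.37,
                                                 0.50, 0.62, 0.75, 0.87,
                                                 1.00, 1.12)) {
  representatives <- as.numeric(representatives)
  if (any(diff(representatives) <= 0))
    stop("representatives must be strictly increasing", call. = FALSE)
  structure(list(representatives = representatives,
                 edges = (head(representatives, -1) +
                            tail(representatives, -1)) / 2),
            class = "category_binning")
}

#' Assign BMD values to categories
#' @param bmd numeric vector (g/cm^3); values are clamped below at 0.
#' @param binning a `category_binning`.
#' @return integer category indices (1..n_categories).
#' @export
bmd_category <- function(bmd, binning = category_binning()) {
  bmd <- pmax(bmd, 0)
  findInterval(bmd, binning$edges) + 1L
}

#' Fit the HU to BMD calibration curve from phantom scans
#'
#' Per scan, the known insertion densities are regressed on the mean
#' insertion HU by ordinary least squares (`BMD = a + b * HU`); the mean
#' conversion curve averages the per-scan coefficients across scans
#' (set `pooled = TRUE` to fit one regression through all points
#' instead).
#'
#' @param insertion_hu list (one element per scan) of numeric vectors of
#'   per-insertion mean HU, or a single numeric vector for one scan.
#' @param densities known insertion densities (g/cm^3), same length and
#'   order as each HU vector; default `c(0, 0.05, 0.10, 0.15, 0.20)`.
#' @param pooled fit a single regression on all (HU, density) points.
#' @param scan_ids optional labels.
#' @return object of class `calibration_curve`: `a` (g/cm^3), `b`
#'   (g/cm^3 per HU), `r_squared`, `per_scan` data.frame, `scan_ids`.
#' @export
fit_calibration <- function(insertion_hu,
                            densities = c(0, 0.05, 0.10, 0.15, 0.20),
                            pooled = FALSE, scan_ids = NULL) {
  if (is.numeric(insertion_hu)) insertion_hu <- list(insertion_hu)
  if (length(unique(densities)) < 2)
    stop("degenerate fit: need >= 2 distinct density levels", call. = FALSE)
  fits <- lapply(insertion_hu, function(hu) {
    if (length(hu) != length(densities))
      stop("one mean HU per insertion required", call. = FALSE)
    if (diff(range(hu)) < 1e-9)
      stop("degenerate fit: identical HU across insertions", call. = FALSE)
    fit <- stats::lm(densities ~ hu)
    # noiseless phantoms fit perfectly; the R^2 warning is expected
    c(a = unname(stats::coef(fit)[1]), b = unname(stats::coef(fit)[2]),
      r2 = suppressWarnings(summary(fit)$r.squared))
  })
  per <- as.data.frame(do.call(rbind, fits))
  per$scan_id <- scan_ids %||% sprintf("scan%d", seq_len(nrow(per)))
  if (pooled) {
    hu_all <- unlist(insertion_hu)
    d_all <- rep(densities, length(insertion_hu))
    fit <- stats::lm(d_all ~ hu_all)
    a <- unname(stats::coef(fit)[1]); b <- unname(stats::coef(fit)[2])
    r2 <- suppressWarnings(summary(fit)$r.squared)
  } else {
    a <- mean(per$a); b <- mean(per$b); r2 <- mean(per$r2)
  }
  structure(list(a = a, b = b, r_squared = r2, per_scan = per,
                 scan_ids = per$scan_id),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve> BMD = %.6g + %.6g * HU (R^2 %.4f, %d scan(s))\n",
    x$a, x$b, x$r_squared, nrow(x$per_scan)))
  invisible(x)
}

#' Select the ROI axial slice at the midplane of two screw tips
#'
#' The ROI rule: the axial slice nearest the midpoint of the two pedicle
#' screw tips' z coordinates in the registered frame.
#'
#' @param vol a `ct_volume` (already in the reference frame).
#' @param screw_tip_a,screw_tip_b world-mm points (e.g. right L4 and L5
#'   pedicle screw tips).
#' @return as [extract_axial_slice()]: `values`, `index`, `z_realized`,
#'   `geometry`.
#' @export
select_roi_slice <- function(vol, screw_tip_a, screw_tip_b) {
  for (p in list(screw_tip_a, screw_tip_b)) {
    v <- world_to_voxel(vol, p)
    d <- dim(vol$voxels)
    if (any(v < -0.5) || any(v > d - 0.5))
      stop("screw tip outside volume", call. = FALSE)
  }
  z_mid <- (as.numeric(screw_tip_a)[3] + as.numeric(screw_tip_b)[3]) / 2
  extract_axial_slice(vol, z_mid)
}

#' Build a single-slice voxel finite-element BMD mesh
#'
#' One hexahedral element per in-mask pixel of the ROI slice; every
#' element carries its HU, its calibrated BMD (`a + b * HU`, clamped
#' below at 0), and its category index. All elements share the volume
#' dx * dy * dz mm^3.
#'
#' @param slice a slice as returned by [extract_axial_slice()] /
#'   [select_roi_slice()].
#' @param bone_mask 2D logical matrix matching the slice (in-mask pixels
#'   become elements).
#' @param curve a `calibration_curve`.
#' @param binning a `category_binning`.
#' @return object of class `voxel_fe_mesh`: `elements` data.frame (i, j
#'   0-based pixel indices, hu, bmd, category), `element_volume_mm3`,
#'   `geometry`, `n_categories`.
#' @export
build_bmd_mesh <- function(slice, bone_mask, curve,
                           binning = category_binning()) {
  stopifnot(all(dim(bone_mask) == dim(slice$values)))
  if (!any(bone_mask)) stop("bone mask is empty", call. = FALSE)
  idx <- which(bone_mask, arr.ind = TRUE)
  hu <- slice$values[bone_mask]
  bmd <- pmax(curve$a + curve$b * hu, 0)
  structure(list(
    elements = data.frame(i = idx[, 1] - 1L, j = idx[, 2] - 1L, hu = hu,
                          bmd = bmd,
                          category = bmd_category(bmd, binning)),
    element_volume_mm3 = prod(slice$geometry$spacing),
    geometry = slice$geometry,
    n_categories = length(binning$representatives)),
    class = "voxel_fe_mesh")
}

#' @export
print.voxel_fe_mesh <- function(x, ...) {
  cat(sprintf("<voxel_fe_mesh> %d elements of %.4f mm^3\n",
              nrow(x$elements), x$element_volume_mm3))
  invisible(x)
}

#' Longitudinal per-category volume table
#'
#' One row per scan, one column per BMD category; each cell is
#' element volume x element count in cm^3. Row sums equal each scan's
#' total ROI bone volume.
#'
#' @param meshes list of `voxel_fe_mesh`, one per scan.
#' @param scan_ids,days labels per scan.
#' @return object of class `bmd_volume_table`: data.frame with `scan_id`,
#'   `days` and `cat1..catN` columns (cm^3).
#' @export
category_volumes <- function(meshes, scan_ids = NULL, days = NULL) {
  stopifnot(length(meshes) >= 1)
  ncat <- meshes[[1]]$n_categories
  rows <- t(vapply(meshes, function(m)
    tabulate(m$elements$category, nbins = ncat) *
      m$element_volume_mm3 / 1000, numeric(ncat)))
  df <- data.frame(scan_id = scan_ids %||%
                     sprintf("scan%d", seq_along(meshes)),
                   days = days %||% rep(NA_integer_, length(meshes)))
  vol <- as.data.frame(rows)
  names(vol) <- sprintf("cat%d", seq_len(ncat))
  out <- cbind(df, vol)
  class(out) <- c("bmd_volume_table", "data.frame")
  out
}

#' Write a BMD volume table as CSV
#' @param table a `bmd_volume_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_volume_table_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Read a BMD volume table from CSV
#' @param path CSV with `scan_id`, `days`, `cat1..catN` columns.
#' @return a `bmd_volume_table`.
#' @export
read_volume_table_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("scan_id", "days") %in% names(df)) ||
      !any(grepl("^cat\\d+$", names(df))))
    stop("not a BMD volume table CSV", call. = FALSE)
  class(df) <- c("bmd_volume_table", "data.frame")
  df
}

#' Export a voxel FE mesh in legacy VTK format
#'
#' Hexahedral elements with BMD and category as cell data; usable in
#' ParaView and as input scaffolding for downstream FE work.
#'
#' @param mesh a `voxel_fe_mesh`.
#' @param path output .vtk path.
#' @return `path`, invisibly.
#' @export
write_bmd_vtk <- function(mesh, path) {
  el <- mesh$elements
  sp <- mesh$geometry$spacing
  orig <- mesh$geometry$origin
  n <- nrow(el)
  corner_off <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                      c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  pts <- do.call(rbind, lapply(seq_len(n), function(r) {
    base <- c(el$i[r] - 0.5, el$j[r] - 0.5, -0.5)
    sweep(corner_off, 2, base, `+`)
  }))
  world <- sweep(sweep(pts, 2, sp, `*`) %*%
                   t(mesh$geometry$orientation), 2, orig, `+`)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "rodmap voxel FE BMD mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nrow(world)),
               sprintf("%.6f %.6f %.6f",
                       world[, 1], world[, 2], world[, 3]),
               sprintf("CELLS %d %d", n, n * 9)), con)
  cells <- t(vapply(seq_len(n), function(r)
    c(8L, (r - 1L) * 8L + 0:7), integer(9)))
  writeLines(apply(cells, 1, paste, collapse = " "), con)
  writeLines(c(sprintf("CELL_TYPES %d", n),
               rep("12", n),
               sprintf("CELL_DATA %d", n),
               "SCALARS bmd double 1", "LOOKUP_TABLE default",
               sprintf("%.6f", el$bmd),
               "SCALARS category int 1", "LOOKUP_TABLE default",
               sprintf("%d", el$category)), con)
  invisible(path)
}
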