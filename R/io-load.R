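#' Load a CT volume from disk
#'
#' Dispatches on `format`: a DICOM series directory, a NIfTI file
#' (.nii/.nii.gz, via RNifti), or an NRRD file. All formats are returned in
#' the package's LPS world convention with voxel values rescaled to
#' Hounsfield units using the format's slope/intercept metadata.
#'
#' @param path file (nifti, nrrd) or directory (dicom_series) path.
#' @param format one of `"dicom_series"`, `"nifti"`, `"nrrd"`; default
#'   guessed from the path.
#' @param scan_id optional scan label (default from file name).
#' @param days_after_surgery optional integer days.
#' @return a `ct_volume`.
#' @export
load_volume <- function(path, format = c("guess", "dicom_series", "nifti",
                                         "nrrd"),
                        scan_id = NULL, days_after_surgery = NA_integer_) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("path does not exist: ", path, call. = FALSE)
  if (format == "guess") {
    format <- if (dir.exists(path)) "dicom_series"
    else if (grepl("\\.nii(\\.gz)?$", path)) "nifti"
    else if (grepl("\\.nrrd$", path)) "nrrd"
    else stop("cannot guess format of ", path, call. = FALSE)
  }
  vol <- switch(format,
    nrrd = read_nrrd(path),
    nifti = read_nifti_volume(path),
    dicom_series = read_dicom_series(path))
  if (!is.null(scan_id)) vol$scan_id <- as.character(scan_id)
  if (!is.na(days_after_surgery))
    vol$days_after_surgery <- as.integer(days_after_surgery)
  vol
}

# NIfTI stores affines in RAS; flip the first two world axes to LPS.
read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  hdr <- RNifti::niftiHeader(img)
  vox <- as.array(img)
  if (length(dim(vox)) != 3L) stop("only 3D NIfTI supported", call. = FALSE)
  # RNifti applies scl_slope/scl_inter on read; values are already HU.
  aff <- RNifti::xform(img)              # 4x4, voxel (0-based) -> RAS mm
  A <- diag(c(-1, -1, 1, 1)) %*% aff     # RAS -> LPS
  M <- A[1:3, 1:3]
  spacing <- sqrt(colSums(M^2))
  orientation <- sweep(M, 2, spacing, `/`)
  if (det(orientation) < 0)
    stop("NIfTI volume has a left-handed orientation; not supported",
         call. = FALSE)
  ct_volume(vox, spacing, origin = A[1:3, 4], orientation = orientation,
            scan_id = sub("\\.nii(\\.gz)?$", "", basename(path)))
}

#' Write a CT volume as NIfTI
#'
#' Inverse of the NIfTI branch of [load_volume()]; the LPS geometry is
#' converted back to the RAS affine NIfTI expects.
#'
#' @param vol a `ct_volume`.
#' @param path output .nii or .nii.gz path.
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(vol, path) {
  A <- rbind(cbind(vol$orientation %*% diag(vol$spacing), vol$origin),
             c(0, 0, 0, 1))
  aff <- diag(c(-1, -1, 1, 1)) %*% A     # LPS -> RAS
  img <- RNifti::asNifti(vol$voxels)
  img <- RNifti::`pixdim<-`(img, vol$spacing)
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
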