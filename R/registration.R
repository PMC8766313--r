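#' Rigid transform constructor
#'
#' A proper rigid transform `y = R x + t` mapping a follow-up scan's
#' coordinates into the reference (first-scan) pelvic frame.
#'
#' @param rotation 3x3 orthonormal matrix with det +1.
#' @param translation length-3 mm vector.
#' @param rms_residual landmark RMS residual (mm), if known.
#' @param landmark_count number of landmarks used in the fit.
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            rms_residual = NA_real_,
                            landmark_count = NA_integer_) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  translation <- as.numeric(translation)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9)
    stop("rotation must be orthonormal with det +1", call. = FALSE)
  structure(list(rotation = rotation, translation = translation,
                 rms_residual = rms_residual,
                 landmark_count = as.integer(landmark_count)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf(
    "<rigid_transform> rotation %.3f deg, translation (%.3f, %.3f, %.3f) mm",
    ang, x$translation[1], x$translation[2], x$translation[3]))
  if (!is.na(x$rms_residual))
    cat(sprintf(", rms %.4f mm (n=%d)", x$rms_residual, x$landmark_count))
  cat("\n")
  invisible(x)
}

#' Compose two rigid transforms (apply `b`, then `a`)
#' @param a,b `rigid_transform` objects.
#' @return their composition as a `rigid_transform`.
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param T a `rigid_transform`.
#' @return the inverse `rigid_transform`.
#' @export
invert_transform <- function(T) {
  rigid_transform(t(T$rotation),
                  as.numeric(-t(T$rotation) %*% T$translation))
}

#' Named landmark set
#'
#' @param points n x 3 matrix of world-mm coordinates (n >= 3).
#' @param names unique landmark names, fixed order.
#' @return object of class `landmark_set`.
#' @export
landmark_set <- function(points, names) {
  points <- rbind_points(points)
  names <- as.character(names)
  if (nrow(points) < 3) stop("need at least 3 landmarks", call. = FALSE)
  if (anyDuplicated(names)) stop("landmark names must be unique",
                                 call. = FALSE)
  if (length(names) != nrow(points))
    stop("one name per point required", call. = FALSE)
  dmin <- min(stats::dist(points))
  if (dmin < 1)
    stop(sprintf("landmarks closer than 1 mm (min %.3f mm)", dmin),
         call. = FALSE)
  structure(list(points = points, names = names), class = "landmark_set")
}

#' Least-squares rigid registration of paired landmarks (Kabsch)
#'
#' Finds the proper rotation and translation minimizing
#' sum ||R p + t - q||^2 over paired landmarks, by centroid subtraction,
#' SVD of the cross-covariance, and determinant correction so reflections
#' are excluded. Closed-form and deterministic.
#'
#' @param moving,fixed `landmark_set` objects with identical names in
#'   identical order.
#' @return a `rigid_transform` mapping moving into the fixed frame, with
#'   `rms_residual` and `landmark_count` filled in.
#' @export
fit_rigid_landmarks <- function(moving, fixed) {
  if (!identical(moving$names, fixed$names))
    stop("pairing error: landmark names/order differ", call. = FALSE)
  P <- moving$points; Q <- fixed$points
  n <- nrow(P)
  if (n < 3) stop("insufficient landmarks (need >= 3)", call. = FALSE)
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  sv <- svd(crossprod(Pc, Qc))
  if (sv$d[2] / max(sv$d[1], .Machine$double.eps) < 1e-8)
    stop("degenerate configuration: landmarks are collinear", call. = FALSE)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_ <- cq - as.numeric(R %*% cp)
  res <- Pc %*% t(R) - Qc
  rigid_transform(R, t_, rms_residual = sqrt(mean(rowSums(res^2))),
                  landmark_count = n)
}

#' Apply a rigid transform
#'
#' Points and mesh vertices are mapped exactly. A `ct_mask` is resampled
#' into a reference grid with nearest-neighbour interpolation so binary
#' labels are preserved: each reference voxel center is pulled back
#' through the inverse transform into the moving mask.
#'
#' @param T a `rigid_transform`.
#' @param target n x 3 point matrix, `landmark_set`, `surface_mesh`, or
#'   `ct_mask`.
#' @param reference for masks: a `ct_volume`/`ct_mask` defining the output
#'   grid (default: the mask's own grid).
#' @return transformed object of the same type.
#' @export
apply_transform <- function(T, target, reference = NULL) {
  map <- function(p) sweep(p %*% t(T$rotation), 2, T$translation, `+`)
  if (inherits(target, "surface_mesh")) {
    target$vertices <- map(target$vertices)
    return(target)
  }
  if (inherits(target, "landmark_set")) {
    target$points <- map(target$points)
    return(target)
  }
  if (inherits(target, "ct_mask")) {
    ref <- reference %||% target
    dims <- dim(ref$voxels)
    centers <- arrayInd(seq_len(prod(dims)), dims) - 1
    world <- voxel_to_world(ref, centers)
    Ti <- invert_transform(T)
    src <- world_to_voxel(target,
                          sweep(world %*% t(Ti$rotation), 2,
                                Ti$translation, `+`))
    src <- round(src)
    d <- dim(target$voxels)
    ok <- src[, 1] >= 0 & src[, 1] <= d[1] - 1 &
      src[, 2] >= 0 & src[, 2] <= d[2] - 1 &
      src[, 3] >= 0 & src[, 3] <= d[3] - 1
    out <- logical(prod(dims))
    lin <- src[ok, 1] + 1 + d[1] * src[ok, 2] + d[1] * d[2] * src[ok, 3]
    out[ok] <- target$voxels[lin]
    return(ct_mask(array(out, dims), ref, label = target$label))
  }
  map(rbind_points(target))
}

#' Read landmarks from a CSV sidecar
#'
#' Expected columns: `scan_id, name, x, y, z` (mm, LPS).
#'
#' @param path CSV path.
#' @return named list of `landmark_set` by scan_id.
#' @export
read_landmarks_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("scan_id", "name", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("landmark CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  out <- lapply(split(df, df$scan_id), function(d)
    landmark_set(cbind(d$x, d$y, d$z), d$name))
  out[unique(df$scan_id)]
}

#' Write landmarks to CSV
#' @param landmarks named list of `landmark_set` by scan_id.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_landmarks_csv <- function(landmarks, path) {
  rows <- do.call(rbind, lapply(names(landmarks), function(id) {
    ls <- landmarks[[id]]
    data.frame(scan_id = id, name = ls$names, x = ls$points[, 1],
               y = ls$points[, 2], z = ls$points[, 3])
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Persist a rigid transform as JSON (row-major rotation + translation)
#' @param T a `rigid_transform`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_transform_json <- function(T, path) {
  jsonlite::write_json(
    list(rotation_row_major = as.vector(t(T$rotation)),
         translation = T$translation, rms_residual = T$rms_residual,
         landmark_count = T$landmark_count),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a rigid transform from JSON
#' @param path JSON path written by [write_transform_json()].
#' @return a `rigid_transform`.
#' @export
read_transform_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(matrix(j$rotation_row_major, 3, 3, byrow = TRUE),
                  j$translation,
                  rms_residual = j$rms_residual %||% NA_real_,
                  landmark_count = j$landmark_count %||% NA_integer_)
}
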