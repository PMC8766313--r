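# Metro-style sampled surface distances between triangle meshes.

# Squared distance from one point to every triangle of a mesh, via the
# barycentric projection (interior case) and the three edge segments
# (exterior case); exact, no voxelization.
point_tri_dist2 <- function(p, tri) {
  D <- sweep(tri$A, 2, p)                     # A - p
  d <- rowSums(tri$E0 * D); e <- rowSums(tri$E1 * D)
  s <- (tri$b * e - tri$c * d) / tri$det
  t <- (tri$b * d - tri$a * e) / tri$det
  inside <- is.finite(s) & is.finite(t) & s >= 0 & t >= 0 & s + t <= 1
  # interior projection
  q1 <- tri$A + s * tri$E0 + t * tri$E1
  d2_in <- rowSums(sweep(q1, 2, p)^2)
  # edge segments AB (E0), AC (E1), BC
  seg2 <- function(P0, Dir, len2) {
    w <- sweep(-P0, 2, -p)                   # p - P0, rowwise
    tt <- pmin(pmax(rowSums(w * Dir) / len2, 0), 1)
    rowSums((w - tt * Dir)^2)
  }
  d2_e <- pmin(seg2(tri$A, tri$E0, tri$a),
               seg2(tri$A, tri$E1, tri$c),
               seg2(tri$B, tri$E2, tri$e2len))
  ifelse(inside, pmin(d2_in, d2_e), d2_e)
}

precompute_tris <- function(mesh) {
  A <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  B <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  C <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  E0 <- B - A; E1 <- C - A; E2 <- C - B
  a <- rowSums(E0 * E0); b <- rowSums(E0 * E1); c <- rowSums(E1 * E1)
  list(A = A, B = B, C = C, E0 = E0, E1 = E1, E2 = E2,
       a = a, b = b, c = c, e2len = rowSums(E2 * E2), det = a * c - b * b)
}

# Closest-point distance from each row of `points` to mesh `m` (mm).
closest_mesh_distance <- function(points, mesh) {
  tri <- precompute_tris(mesh)
  apply(points, 1, function(p) sqrt(max(0, min(point_tri_dist2(p, tri)))))
}

triangle_areas <- function(mesh) {
  tri <- precompute_tris(mesh)
  cr <- cbind(tri$E0[, 2] * tri$E1[, 3] - tri$E0[, 3] * tri$E1[, 2],
              tri$E0[, 3] * tri$E1[, 1] - tri$E0[, 1] * tri$E1[, 3],
              tri$E0[, 1] * tri$E1[, 2] - tri$E0[, 2] * tri$E1[, 1])
  sqrt(rowSums(cr^2)) / 2
}

# Area-uniform random samples on a mesh surface; mesh vertices are also
# included (deterministically thinned to n on dense meshes) so polyhedral
# extrema are hit exactly.
sample_mesh_points <- function(mesh, n) {
  verts <- mesh$vertices
  if (n > 0 && nrow(verts) > n)
    verts <- verts[unique(round(seq(1, nrow(verts), length.out = n))), ,
                   drop = FALSE]
  ar <- triangle_areas(mesh)
  if (n > 0 && sum(ar) > 0) {
    pick <- sample.int(nrow(mesh$faces), n, replace = TRUE, prob = ar)
    u <- stats::runif(n); v <- stats::runif(n)
    flip <- u + v > 1
    u[flip] <- 1 - u[flip]; v[flip] <- 1 - v[flip]
    A <- mesh$vertices[mesh$faces[pick, 1], , drop = FALSE]
    B <- mesh$vertices[mesh$faces[pick, 2], , drop = FALSE]
    C <- mesh$vertices[mesh$faces[pick, 3], , drop = FALSE]
    rbind(verts, A + u * (B - A) + v * (C - A))
  } else verts
}

#' Sampled symmetric surface distance between two meshes
#'
#' Points are sampled uniformly by area on each mesh (plus all vertices);
#' each sample's exact closest-point distance to the other mesh is
#' computed point-to-triangle. `hd_max` is the symmetric Hausdorff
#' estimate (max of the two one-sided maxima); `hd_mean` the mean of all
#' sampled closest distances, both directions pooled.
#'
#' @param a,b nonempty `surface_mesh` objects.
#' @param samples_per_mm2 sampling density (default 10/mm^2).
#' @param max_samples cap on random samples per mesh.
#' @param seed RNG seed for reproducible sampling.
#' @return list with `hd_max`, `hd_mean`, `n_samples` and per-direction
#'   maxima/means (`forward` = a to b).
#' @export
surface_distance <- function(a, b, samples_per_mm2 = 10, max_samples = 4000,
                             seed = 0) {
  for (m in list(a, b))
    if (nrow(m$faces) == 0 || all(triangle_areas(m) < 1e-12))
      stop("degenerate mesh", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  n_a <- min(max_samples, ceiling(samples_per_mm2 * sum(triangle_areas(a))))
  n_b <- min(max_samples, ceiling(samples_per_mm2 * sum(triangle_areas(b))))
  pa <- sample_mesh_points(a, n_a)
  pb <- sample_mesh_points(b, n_b)
  dab <- closest_mesh_distance(pa, b)
  dba <- closest_mesh_distance(pb, a)
  list(hd_max = max(max(dab), max(dba)),
       hd_mean = mean(c(dab, dba)),
       n_samples = nrow(pa) + nrow(pb),
       forward = list(max = max(dab), mean = mean(dab)),
       backward = list(max = max(dba), mean = mean(dba)))
}

#' Fit the axis of an approximately cylindrical structure
#'
#' Principal-component fit: the axis is the dominant principal direction
#' of the structure's point set through its centroid. The direction sign
#' is normalized to a positive Z component (positive X on a tie). Used to
#' check iliac-screw axis collinearity after registration.
#'
#' @param x a `ct_mask`, `surface_mesh`, or n x 3 point matrix.
#' @param min_anisotropy minimum ratio of first to second singular value;
#'   below it the axis is ambiguous and an error is raised.
#' @return list with `point` (centroid), `direction` (unit), `radius`
#'   (estimate, mm), `anisotropy`.
#' @export
fit_screw_axis <- function(x, min_anisotropy = 2) {
  pts <- if (inherits(x, "ct_mask")) {
    voxel_to_world(x, arrayInd(which(x$voxels), dim(x$voxels)) - 1)
  } else if (inherits(x, "surface_mesh")) x$vertices else rbind_points(x)
  if (nrow(pts) < 3) stop("too few points for an axis fit", call. = FALSE)
  pc <- stats::prcomp(pts, center = TRUE)
  sv <- pc$sdev
  aniso <- sv[1] / max(sv[2], .Machine$double.eps)
  if (aniso < min_anisotropy)
    stop(sprintf(
      "ambiguous axis: anisotropy ratio %.2f < %.2f (isotropic point cloud)",
      aniso, min_anisotropy), call. = FALSE)
  dir <- pc$rotation[, 1]
  if (dir[3] < 0 || (abs(dir[3]) < 1e-12 && dir[1] < 0)) dir <- -dir
  r <- 2 * sqrt(mean(sv[2:3]^2))
  list(point = colMeans(pts), direction = dir / sqrt(sum(dir^2)),
       radius = r, anisotropy = aniso)
}

#' Angle in degrees between two axis directions (sign-insensitive)
#' @param u,v numeric length-3 directions.
#' @return angle in degrees in `[0, 90]`.
#' @export
axis_angle_deg <- function(u, v) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  acos(pmin(1, abs(sum(u * v)))) * 180 / pi
}

#' Write a mesh as ASCII STL
#' @param mesh a `surface_mesh`.
#' @param path output .stl path.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cat(sprintf("solid %s\n", mesh$label), file = con)
  A <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  B <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  C <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  e0 <- B - A; e1 <- C - A
  n <- cbind(e0[, 2] * e1[, 3] - e0[, 3] * e1[, 2],
             e0[, 3] * e1[, 1] - e0[, 1] * e1[, 3],
             e0[, 1] * e1[, 2] - e0[, 2] * e1[, 1])
  len <- sqrt(rowSums(n^2)); len[len == 0] <- 1
  n <- n / len
  txt <- sprintf(paste0(
    " facet normal %.9g %.9g %.9g\n  outer loop\n",
    "   vertex %.9g %.9g %.9g\n   vertex %.9g %.9g %.9g\n",
    "   vertex %.9g %.9g %.9g\n  endloop\n endfacet"),
    n[, 1], n[, 2], n[, 3], A[, 1], A[, 2], A[, 3],
    B[, 1], B[, 2], B[, 3], C[, 1], C[, 2], C[, 3])
  writeLines(txt, con)
  cat(sprintf("endsolid %s\n", mesh$label), file = con)
  invisible(path)
}

#' Read an ASCII STL mesh
#' @param path .stl path written by [write_stl()] or any ASCII STL.
#' @return a `surface_mesh` (vertices deduplicated).
#' @export
read_stl <- function(path) {
  lines <- readLines(path)
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  nums <- t(vapply(strsplit(trimws(vl), "\\s+"),
                   function(x) as.numeric(x[2:4]), numeric(3)))
  key <- apply(round(nums, 9), 1, paste, collapse = ",")
  uk <- unique(key)
  vid <- match(key, uk)
  verts <- nums[match(uk, key), , drop = FALSE]
  faces <- matrix(vid, ncol = 3, byrow = TRUE)
  label <- sub("^solid\\s*", "", lines[1])
  surface_mesh(verts, faces, label = if (nzchar(label)) label else "stl")
}
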