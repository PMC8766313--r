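#' Surface mesh constructor
#'
#' @param vertices n x 3 matrix of world-mm points.
#' @param faces m x 3 integer matrix of 1-based vertex indices, oriented
#'   counter-clockwise seen from outside.
#' @param label structure name.
#' @return object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, label = "mesh") {
  vertices <- rbind_points(vertices)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (nrow(faces) > 0 && (min(faces) < 1 || max(faces) > nrow(vertices)))
    stop("faces reference invalid vertices", call. = FALSE)
  structure(list(vertices = vertices, faces = faces,
                 label = as.character(label)),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh '%s'> %d vertices, %d faces\n",
              x$label, nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

# cyclic in-plane axes for face direction along axis a: cross(u, v) = a
.cuberille_uv <- list(c(2L, 3L), c(3L, 1L), c(1L, 2L))

#' Triangulated surface of a binary mask
#'
#' Extracts the 0.5 iso-surface of the mask under nearest-neighbour
#' interpolation: the cuberille surface made of the voxel faces separating
#' foreground from background, triangulated with consistent outward
#' orientation and converted to world mm. The result is closed and
#' watertight; its signed volume equals voxel count x voxel volume.
#'
#' @param mask nonempty `ct_mask`.
#' @param iso iso-level, fixed at 0.5 (argument kept for interface parity).
#' @return a `surface_mesh`.
#' @export
mesh_from_mask <- function(mask, iso = 0.5) {
  fg <- mask$voxels
  if (!any(fg)) stop("cannot mesh an empty mask", call. = FALSE)
  dims <- dim(fg)
  quads <- list()  # each row: center index (0-based) + axis + sign
  for (a in 1:3) for (s in c(1L, -1L)) {
    shifted <- array(FALSE, dims)
    n <- dims[a]
    src <- if (s == 1L) 2:n else 1:(n - 1)
    dst <- if (s == 1L) 1:(n - 1) else 2:n
    ix <- list(quote(expr = ), quote(expr = ), quote(expr = ))
    ix_dst <- ix; ix_src <- ix
    ix_dst[[a]] <- dst; ix_src[[a]] <- src
    shifted <- do.call(`[<-`, c(list(shifted), ix_dst,
                                list(do.call(`[`, c(list(fg), ix_src)))))
    boundary <- fg & !shifted
    # voxels at the grid edge in direction s*a are always boundary
    edge <- array(FALSE, dims)
    ix_edge <- ix; ix_edge[[a]] <- if (s == 1L) n else 1L
    edge <- do.call(`[<-`, c(list(edge), ix_edge, list(TRUE)))
    boundary <- fg & (!shifted | edge)
    idx <- which(boundary)
    if (length(idx) == 0) next
    co <- arrayInd(idx, dims) - 1L  # 0-based centers
    quads[[length(quads) + 1]] <- cbind(co, a, s)
  }
  quads <- do.call(rbind, quads)

  # corner coordinates in doubled 0-based index space (always odd offsets)
  uvs <- matrix(c(-1, -1, 1, -1, 1, 1, -1, 1), ncol = 2, byrow = TRUE)
  nq <- nrow(quads)
  corner <- matrix(0L, nq * 4L, 3L)
  for (ci in 1:4) {
    rowsel <- seq_len(nq) + (ci - 1L) * nq
    cc <- 2L * quads[, 1:3]
    a <- quads[, 4]; s <- quads[, 5]
    for (ax in 1:3) {
      uv <- .cuberille_uv[[ax]]
      sel <- a == ax
      cc[sel, ax] <- cc[sel, ax] + s[sel]
      # reverse winding for negative faces so normals point outward
      ci_eff <- ifelse(s[sel] == 1L, ci, 5L - ci)
      cc[sel, uv[1]] <- cc[sel, uv[1]] + uvs[ci_eff, 1]
      cc[sel, uv[2]] <- cc[sel, uv[2]] + uvs[ci_eff, 2]
    }
    corner[rowsel, ] <- cc
  }
  key <- corner[, 1] + 1e4 * (corner[, 2] + 1e4 * corner[, 3])
  uk <- unique(key)
  vid <- match(key, uk)
  first <- match(uk, key)
  verts_idx <- corner[first, , drop = FALSE] / 2  # back to index space
  vertices <- voxel_to_world(mask, verts_idx)
  q <- matrix(vid, nq, 4)
  faces <- rbind(q[, c(1, 2, 3), drop = FALSE], q[, c(1, 3, 4), drop = FALSE])
  surface_mesh(vertices, faces, label = mask$label)
}

#' Signed enclosed volume of a closed mesh (mm^3)
#' @param mesh a `surface_mesh`.
#' @return signed volume; positive for outward-oriented closed surfaces.
#' @export
mesh_volume <- function(mesh) {
  v <- sweep(mesh$vertices, 2, colMeans(mesh$vertices), `-`)
  a <- v[mesh$faces[, 1], , drop = FALSE]
  b <- v[mesh$faces[, 2], , drop = FALSE]
  c_ <- v[mesh$faces[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
      a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

#' Euler characteristic V - E + F of a mesh
#' @param mesh a `surface_mesh`.
#' @return integer Euler characteristic (2 for a topological sphere).
#' @export
mesh_euler <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  ne <- nrow(unique(e))
  nrow(mesh$vertices) - ne + nrow(f)
}

#' Axis-aligned cuboid region (world mm)
#' @param min_corner,max_corner numeric length-3; `min < max` per axis.
#' @return object of class `cuboid_region`.
#' @export
cuboid_region <- function(min_corner, max_corner) {
  min_corner <- as.numeric(min_corner); max_corner <- as.numeric(max_corner)
  if (any(min_corner >= max_corner))
    stop("cuboid min corner must be < max corner on every axis",
         call. = FALSE)
  structure(list(min = min_corner, max = max_corner),
            class = "cuboid_region")
}

#' Clip a mesh with an axis-aligned cuboid
#'
#' Removes triangles on the discarded side. A triangle is kept only when
#' all three vertices lie on the kept side, so the cut is left open
#' (uncapped) and no kept vertex crosses the cuboid boundary.
#'
#' @param mesh a `surface_mesh`.
#' @param region a `cuboid_region`.
#' @param keep `"inside"` or `"outside"`.
#' @return the clipped `surface_mesh`; error if nothing remains.
#' @export
clip_cuboid <- function(mesh, region, keep = c("outside", "inside")) {
  keep <- match.arg(keep)
  v <- mesh$vertices
  inside <- v[, 1] >= region$min[1] & v[, 1] <= region$max[1] &
    v[, 2] >= region$min[2] & v[, 2] <= region$max[2] &
    v[, 3] >= region$min[3] & v[, 3] <= region$max[3]
  vkeep <- if (keep == "inside") inside else !inside
  fkeep <- vkeep[mesh$faces[, 1]] & vkeep[mesh$faces[, 2]] &
    vkeep[mesh$faces[, 3]]
  if (!any(fkeep)) stop("clip removed the entire mesh", call. = FALSE)
  f <- mesh$faces[fkeep, , drop = FALSE]
  used <- sort(unique(as.vector(f)))
  remap <- integer(nrow(v)); remap[used] <- seq_along(used)
  surface_mesh(v[used, , drop = FALSE],
               matrix(remap[f], ncol = 3), label = mesh$label)
}
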