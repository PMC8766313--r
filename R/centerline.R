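#' Extract the centerline of a tubular implant mask
#'
#' Geodesic level-set-centroid method for tubular structures: the mask's
#' foreground voxels form a 26-connected graph weighted by physical
#' distance; a double sweep finds the two geodesically farthest endpoints
#' (the rod ends); voxels whose two-endpoint geodesic eccentricity
#' exceeds the tube's own width are pruned (this removes screw stubs and
#' other side branches); the remaining voxels are binned by geodesic
#' distance from one end and each bin's centroid forms the ordered
#' polyline, smoothed with a moving average.
#'
#' @param implant_mask connected, tubular `ct_mask`.
#' @param prune_mm side branches deeper than this stay pruned regardless of
#'   tube width (informational; the eccentricity filter removes any branch
#'   deeper than `slack_mm`).
#' @param slack_mm eccentricity slack; default 3x the estimated tube
#'   radius. Branch voxels deeper than `slack_mm`/2 beyond the main tube
#'   are discarded.
#' @param smooth_window moving-average window (points), default 5.
#' @return object of class `centerline`: `points` (n x 3 world mm),
#'   `arc_length` (per-point, mm), `total_length` (mm).
#' @export
extract_centerline <- function(implant_mask, prune_mm = 15,
                               slack_mm = NULL, smooth_window = 5) {
  fg <- implant_mask$voxels
  if (!any(fg)) stop("empty implant mask", call. = FALSE)
  dims <- dim(fg)
  idx <- which(fg)
  lab <- label_components(fg, 26)
  if (max(lab) > 1)
    stop("implant mask is disconnected (", max(lab), " components)",
         call. = FALSE)
  coord <- arrayInd(idx, dims) - 1
  world <- voxel_to_world(implant_mask, coord)
  rank <- integer(prod(dims)); rank[idx] <- seq_along(idx)
  ed <- voxel_edges(fg, dims, 26)
  w <- sqrt(rowSums((world[rank[ed[, 1]], , drop = FALSE] -
                     world[rank[ed[, 2]], , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(cbind(rank[ed[, 1]], rank[ed[, 2]]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  igraph::E(g)$weight <- w

  far <- function(v) {
    d <- as.numeric(igraph::distances(g, v = v))
    list(v = which.max(d), d = d)
  }
  a <- far(1)$v
  fa <- far(a); b <- fa$v
  dA <- fa$d
  dB <- far(b)$d
  L <- dA[b]
  if (!is.finite(L) || L < 10 * max(implant_mask$spacing))
    stop("no centerline path of at least 10 voxels found", call. = FALSE)

  # tube radius estimate from volume/length; used to size the
  # eccentricity slack that prunes screw stubs
  voxvol <- prod(implant_mask$spacing)
  r_est <- sqrt(length(idx) * voxvol / (pi * L))
  if (is.null(slack_mm)) slack_mm <- 3 * r_est
  keep <- (dA + dB) <= (L + slack_mm)

  bw <- max(implant_mask$spacing)
  dAk <- dA[keep]
  bins <- floor(dAk / bw)
  pts <- world[keep, , drop = FALSE]
  cx <- tapply(pts[, 1], bins, mean)
  cy <- tapply(pts[, 2], bins, mean)
  cz <- tapply(pts[, 3], bins, mean)
  counts <- tapply(pts[, 1], bins, length)
  ord <- order(as.numeric(names(cx)))
  poly <- cbind(cx[ord], cy[ord], cz[ord])
  rownames(poly) <- NULL
  bin_d <- as.numeric(names(cx))[ord] * bw

  # tube radius from the median per-bin cross-section voxel count
  # (robust to junction bins); used to trim and rebuild the cap ends
  r_bin <- sqrt(stats::median(counts[ord]) * voxvol / (pi * bw))
  r_est <- r_bin

  # the geodesic sweep starts at a cap-surface voxel, so bins within
  # ~1.5 radii of either end follow the spherical cap, not the axis:
  # trim them and restore each end on the local tangent, one radius
  # short of the farthest voxel
  trim <- bin_d > 2.5 * r_bin & bin_d < L - 2.5 * r_bin
  if (sum(trim) >= 4) {
    poly <- poly[trim, , drop = FALSE]
    # end tangent from a PCA line fit through the nearest bin centroids
    cap_tip <- function(end_centroids, region_pts) {
      c0 <- colMeans(end_centroids)
      u <- stats::prcomp(end_centroids, center = TRUE)$rotation[, 1]
      out <- end_centroids[1, ] - end_centroids[nrow(end_centroids), ]
      if (sum(u * out) < 0) u <- -u
      x <- as.numeric(sweep(region_pts, 2, c0) %*% u)
      # the outermost surface voxel is eroded by about half a voxel on
      # average under a mid-band threshold; compensate
      c0 + u * (max(x) - r_bin + 0.5 * bw)
    }
    kf <- min(10L, nrow(poly))
    tip1 <- cap_tip(poly[seq_len(kf), , drop = FALSE],
                    pts[dAk <= 4 * r_bin, , drop = FALSE])
    n <- nrow(poly)
    tip2 <- cap_tip(poly[seq(n, n - kf + 1L), , drop = FALSE],
                    pts[dAk >= L - 4 * r_bin, , drop = FALSE])
    poly <- rbind(tip1, poly, tip2)
    rownames(poly) <- NULL
  }
  if (smooth_window > 1 && nrow(poly) >= smooth_window + 2) {
    k <- smooth_window
    sm <- apply(poly[-c(1, nrow(poly)), , drop = FALSE], 2, function(col)
      stats::filter(col, rep(1 / k, k), sides = 2))
    inner <- which(!is.na(sm[, 1])) + 1L
    poly[inner, ] <- sm[inner - 1L, ]
  }
  # subdivide long segments (the rebuilt cap ends) so consecutive
  # point spacing stays below two voxels
  seg <- sqrt(rowSums(diff(poly)^2))
  if (any(seg > 1.5 * bw)) {
    pieces <- lapply(seq_len(nrow(poly) - 1), function(i) {
      k <- ceiling(seg[i] / bw)
      tt <- seq(0, 1, length.out = k + 1)[-(k + 1)]
      outer(1 - tt, poly[i, ]) + outer(tt, poly[i + 1, ])
    })
    poly <- rbind(do.call(rbind, pieces), poly[nrow(poly), ])
  }
  seg <- sqrt(rowSums(diff(poly)^2))
  structure(list(points = poly,
                 arc_length = c(0, cumsum(seg)),
                 total_length = sum(seg),
                 radius_estimate = r_est),
            class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("<centerline> %d points, arc length %.2f mm\n",
              nrow(x$points), x$total_length))
  invisible(x)
}

#' Snap a point to the nearest centerline point
#' @param centerline a `centerline`.
#' @param point world-mm point.
#' @return the nearest polyline point (length-3 numeric).
#' @export
snap_to_centerline <- function(centerline, point) {
  d2 <- rowSums(sweep(centerline$points, 2, as.numeric(point))^2)
  centerline$points[which.min(d2), ]
}

#' Export a centerline as an ASCII PLY polyline
#' @param centerline a `centerline`.
#' @param path output .ply path.
#' @return `path`, invisibly.
#' @export
write_centerline_ply <- function(centerline, path) {
  p <- centerline$points
  n <- nrow(p)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", n),
               "property float x", "property float y", "property float z",
               sprintf("element edge %d", n - 1),
               "property int vertex1", "property int vertex2",
               "end_header",
               sprintf("%.6f %.6f %.6f", p[, 1], p[, 2], p[, 3]),
               sprintf("%d %d", 0:(n - 2), 1:(n - 1))), con)
  invisible(path)
}
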