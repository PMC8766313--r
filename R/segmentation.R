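#' Threshold-based segmentation
#'
#' Selects all voxels with `lo <= HU <= hi`. Default bands for the phantom
#' place metal at >= 3000 HU and bone at 226-3000 HU; real-data thresholds
#' are configuration values.
#'
#' @param vol a `ct_volume`.
#' @param lo,hi HU band (inclusive); `lo < hi` required.
#' @param label mask label.
#' @return a `ct_mask`; an empty result warns but is returned.
#' @export
threshold_segment <- function(vol, lo, hi = Inf, label = "threshold") {
  if (!(lo < hi)) stop("lo must be < hi", call. = FALSE)
  m <- vol$voxels >= lo & vol$voxels <= hi
  if (!any(m)) warning("threshold produced an empty mask", call. = FALSE)
  ct_mask(m, vol, label = label)
}

# Edge list of the foreground voxel adjacency graph, as 1-based linear
# index pairs. connectivity 6 uses face neighbours; 26 adds edge and
# corner neighbours. Only "positive" offsets are enumerated (undirected).
voxel_edges <- function(fg, dims, connectivity) {
  offs <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  if (connectivity == 26) {
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      v <- c(dx, dy, dz)
      if (sum(abs(v)) > 1 && (dz > 0 || (dz == 0 && (dy > 0 ||
          (dy == 0 && dx > 0)))))
        offs[[length(offs) + 1]] <- v
    }
  }
  idx <- which(fg)
  coord <- arrayInd(idx, dims)
  inside <- logical(prod(dims))
  inside[idx] <- TRUE
  from <- integer(0); to <- integer(0)
  for (o in offs) {
    nb <- coord[, 1] + o[1] >= 1 & coord[, 1] + o[1] <= dims[1] &
      coord[, 2] + o[2] >= 1 & coord[, 2] + o[2] <= dims[2] &
      coord[, 3] + o[3] >= 1 & coord[, 3] + o[3] <= dims[3]
    src <- idx[nb]
    dst <- src + o[1] + dims[1] * o[2] + dims[1] * dims[2] * o[3]
    keep <- inside[dst]
    from <- c(from, src[keep]); to <- c(to, dst[keep])
  }
  cbind(from, to)
}

# Connected-component labels (0 = background) of a logical array.
label_components <- function(fg, connectivity = 26) {
  dims <- dim(fg)
  idx <- which(fg)
  lab <- integer(prod(dims))
  if (length(idx) == 0) return(array(lab, dims))
  ed <- voxel_edges(fg, dims, connectivity)
  rank <- integer(prod(dims))
  rank[idx] <- seq_along(idx)
  g <- igraph::graph_from_edgelist(cbind(rank[ed[, 1]], rank[ed[, 2]]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  lab[idx] <- comp
  array(lab, dims)
}

#' Largest connected components of a mask
#'
#' Returns the `k` largest connected components by voxel count, in
#' descending size; ties are broken by the smallest minimum linear index.
#' If fewer than `k` components exist, all are returned and the result
#' carries a `shortfall` attribute.
#'
#' @param mask a `ct_mask`.
#' @param k number of components requested (>= 1).
#' @param connectivity 6 (faces) or 26 (faces+edges+corners, default).
#' @return list of `ct_mask`, with attribute `shortfall` (logical).
#' @export
largest_components <- function(mask, k = 1, connectivity = c(26, 6)) {
  connectivity <- match.arg(as.character(connectivity[1]), c("26", "6"))
  stopifnot(k >= 1)
  lab <- label_components(mask$voxels, as.integer(connectivity))
  ncomp <- max(lab)
  if (ncomp == 0) stop("mask is empty", call. = FALSE)
  sizes <- tabulate(lab[lab > 0], nbins = ncomp)
  first_idx <- vapply(seq_len(ncomp), function(i) min(which(lab == i)), 0L)
  ord <- order(-sizes, first_idx)
  take <- head(ord, k)
  out <- lapply(seq_along(take), function(i)
    ct_mask(lab == take[i], mask,
            label = sprintf("%s_cc%d", mask$label, i)))
  attr(out, "shortfall") <- ncomp < k
  if (ncomp < k)
    warning(sprintf("only %d component(s) found, %d requested", ncomp, k),
            call. = FALSE)
  out
}

# 4-connected flood fill of a 2D logical background from the border;
# returns the set of reachable background pixels.
border_background <- function(slice) {
  bg <- !slice
  reach <- matrix(FALSE, nrow(slice), ncol(slice))
  reach[1, ] <- bg[1, ]; reach[nrow(bg), ] <- bg[nrow(bg), ]
  reach[, 1] <- bg[, 1]; reach[, ncol(bg)] <- bg[, ncol(bg)]
  repeat {
    grown <- reach
    grown[-1, ] <- grown[-1, ] | reach[-nrow(reach), ]
    grown[-nrow(reach), ] <- grown[-nrow(reach), ] | reach[-1, ]
    grown[, -1] <- grown[, -1] | reach[, -ncol(reach)]
    grown[, -ncol(reach)] <- grown[, -ncol(reach)] | reach[, -1]
    grown <- grown & bg
    if (identical(grown, reach)) break
    reach <- grown
  }
  reach
}

#' Fill enclosed 2D regions slice by slice
#'
#' Per axial slice, every background region not 4-connected to the slice
#' border is set to foreground, preserving the outer contour. Idempotent;
#' never removes a foreground voxel. Background connectivity is
#' 4-connected so fills cannot leak through diagonal gaps.
#'
#' @param mask a `ct_mask`.
#' @param plane currently only `"axial"` (third array axis).
#' @return the filled `ct_mask`.
#' @export
fill_2d <- function(mask, plane = "axial") {
  stopifnot(identical(plane, "axial"))
  v <- mask$voxels
  for (k in seq_len(dim(v)[3])) {
    slice <- v[, , k]
    if (!any(slice)) next
    v[, , k] <- !border_background(slice)
  }
  ct_mask(v, mask, label = mask$label)
}

#' Dice similarity between two masks
#'
#' DSI = 2|A n B| / (|A| + |B|); 1 denotes a perfect match, 0 disjoint
#' masks. Both masks must share the same grid geometry.
#'
#' @param a,b `ct_mask` objects on identical geometry.
#' @return list with `dsi`, `n_A`, `n_B`, `n_intersection`.
#' @export
dice <- function(a, b) {
  if (!same_geometry(a, b))
    stop("geometry mismatch between masks", call. = FALSE)
  nA <- sum(a$voxels); nB <- sum(b$voxels)
  if (nA + nB == 0) stop("DSI undefined: both masks empty", call. = FALSE)
  nI <- sum(a$voxels & b$voxels)
  list(dsi = 2 * nI / (nA + nB), n_A = nA, n_B = nB, n_intersection = nI)
}
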