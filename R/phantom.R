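# Synthetic CT phantom: a U-shaped tubular rod with screws embedded in two
# bone blocks, a progressively densifying fusion region, programmable rigid
# motion and rod bending per timepoint, and a 5-insertion density
# calibration phantom. Every quantity the downstream pipeline estimates is
# recorded as ground truth at generation time.

#' Phantom specification
#'
#' Defaults describe a 96 x 96 x 80 grid at 1 mm isotropic spacing holding
#' a U-rod (radius 4 mm, 8000 HU) whose two vertical legs are bridged by a
#' semicircular bottom arc, four screws (two pedicle-like stubs on one leg
#' marking the ROI levels, two iliac-like screws through the bottom arc
#' into the bone blocks), two cortical-shelled bone blocks (1200 HU shell,
#' 300 HU interior), a soft-tissue body block (40 HU) in air (-1000 HU),
#' and an ellipsoidal fusion region between the ROI screw levels whose HU
#' ramps linearly from 100 to 1200 across timepoints. The density
#' calibration phantom carries five cylindrical insertions at 0, 0.05,
#' 0.10, 0.15 and 0.20 g/cm^3 synthesized from the line BMD = a + b * HU
#' with a = 0, b = 0.001.
#'
#' @param shape grid dimensions (voxels).
#' @param spacing voxel spacing, mm.
#' @param rod_radius rod radius, mm (must cover >= 1 voxel).
#' @param rod_hu,screw_hu,shell_hu,trabecular_hu,soft_hu,air_hu HU values.
#' @param fusion_hu_range HU of the fusion interior at the first and last
#'   timepoint (linear ramp between).
#' @param calibration list with `a`, `b` (b != 0) and `densities`.
#' @param noise_sd additive Gaussian HU noise SD (default 10).
#' @param seed RNG seed; fixed seed reproduces volumes bit-exact.
#' @param supersample per-axis supersampling factor (>= 3) for
#'   partial-volume rendering at surfaces.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(96, 96, 80), spacing = c(1, 1, 1),
                         rod_radius = 4,
                         rod_hu = 8000, screw_hu = 8000, shell_hu = 1200,
                         trabecular_hu = 300, soft_hu = 40, air_hu = -1000,
                         fusion_hu_range = c(100, 1200),
                         calibration = list(a = 0, b = 0.001,
                                            densities = c(0, 0.05, 0.10,
                                                          0.15, 0.20)),
                         noise_sd = 10, seed = 1, supersample = 3) {
  if (rod_radius < min(spacing))
    stop("resolution error: rod radius smaller than one voxel",
         call. = FALSE)
  if (!is.null(calibration$b) && calibration$b == 0)
    stop("degenerate calibration: b must be non-zero", call. = FALSE)
  if (supersample < 3) stop("supersample factor must be >= 3", call. = FALSE)
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 rod_radius = rod_radius, rod_hu = rod_hu,
                 screw_hu = screw_hu, shell_hu = shell_hu,
                 trabecular_hu = trabecular_hu, soft_hu = soft_hu,
                 air_hu = air_hu, fusion_hu_range = fusion_hu_range,
                 calibration = calibration, noise_sd = noise_sd,
                 seed = as.integer(seed),
                 supersample = as.integer(supersample)),
            class = "phantom_spec")
}

# canonical rod centerline: leg B top -> down -> bottom arc -> leg A top
# (the mobile end). Points roughly 2 mm apart.
phantom_rod_polyline <- function(bend = c(0, 0, 0)) {
  legB <- cbind(68, 48, seq(64, 24, by = -2))
  th <- seq(pi, 0, length.out = 32)          # arc from x=68 to x=28
  arc <- cbind(48 - 20 * cos(th), 48, 24 - 20 * sin(th))
  legA <- cbind(28, 48, seq(26, 64, by = 2))
  pts <- rbind(legB, arc[-1, ], legA)
  seg <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seg))
  S <- max(s)
  s0 <- S - 40                               # bending affects the free leg
  w <- ifelse(s > s0, ((s - s0) / (S - s0))^2, 0)
  pts + outer(w, as.numeric(bend))
}

phantom_fixtures <- function() {
  list(
    screws = list(
      list(p1 = c(68, 48, 40), p2 = c(68, 36, 40), r = 2.5,
           name = "screw_L4"),
      list(p1 = c(68, 48, 28), p2 = c(68, 36, 28), r = 2.5,
           name = "screw_L5"),
      list(p1 = c(44, 48, 10), p2 = c(16, 48, 10), r = 2.5,
           name = "screw_iliac_left"),
      list(p1 = c(52, 48, 10), p2 = c(80, 48, 10), r = 2.5,
           name = "screw_iliac_right")),
    blocks = list(list(min = c(8, 36, 2), max = c(36, 60, 20)),
                  list(min = c(60, 36, 2), max = c(88, 60, 20))),
    soft = list(min = c(4, 30, 0), max = c(92, 66, 76)),
    fusion = list(center = c(48, 48, 34), axes = c(24, 9, 11),
                  shell = 2),
    mobile = c(28, 48, 64),
    fixed = c(16, 48, 10),                   # left iliac screw tip
    roi_tips = list(c(68, 36, 40), c(68, 36, 28)),
    landmarks = landmark_set(
      rbind(c(8, 36, 2), c(36, 60, 2), c(8, 60, 20), c(36, 36, 20),
            c(60, 36, 2), c(88, 60, 2), c(60, 60, 20), c(88, 36, 20)),
      c("blkA_1", "blkA_2", "blkA_3", "blkA_4",
        "blkB_1", "blkB_2", "blkB_3", "blkB_4")))
}

# --- primitive coverage -----------------------------------------------

dist_to_polyline <- function(P, poly) {
  d2 <- rep(Inf, nrow(P))
  for (i in seq_len(nrow(poly) - 1)) {
    a <- poly[i, ]; bvec <- poly[i + 1, ] - a
    len2 <- sum(bvec^2)
    W <- sweep(P, 2, a)
    tt <- pmin(pmax((W %*% bvec) / len2, 0), 1)
    d2 <- pmin(d2, rowSums((W - tt %*% t(bvec))^2))
  }
  sqrt(d2)
}

sd_box <- function(P, bmin, bmax) {
  ctr <- (bmin + bmax) / 2; half <- (bmax - bmin) / 2
  q <- abs(sweep(P, 2, ctr)) - rep(half, each = nrow(P))
  qc <- pmax(q, 0)
  sqrt(rowSums(qc^2)) + pmin(pmax(q[, 1], q[, 2], q[, 3]), 0)
}

sd_ellipsoid <- function(P, center, axes) {
  W <- sweep(P, 2, center)
  k <- sqrt(rowSums(sweep(W, 2, axes, `/`)^2))
  (k - 1) * min(axes)
}

# Paint one primitive into `vox`. `Y` are voxel centers mapped into the
# canonical frame; `offs` the (already rotated) supersampling offsets.
# `sdf(P)` returns a signed distance (< 0 inside).
paint <- function(vox, Y, sdf, hu, offs, h) {
  d <- sdf(Y)
  full <- d <= -h
  shell <- !full & d < h
  vox[full] <- hu
  si <- which(shell)
  if (length(si)) {
    frac <- numeric(length(si))
    for (o in seq_len(ncol(offs))) {
      Ps <- sweep(Y[si, , drop = FALSE], 2, offs[, o], `+`)
      frac <- frac + (sdf(Ps) <= 0)
    }
    frac <- frac / ncol(offs)
    vox[si] <- (1 - frac) * vox[si] + frac * hu
  }
  vox
}

rasterize_phantom <- function(spec, transform = rigid_transform(),
                              bend = c(0, 0, 0), fusion_hu = 100) {
  fx <- phantom_fixtures()
  dims <- spec$shape
  centers <- (arrayInd(seq_len(prod(dims)), dims) - 1) *
    rep(spec$spacing, each = prod(dims))
  Ti <- invert_transform(transform)
  Y <- sweep(centers %*% t(Ti$rotation), 2, Ti$translation, `+`)
  ss <- spec$supersample
  g <- (seq_len(ss) - (ss + 1) / 2) / ss
  offs <- as.matrix(expand.grid(g * spec$spacing[1], g * spec$spacing[2],
                                g * spec$spacing[3]))
  offs <- t(Ti$rotation %*% t(offs))
  offs <- t(offs)                               # 3 x m
  h <- 0.87 * max(spec$spacing)

  vox <- rep(spec$air_hu, prod(dims))

  paint_bb <- function(vox, sdf, hu, bmin, bmax) {
    # cheap canonical-frame bounding-box prefilter
    pad <- h + max(spec$spacing)
    sel <- which(Y[, 1] >= bmin[1] - pad & Y[, 1] <= bmax[1] + pad &
                 Y[, 2] >= bmin[2] - pad & Y[, 2] <= bmax[2] + pad &
                 Y[, 3] >= bmin[3] - pad & Y[, 3] <= bmax[3] + pad)
    if (!length(sel)) return(vox)
    sub <- paint(vox[sel], Y[sel, , drop = FALSE], sdf, hu, offs, h)
    vox[sel] <- sub
    vox
  }

  sf <- fx$soft
  vox <- paint_bb(vox, function(P) sd_box(P, sf$min, sf$max), spec$soft_hu,
                  sf$min, sf$max)
  for (blk in fx$blocks) {
    vox <- paint_bb(vox, function(P) sd_box(P, blk$min, blk$max),
                    spec$shell_hu, blk$min, blk$max)
    inner_min <- blk$min + 3; inner_max <- blk$max - 3
    vox <- paint_bb(vox, function(P) sd_box(P, inner_min, inner_max),
                    spec$trabecular_hu, inner_min, inner_max)
  }
  fu <- fx$fusion
  vox <- paint_bb(vox, function(P) sd_ellipsoid(P, fu$center, fu$axes),
                  spec$shell_hu, fu$center - fu$axes, fu$center + fu$axes)
  inner_axes <- fu$axes - fu$shell
  vox <- paint_bb(vox, function(P) sd_ellipsoid(P, fu$center, inner_axes),
                  fusion_hu, fu$center - inner_axes, fu$center + inner_axes)

  poly <- phantom_rod_polyline(bend)
  rmin <- apply(poly, 2, min) - spec$rod_radius
  rmax <- apply(poly, 2, max) + spec$rod_radius
  vox <- paint_bb(vox, function(P)
    dist_to_polyline(P, poly) - spec$rod_radius, spec$rod_hu, rmin, rmax)
  for (sc in phantom_screws(bend)) {
    seg <- rbind(sc$p1, sc$p2)
    vox <- paint_bb(vox, function(P) dist_to_polyline(P, seg) - sc$r,
                    spec$screw_hu,
                    pmin(sc$p1, sc$p2) - sc$r, pmax(sc$p1, sc$p2) + sc$r)
  }
  array(vox, dims)
}

# screws follow the bending of their attachment point on the rod; all
# default screws attach where the bending weight is zero.
phantom_screws <- function(bend = c(0, 0, 0)) {
  phantom_fixtures()$screws
}

#' Rasterize a tube (capsule around a polyline) into a fresh grid
#'
#' Stand-alone access to the phantom's partial-volume rasterizer: voxels
#' within `radius` of the polyline get `hu_in`, the rest `hu_out`, with
#' boundary voxels blended by supersampled coverage fractions.
#'
#' @param polyline n x 3 matrix of world-mm points.
#' @param radius tube radius, mm.
#' @param shape,spacing output grid.
#' @param hu_in,hu_out interior/background HU.
#' @param supersample per-axis supersampling factor (>= 1).
#' @return a `ct_volume`.
#' @export
rasterize_tube <- function(polyline, radius, shape = c(64, 32, 32),
                           spacing = c(1, 1, 1), hu_in = 8000,
                           hu_out = -1000, supersample = 3) {
  polyline <- rbind_points(polyline)
  dims <- as.integer(shape)
  centers <- (arrayInd(seq_len(prod(dims)), dims) - 1) *
    rep(spacing, each = prod(dims))
  g <- (seq_len(supersample) - (supersample + 1) / 2) / supersample
  offs <- t(as.matrix(expand.grid(g * spacing[1], g * spacing[2],
                                  g * spacing[3])))
  vox <- rep(hu_out, prod(dims))
  vox <- paint(vox, centers,
               function(P) dist_to_polyline(P, polyline) - radius,
               hu_in, offs, 0.87 * max(spacing))
  ct_volume(array(vox, dims), spacing, scan_id = "tube")
}

#' Canonical follow-up schedule (days after surgery)
#'
#' The default longitudinal sampling used by the phantom: a 6-year
#' follow-up with denser early sampling (7, 34, 83, 138, 250, 446, 656,
#' 1027, 1384, 1734, 1937, 2112 days).
#'
#' @param n number of timepoints (<= 12).
#' @return integer vector of days.
#' @export
default_followup_days <- function(n = 12) {
  days <- c(7L, 34L, 83L, 138L, 250L, 446L, 656L, 1027L, 1384L, 1734L,
            1937L, 2112L)
  if (n > length(days)) stop("at most 12 default timepoints", call. = FALSE)
  days[seq_len(n)]
}

default_motion <- function(t) {
  if (t == 1) return(rigid_transform())
  ang <- 2 * pi / 180 * sin(t - 1)
  Rz <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1),
               3, 3)
  rigid_transform(Rz, c(3 * sin(t - 1), 2 * sin(2 * (t - 1)),
                        1.5 * sin(3 * (t - 1))))
}

#' Generate a synthetic follow-up CT series with ground truth
#'
#' Each timepoint's volume is the phantom rasterized after applying that
#' timepoint's rigid motion and rod bending, with partial volume rendered
#' by supersampling and optional Gaussian HU noise. The ground truth
#' records exactly what was programmed: the rigid transform, the bent rod
#' centerline, the mobile/fixed measurement points, the per-axis
#' deformation components in the reference frame, the anatomical
#' landmarks, and the ROI slice's per-category BMD volumes.
#'
#' @param spec a `phantom_spec`.
#' @param n_timepoints number of follow-up scans (>= 1).
#' @param days days after surgery per scan (default
#'   [default_followup_days()]).
#' @param motions list of `rigid_transform` per timepoint (default: a
#'   bounded deterministic motion pattern, identity at t = 1).
#' @param bending per-timepoint displacement of the mobile rod end, an
#'   n x 3 matrix (default: a linear ramp to `c(1.5, 1.0, -10)` mm at the
#'   last timepoint).
#' @return list with `volumes` (list of `ct_volume`) and `ground_truth`
#'   (per-timepoint list plus shared fields).
#' @export
generate_followup_series <- function(spec, n_timepoints,
                                     days = NULL, motions = NULL,
                                     bending = NULL) {
  stopifnot(n_timepoints >= 1)
  nt <- n_timepoints
  days <- days %||% default_followup_days(nt)
  motions <- motions %||% lapply(seq_len(nt), default_motion)
  if (is.null(bending)) {
    f <- if (nt > 1) (seq_len(nt) - 1) / (nt - 1) else 0
    bending <- outer(f, c(1.5, 1.0, -10))
  }
  bending <- matrix(bending, nrow = nt, ncol = 3)
  fx <- phantom_fixtures()
  fur <- spec$fusion_hu_range
  fusion_hu <- if (nt > 1)
    fur[1] + (fur[2] - fur[1]) * (seq_len(nt) - 1) / (nt - 1)
  else fur[1]

  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  volumes <- vector("list", nt)
  gt <- vector("list", nt)
  for (t in seq_len(nt)) {
    Tt <- motions[[t]]
    vox <- rasterize_phantom(spec, Tt, bending[t, ], fusion_hu[t])
    # ground truth before noise
    mobile_ref <- fx$mobile + bending[t, ]
    fixed_ref <- fx$fixed
    d <- abs(mobile_ref - fixed_ref)
    tips_scan <- lapply(fx$roi_tips, function(p)
      as.numeric(Tt$rotation %*% p + Tt$translation))
    roi_z <- (tips_scan[[1]][3] + tips_scan[[2]][3]) / 2
    vol0 <- ct_volume(vox, spec$spacing, scan_id = sprintf("tp%02d", t),
                      days_after_surgery = days[t])
    sl <- extract_axial_slice(vol0, roi_z)
    hu <- sl$values[sl$values >= 226 & sl$values <= 3000]
    bmd <- pmax(spec$calibration$a + spec$calibration$b * hu, 0)
    counts <- tabulate(bmd_category(bmd), nbins = 10)

    cl <- phantom_rod_polyline(bending[t, ])
    gt[[t]] <- list(
      transform = Tt,
      bend = bending[t, ],
      centerline = sweep(cl %*% t(Tt$rotation), 2, Tt$translation, `+`),
      centerline_ref = cl,
      mobile_ref = mobile_ref, fixed_ref = fixed_ref,
      mobile_scan = as.numeric(Tt$rotation %*% mobile_ref +
                                 Tt$translation),
      fixed_scan = as.numeric(Tt$rotation %*% fixed_ref + Tt$translation),
      Xd = d[1], Yd = d[2], Zd = d[3], D3d = sqrt(sum(d^2)),
      landmarks = apply_transform(Tt, fx$landmarks),
      roi_tips_scan = tips_scan, roi_z = roi_z,
      fusion_hu = fusion_hu[t],
      category_counts = counts,
      category_volumes_cm3 = counts * prod(spec$spacing) / 1000)
    if (spec$noise_sd > 0)
      vox <- vox + array(stats::rnorm(length(vox), 0, spec$noise_sd),
                         dim(vox))
    volumes[[t]] <- ct_volume(vox, spec$spacing,
                              scan_id = sprintf("tp%02d", t),
                              days_after_surgery = days[t])
  }
  list(volumes = volumes,
       ground_truth = list(timepoints = gt, days = days,
                           landmarks_canonical = fx$landmarks,
                           calibration = spec$calibration,
                           rod_radius = spec$rod_radius))
}

#' Generate a density calibration phantom scan
#'
#' A water-equivalent cylinder block holding five cylindrical insertions
#' whose interior mean HU equals `(density - a) / b` (plus noise), so a
#' closed-loop calibration fit recovers the synthesizing line.
#'
#' @param spec a `phantom_spec` (uses its `calibration`, `noise_sd`,
#'   `seed`).
#' @return list with `volume` (a `ct_volume`), `insertions` (data.frame
#'   of center coordinates, radius, density, true HU), and the true
#'   `a`, `b`.
#' @export
generate_calibration_scan <- function(spec) {
  cal <- spec$calibration
  if (cal$b == 0) stop("degenerate calibration: b = 0", call. = FALSE)
  dims <- c(96, 64, 12)
  spacing <- c(1, 1, 3)
  centers_x <- seq(14, 82, length.out = length(cal$densities))
  hu_true <- (cal$densities - cal$a) / cal$b
  centers <- (arrayInd(seq_len(prod(dims)), dims) - 1) *
    rep(spacing, each = prod(dims))
  vox <- rep(-1000, prod(dims))
  body <- sd_box(centers, c(4, 8, 0), c(92, 56, 36))
  vox[body <= 0] <- 0                          # water block
  g <- (seq_len(spec$supersample) - (spec$supersample + 1) / 2) /
    spec$supersample
  offs <- t(as.matrix(expand.grid(g * spacing[1], g * spacing[2],
                                  g * spacing[3])))
  h <- 0.87 * max(spacing)
  for (i in seq_along(cal$densities)) {
    seg <- rbind(c(centers_x[i], 32, 0), c(centers_x[i], 32, 36))
    vox <- paint(vox, centers, function(P)
      dist_to_polyline(P, seg) - 6, hu_true[i], offs, h)
  }
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed + 1L)
  if (spec$noise_sd > 0)
    vox <- vox + stats::rnorm(length(vox), 0, spec$noise_sd)
  list(volume = ct_volume(array(vox, dims), spacing,
                          scan_id = "calibration"),
       insertions = data.frame(x = centers_x, y = 32,
                               radius = 6, density = cal$densities,
                               hu_true = hu_true),
       a = cal$a, b = cal$b)
}

#' Mean HU inside each calibration insertion
#'
#' Averages HU over voxels within `radius - margin` of each insertion
#' axis (the margin excludes partial-volume voxels at the rim).
#'
#' @param vol the calibration `ct_volume`.
#' @param insertions data.frame with `x`, `y`, `radius` columns.
#' @param margin rim exclusion, mm (default 2).
#' @return numeric vector of mean HU, one per insertion.
#' @export
insertion_mean_hu <- function(vol, insertions, margin = 2) {
  dims <- dim(vol$voxels)
  centers <- voxel_to_world(vol, arrayInd(seq_len(prod(dims)), dims) - 1)
  vapply(seq_len(nrow(insertions)), function(i) {
    r2 <- (insertions$radius[i] - margin)^2
    sel <- (centers[, 1] - insertions$x[i])^2 +
      (centers[, 2] - insertions$y[i])^2 <= r2
    mean(vol$voxels[sel])
  }, numeric(1))
}
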