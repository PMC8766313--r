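rand_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

rand_landmarks <- function(n = 8) {
  landmark_set(matrix(runif(n * 3, 0, 80), ncol = 3), letters[1:n])
}

rot_angle_deg <- function(R) {
  acos(pmin(1, pmax(-1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}

test_that("identity and pure-translation fits are exact", {
  set.seed(2)
  lm <- rand_landmarks()
  T0 <- fit_rigid_landmarks(lm, lm)
  expect_lt(max(abs(T0$rotation - diag(3))), 1e-12)
  expect_lt(max(abs(T0$translation)), 1e-12)
  expect_equal(T0$rms_residual, 0, tolerance = 1e-12)

  shifted <- landmark_set(sweep(lm$points, 2, c(1, 2, 3)), lm$names)
  Tt <- fit_rigid_landmarks(shifted, lm)
  expect_lt(max(abs(Tt$rotation - diag(3))), 1e-12)
  expect_equal(Tt$translation, c(1, 2, 3), tolerance = 1e-12)
})

test_that("a 90-degree z rotation is recovered to 1e-9", {
  set.seed(4)
  lm <- rand_landmarks()
  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  fixed <- landmark_set(lm$points %*% t(Rz), lm$names)
  T <- fit_rigid_landmarks(lm, fixed)
  expect_lt(max(abs(T$rotation - Rz)), 1e-9)
  expect_lt(max(abs(T$translation)), 1e-9)
})

test_that("random rigid transforms are recovered from noiseless landmarks", {
  set.seed(6)
  for (i in 1:10) {
    lm <- rand_landmarks()
    R <- rand_rotation(); tr <- runif(3, -20, 20)
    fixed <- landmark_set(sweep(lm$points %*% t(R), 2, tr, `+`), lm$names)
    T <- fit_rigid_landmarks(lm, fixed)
    expect_lt(rot_angle_deg(t(T$rotation) %*% R), 1e-4)
    expect_lt(max(abs(T$translation - tr)), 1e-7)
    expect_lt(T$rms_residual, 1e-9)
  }
})

test_that("rms residual tracks landmark noise magnitude", {
  set.seed(8)
  lm <- rand_landmarks(20)
  R <- rand_rotation(); tr <- runif(3, -10, 10)
  noisy <- sweep(lm$points %*% t(R), 2, tr, `+`) +
    matrix(rnorm(60, 0, 0.5), ncol = 3)
  T <- fit_rigid_landmarks(lm, landmark_set(noisy, lm$names))
  expect_gt(T$rms_residual, 0.2)
  expect_lt(T$rms_residual, 1.2)
})

test_that("degenerate and mismatched landmark inputs error", {
  pts <- cbind(seq(0, 35, 5), seq(0, 70, 10), seq(0, 35, 5))  # collinear
  col <- landmark_set(pts, letters[1:8])
  lm <- landmark_set(matrix(c(0, 0, 0, 10, 0, 0, 0, 10, 0, 0, 0, 10),
                            ncol = 3, byrow = TRUE), letters[1:4])
  expect_error(fit_rigid_landmarks(col, col), "collinear")
  lm2 <- landmark_set(lm$points, c("a", "b", "c", "e"))
  expect_error(fit_rigid_landmarks(lm, lm2), "pairing")
  expect_error(landmark_set(matrix(0, 2, 3), c("a", "b")), "at least 3")
  expect_error(landmark_set(rbind(c(0, 0, 0), c(0.5, 0, 0), c(9, 9, 9)),
                            c("a", "b", "c")), "1 mm")
})

test_that("transforms compose, invert, and round-trip meshes exactly", {
  set.seed(9)
  R <- rand_rotation()
  T <- rigid_transform(R, c(4, -3, 7))
  m <- mesh_from_mask(box_mask(c(6, 6, 6), c(2, 2, 2), c(5, 5, 5)))
  back <- apply_transform(invert_transform(T), apply_transform(T, m))
  expect_lt(max(abs(back$vertices - m$vertices)), 1e-9)
  TI <- compose_transform(invert_transform(T), T)
  expect_lt(max(abs(TI$rotation - diag(3))), 1e-12)
  expect_lt(max(abs(TI$translation)), 1e-12)
  # identity transform leaves input unchanged
  id <- rigid_transform()
  expect_identical(apply_transform(id, m)$vertices, m$vertices)
})

test_that("mask resampling under pure translation shifts the mask", {
  m <- box_mask(c(20, 20, 20), c(5, 5, 5), c(9, 9, 9))
  T <- rigid_transform(diag(3), c(3, 0, 0))
  r <- apply_transform(T, m)
  expect_equal(sum(r$voxels), sum(m$voxels))
  ci <- colMeans(arrayInd(which(r$voxels), dim(r$voxels)))
  ci0 <- colMeans(arrayInd(which(m$voxels), dim(m$voxels)))
  expect_equal(ci - ci0, c(3, 0, 0), tolerance = 1e-9)
})

test_that("transform JSON persistence round-trips", {
  set.seed(10)
  T <- rigid_transform(rand_rotation(), c(1.5, -2.25, 9),
                       rms_residual = 0.12, landmark_count = 8L)
  p <- file.path(tempdir(), "t.json")
  write_transform_json(T, p)
  T2 <- read_transform_json(p)
  expect_equal(T2$rotation, T$rotation, tolerance = 1e-12)
  expect_equal(T2$translation, T$translation, tolerance = 1e-12)
  expect_equal(T2$rms_residual, 0.12)
})

test_that("landmark CSV round-trips by scan", {
  set.seed(12)
  lms <- list(s1 = rand_landmarks(4), s2 = rand_landmarks(4))
  p <- file.path(tempdir(), "lm.csv")
  write_landmarks_csv(lms, p)
  back <- read_landmarks_csv(p)
  expect_equal(names(back), c("s1", "s2"))
  expect_equal(back$s1$points, lms$s1$points, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_identical(back$s2$names, lms$s2$names)
})

test_that("registered phantom screw bodies overlap and axes are collinear", {
  ser <- phantom_series()
  gt <- ser$ground_truth$timepoints
  v1 <- ser$volumes[[1]]; v3 <- ser$volumes[[3]]
  T <- fit_rigid_landmarks(gt[[3]]$landmarks, gt[[1]]$landmarks)
  # programmed motion recovered: T should invert the applied transform
  M <- gt[[3]]$transform
  err <- compose_transform(T, M)
  expect_lt(rot_angle_deg(err$rotation), 0.1)
  expect_lt(max(abs(err$translation)), 0.1)

  # left iliac screw shaft, fitted in each scan's own frame from the
  # partial-volume occupancy around the known tip, then mapped into the
  # reference frame through the fitted registration
  shaft_points <- function(vol, tip, dir) {
    a <- tip + 2 * dir; b <- tip + 11 * dir       # stay clear of the rod
    dims <- dim(vol$voxels)
    ci <- arrayInd(seq_len(prod(dims)), dims) - 1
    ab <- b - a
    tt <- pmin(pmax(sweep(ci, 2, a) %*% ab / sum(ab^2), 0), 1)
    d2 <- rowSums((sweep(ci, 2, a) - tt %*% t(ab))^2)
    sel <- d2 <= 4.5^2
    w <- pmin(pmax((vol$voxels[sel] - 40) / (8000 - 40), 0), 1)
    list(p = ci[sel, , drop = FALSE], w = w)
  }
  fit_dir <- function(sp) {
    mu <- colSums(sp$p * sp$w) / sum(sp$w)
    cc <- sweep(sp$p, 2, mu)
    ev <- eigen(crossprod(cc * sqrt(sp$w)))$vectors[, 1]
    list(dir = ev / sqrt(sum(ev^2)), centroid = mu)
  }
  dir_x <- c(1, 0, 0)
  f1 <- fit_dir(shaft_points(v1, gt[[1]]$fixed_scan, dir_x))
  M3 <- gt[[3]]$transform
  f3 <- fit_dir(shaft_points(v3, gt[[3]]$fixed_scan,
                             as.numeric(M3$rotation %*% dir_x)))
  dir3_ref <- as.numeric(T$rotation %*% f3$dir)
  expect_lt(axis_angle_deg(f1$dir, dir3_ref), 1)
  # inter-axis perpendicular distance below half a voxel
  c3_ref <- as.numeric(T$rotation %*% f3$centroid + T$translation)
  d <- c3_ref - f1$centroid
  perp <- d - sum(d * f1$dir) * f1$dir
  expect_lt(sqrt(sum(perp^2)), 0.5)
})
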