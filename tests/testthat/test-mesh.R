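test_that("cuberille mesh of a solid cube is watertight with the right volume", {
  m <- box_mask(c(14, 14, 14), c(3, 3, 3), c(12, 12, 12))   # 10^3 voxels
  mesh <- mesh_from_mask(m)
  expect_equal(mesh_euler(mesh), 2)                  # topological sphere
  expect_equal(mesh_volume(mesh), 1000, tolerance = 0.05)
  # cuberille volume is exact for binary masks
  expect_equal(mesh_volume(mesh), 1000, tolerance = 1e-9)
  # watertight: every edge shared by exactly 2 faces
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  expect_true(all(table(key) == 2))
})

test_that("single-voxel mesh encloses one voxel volume", {
  m <- box_mask(c(5, 5, 5), c(3, 3, 3), c(3, 3, 3))
  g <- list(spacing = c(0.7, 0.7, 3.75), origin = c(0, 0, 0),
            orientation = diag(3))
  m2 <- ct_mask(m$voxels, g)
  mesh <- mesh_from_mask(m2)
  expect_equal(mesh_volume(mesh), prod(g$spacing), tolerance = 1e-9)
  expect_equal(mesh_euler(mesh), 2)
})

test_that("meshing an empty mask errors", {
  e <- ct_mask(array(FALSE, c(3, 3, 3)),
               list(spacing = c(1, 1, 1), origin = c(0, 0, 0),
                    orientation = diag(3)))
  expect_error(mesh_from_mask(e), "empty")
})

test_that("mesh volume converges to voxel volume across resolutions", {
  for (n in c(6, 12)) {
    m <- box_mask(c(n + 4, n + 4, n + 4), c(3, 3, 3),
                  c(n + 2, n + 2, n + 2))
    g <- list(spacing = rep(12 / n, 3), origin = c(0, 0, 0),
              orientation = diag(3))
    mesh <- mesh_from_mask(ct_mask(m$voxels, g))
    expect_equal(mesh_volume(mesh), sum(m$voxels) * prod(g$spacing),
                 tolerance = 1e-9)
  }
})

test_that("cuboid clipping drops the discarded side and leaves cuts open", {
  m <- box_mask(c(12, 12, 12), c(2, 2, 2), c(11, 11, 11))
  mesh <- mesh_from_mask(m)   # cube spanning [0.5, 10.5]^3 in world mm
  # disjoint region, keep outside -> unchanged
  far <- cuboid_region(c(50, 50, 50), c(60, 60, 60))
  expect_identical(clip_cuboid(mesh, far, "outside")$vertices,
                   mesh$vertices)
  # region covering everything, keep outside -> empty error
  all_r <- cuboid_region(c(-10, -10, -10), c(20, 20, 20))
  expect_error(clip_cuboid(mesh, all_r, "outside"), "entire mesh")
  # half-space clip: all kept vertices obey the bound
  half <- cuboid_region(c(-1, -1, -1), c(5.5, 20, 20))
  lowx <- clip_cuboid(mesh, half, "inside")
  expect_true(all(lowx$vertices[, 1] <= 5.5 + 1e-12))
  expect_error(cuboid_region(c(1, 1, 1), c(0, 2, 2)), "min corner")
})

test_that("surface distance is zero on itself and exact for offset planes", {
  sq1 <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0),
                            c(0, 1, 0)),
                      rbind(c(1, 2, 3), c(1, 3, 4)), "sq1")
  self <- surface_distance(sq1, sq1)
  expect_equal(self$hd_max, 0)
  expect_equal(self$hd_mean, 0)

  sq2 <- surface_mesh(cbind(sq1$vertices[, 1:2], 2),
                      sq1$faces, "sq2")
  d <- surface_distance(sq1, sq2)
  expect_equal(d$hd_max, 2, tolerance = 1e-6)
  expect_equal(d$hd_mean, 2, tolerance = 1e-6)
  expect_gte(d$hd_max, d$hd_mean - 1e-12)
})

test_that("surface distance is symmetric under swapping meshes", {
  set.seed(11)
  t1 <- surface_mesh(matrix(runif(9), 3), matrix(1:3, 1), "t1")
  t2 <- surface_mesh(matrix(runif(9, 2, 3), 3), matrix(1:3, 1), "t2")
  a <- surface_distance(t1, t2)
  b <- surface_distance(t2, t1)
  expect_equal(a$hd_max, b$hd_max, tolerance = 1e-9)
  expect_equal(a$forward$max, b$backward$max, tolerance = 1e-9)
})

test_that("hd_max matches a brute-force dense point oracle on triangles", {
  set.seed(23)
  for (rep in 1:3) {
    v1 <- matrix(runif(9, 0, 1), 3)
    v2 <- matrix(runif(9, 3, 4.5), 3)
    t1 <- surface_mesh(v1, matrix(1:3, 1), "a")
    t2 <- surface_mesh(v2, matrix(1:3, 1), "b")
    # dense barycentric lattices (independent of the sampling code)
    lattice <- function(v, k) {
      uv <- expand.grid(u = seq(0, 1, length.out = k),
                        v = seq(0, 1, length.out = k))
      uv <- uv[uv$u + uv$v <= 1, ]
      cbind(v[1, 1] + uv$u * (v[2, 1] - v[1, 1]) + uv$v * (v[3, 1] - v[1, 1]),
            v[1, 2] + uv$u * (v[2, 2] - v[1, 2]) + uv$v * (v[3, 2] - v[1, 2]),
            v[1, 3] + uv$u * (v[2, 3] - v[1, 3]) + uv$v * (v[3, 3] - v[1, 3]))
    }
    p1 <- lattice(v1, 230); p2 <- lattice(v2, 230)   # ~2.6e4 each
    one_sided <- function(A, B) {
      mx <- 0
      for (i in seq(1, nrow(A), by = 400)) {
        block <- A[i:min(i + 399, nrow(A)), , drop = FALSE]
        d2 <- outer(rowSums(block^2), rowSums(B^2), `+`) -
          2 * block %*% t(B)
        mx <- max(mx, sqrt(pmax(apply(d2, 1, min), 0)))
      }
      mx
    }
    oracle <- max(one_sided(p1, p2), one_sided(p2, p1))
    est <- surface_distance(t1, t2, samples_per_mm2 = 200)$hd_max
    expect_equal(est, oracle, tolerance = 0.02)
  }
})

test_that("screw axis fit recovers a cylinder axis within 1 degree", {
  set.seed(3)
  ci <- arrayInd(seq_len(40 * 12 * 12), c(40, 12, 12)) - 1
  inside <- (ci[, 2] - 5.5)^2 + (ci[, 3] - 5.5)^2 <= 6.25
  pts <- ci[inside, ]
  ax <- fit_screw_axis(pts)
  expect_lt(axis_angle_deg(ax$direction, c(1, 0, 0)), 1)
  expect_equal(ax$radius, 2.5, tolerance = 0.25)
})

test_that("isotropic point clouds raise an ambiguous-axis error", {
  set.seed(5)
  sphere <- matrix(rnorm(3000), ncol = 3)
  sphere <- sphere / sqrt(rowSums(sphere^2)) * 5
  expect_error(fit_screw_axis(sphere), "ambiguous")
})

test_that("STL write/read round-trips a mesh", {
  m <- box_mask(c(6, 6, 6), c(2, 2, 2), c(4, 4, 4))
  mesh <- mesh_from_mask(m)
  p <- file.path(tempdir(), "rt.stl")
  write_stl(mesh, p)
  back <- read_stl(p)
  expect_equal(nrow(back$faces), nrow(mesh$faces))
  expect_equal(mesh_volume(back), mesh_volume(mesh), tolerance = 1e-6)
})
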