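test_that("category binning uses midpoint edges, upper edge wins ties", {
  b <- category_binning()
  expect_length(b$edges, 9)
  expect_equal(b$edges[1], 0.06)
  expect_identical(bmd_category(c(-0.03, 0, 0.059), b), c(1L, 1L, 1L))
  expect_identical(bmd_category(0.06, b), 2L)        # edge -> higher bin
  expect_identical(bmd_category(1.2, b), 10L)
  expect_identical(bmd_category(b$representatives, b),
                   seq_along(b$representatives))
  expect_error(category_binning(c(0.2, 0.1)), "increasing")
})

test_that("category index is nondecreasing in HU for positive slope", {
  curve <- list(a = 0, b = 0.001)
  hu <- seq(-200, 2000, by = 7)
  cats <- bmd_category(curve$a + curve$b * hu)
  expect_true(all(diff(cats) >= 0))
})

test_that("calibration fit recovers a synthetic line and averages scans", {
  hu <- c(0, 50, 100, 150, 200)
  fit <- fit_calibration(hu)
  expect_equal(fit$a, 0, tolerance = 1e-12)
  expect_equal(fit$b, 0.001, tolerance = 1e-12)
  # mean of per-scan coefficients
  hu2 <- (c(0, 0.05, 0.10, 0.15, 0.20) - 0.02) / 0.0008
  two <- fit_calibration(list(hu, hu2))
  expect_equal(two$a, 0.01, tolerance = 1e-9)
  expect_equal(two$b, 0.0009, tolerance = 1e-9)
  expect_error(fit_calibration(rep(100, 5)), "identical HU")
  expect_error(fit_calibration(hu, densities = rep(0.1, 5)),
               "density levels")
})

test_that("pooled calibration differs from coefficient averaging", {
  hu1 <- c(0, 50, 100, 150, 200)
  hu2 <- (c(0, 0.05, 0.10, 0.15, 0.20) - 0.05) / 0.0005
  avg <- fit_calibration(list(hu1, hu2))
  pool <- fit_calibration(list(hu1, hu2), pooled = TRUE)
  expect_equal(avg$b, (0.001 + 0.0005) / 2, tolerance = 1e-9)
  expect_false(isTRUE(all.equal(avg$b, pool$b)))
})

test_that("ROI slice sits at the screw-tip midplane", {
  v <- ct_volume(array(0, c(8, 8, 10)), c(1, 1, 3.75))
  s <- select_roi_slice(v, c(2, 2, 10), c(2, 2, 20))
  expect_equal(s$z_realized, 15)                 # slice index 4, z 15
  s2 <- select_roi_slice(v, c(2, 2, 12), c(2, 2, 12))
  expect_equal(s2$z_realized, 11.25)             # nearest to 12
  expect_error(select_roi_slice(v, c(2, 2, 200), c(2, 2, 10)), "outside")
})

test_that("voxel FE mesh clamps negative BMD and bins on half-open edges", {
  slice <- list(values = matrix(c(-500, 60, 1200, 2000), 2, 2),
                geometry = list(spacing = c(0.742, 0.742, 3.75),
                                origin = c(0, 0, 0),
                                orientation = diag(3)))
  curve <- list(a = 0, b = 0.001)
  mesh <- build_bmd_mesh(slice, matrix(TRUE, 2, 2), curve)
  expect_equal(nrow(mesh$elements), 4)
  expect_equal(mesh$elements$bmd[1], 0)            # clamped from -0.5
  expect_identical(mesh$elements$category[1], 1L)
  expect_identical(bmd_category(0.06), 2L)
  # uniform BMD beyond the last representative -> all category 10
  hi <- build_bmd_mesh(list(values = matrix(1200, 3, 3),
                            geometry = slice$geometry),
                       matrix(TRUE, 3, 3), curve)
  expect_true(all(hi$elements$category == 10L))
  expect_error(build_bmd_mesh(slice, matrix(FALSE, 2, 2), curve), "empty")
})

test_that("category volumes: 100 elements of one category in cm^3", {
  vals <- matrix(250, 10, 10)                      # BMD 0.25 -> category 3
  slice <- list(values = vals,
                geometry = list(spacing = c(0.742, 0.742, 3.75),
                                origin = c(0, 0, 0),
                                orientation = diag(3)))
  mesh <- build_bmd_mesh(slice, matrix(TRUE, 10, 10),
                         list(a = 0, b = 0.001))
  vt <- category_volumes(list(mesh), scan_ids = "s1", days = 7)
  expect_equal(vt$cat3, 100 * 0.742 * 0.742 * 3.75 / 1000,
               tolerance = 1e-9)
  expect_equal(vt$cat3, 0.2065, tolerance = 1e-3)
  other <- grep("^cat", names(vt), value = TRUE)
  expect_equal(sum(vt[, setdiff(other, "cat3")]), 0)
})

test_that("row sums conserve total ROI bone volume", {
  set.seed(31)
  geometry <- list(spacing = c(0.8, 0.8, 3), origin = c(0, 0, 0),
                   orientation = diag(3))
  meshes <- lapply(1:3, function(i) {
    vals <- matrix(runif(400, -200, 1500), 20, 20)
    mask <- matrix(runif(400) < 0.6, 20, 20)
    build_bmd_mesh(list(values = vals, geometry = geometry), mask,
                   list(a = 0, b = 0.001))
  })
  vt <- category_volumes(meshes, days = c(7, 34, 83))
  rows <- rowSums(vt[, grep("^cat", names(vt))])
  expected <- vapply(meshes, function(m)
    nrow(m$elements) * m$element_volume_mm3 / 1000, 0)
  expect_equal(rows, expected, tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(as.matrix(vt[, grep("^cat", names(vt))]) >= 0))
})

test_that("volume table CSV round-trips", {
  vt <- followup_bmd_volumes()
  expect_equal(dim(vt), c(12, 12))
  p <- file.path(tempdir(), "vt.csv")
  write_volume_table_csv(vt, p)
  back <- read_volume_table_csv(p)
  expect_equal(as.data.frame(back), as.data.frame(vt), tolerance = 1e-12)
})

test_that("calibration phantom closed loop recovers (a, b) to 1e-9", {
  cal <- phantom_calibration()
  hu <- insertion_mean_hu(cal$volume, cal$insertions)
  fit <- fit_calibration(hu, densities = cal$insertions$density)
  expect_equal(fit$a, cal$a, tolerance = 1e-9)
  expect_equal(fit$b, cal$b, tolerance = 1e-9)
  expect_gt(fit$r_squared, 1 - 1e-12)
  # insertion interior HU equals (density - a)/b exactly when noiseless
  expect_equal(hu, cal$insertions$hu_true, tolerance = 1e-9)
})

test_that("degenerate calibration line is rejected at generation", {
  expect_error(phantom_spec(calibration = list(a = 0, b = 0,
                                               densities = 1:5 / 10)),
               "degenerate")
})

test_that("VTK export writes one hexahedron per element", {
  slice <- list(values = matrix(300, 2, 3),
                geometry = list(spacing = c(1, 1, 2), origin = c(0, 0, 0),
                                orientation = diag(3)))
  mesh <- build_bmd_mesh(slice, matrix(TRUE, 2, 3), list(a = 0, b = 0.001))
  p <- file.path(tempdir(), "m.vtk")
  write_bmd_vtk(mesh, p)
  lines <- readLines(p)
  expect_true(any(grepl("CELLS 6 54", lines)))
  expect_true(any(grepl("SCALARS bmd", lines)))
})
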