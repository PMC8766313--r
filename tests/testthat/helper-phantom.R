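# Shared phantom fixtures, generated once per test session.

.phantom_env <- new.env(parent = emptyenv())

# Noiseless 3-timepoint follow-up series with default geometry.
phantom_series <- function() {
  if (is.null(.phantom_env$series)) {
    spec <- phantom_spec(noise_sd = 0, seed = 42)
    .phantom_env$series <- generate_followup_series(spec, 4)
    .phantom_env$spec <- spec
  }
  .phantom_env$series
}

phantom_spec_cached <- function() {
  phantom_series()
  .phantom_env$spec
}

# Noiseless calibration phantom scan.
phantom_calibration <- function() {
  if (is.null(.phantom_env$cal)) {
    spec <- phantom_spec(noise_sd = 0, seed = 42)
    .phantom_env$cal <- generate_calibration_scan(spec)
  }
  .phantom_env$cal
}

# Small analytic tube mask along +X (no partial volume), for centerline
# and axis-fit oracles.
tube_mask <- function(dims = c(60, 24, 24), center = c(11.5, 11.5),
                      radius = 3, x_range = c(5, 54), hu = 8000) {
  vox <- array(-1000, dims)
  ci <- arrayInd(seq_len(prod(dims)), dims) - 1
  inside <- (ci[, 2] - center[1])^2 + (ci[, 3] - center[2])^2 <=
    radius^2 & ci[, 1] >= x_range[1] & ci[, 1] <= x_range[2]
  vox[inside] <- hu
  threshold_segment(ct_volume(vox, c(1, 1, 1)), 3000, label = "tube")
}

# Logical box helper on an empty grid.
box_mask <- function(dims, lo, hi, geometry = NULL) {
  v <- array(FALSE, dims)
  v[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  g <- geometry %||% list(spacing = c(1, 1, 1), origin = c(0, 0, 0),
                          orientation = diag(3))
  ct_mask(v, g, label = "box")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
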