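# Byte-level writer for minimal Explicit VR Little Endian DICOM CT
# slices, used to exercise the DICOM series reader against files built
# independently of it.

dcm_raw_uint <- function(x, size) {
  as.raw(x %/% 256^(seq_len(size) - 1) %% 256)
}

dcm_element <- function(group, element, vr, value_raw) {
  long <- vr %in% c("OB", "OW", "OF", "OD", "OL", "SQ", "UT", "UN")
  if (length(value_raw) %% 2 == 1) value_raw <- c(value_raw, as.raw(0x20))
  c(dcm_raw_uint(group, 2), dcm_raw_uint(element, 2), charToRaw(vr),
    if (long) c(as.raw(c(0, 0)), dcm_raw_uint(length(value_raw), 4))
    else dcm_raw_uint(length(value_raw), 2),
    value_raw)
}

dcm_ds_val <- function(...) charToRaw(paste(
  vapply(list(...), function(x) sprintf("%g", x), ""), collapse = "\\"))

write_test_dicom_slice <- function(path, pixels, position,
                                   pixel_spacing = c(1, 1),
                                   orientation = c(1, 0, 0, 0, 1, 0),
                                   slope = 1, intercept = -1024) {
  # pixels: matrix [col, row] of stored values (signed 16-bit)
  rows <- ncol(pixels); cols <- nrow(pixels)
  stored <- as.integer(pixels)          # column index fastest (row-major)
  pix <- writeBin(stored, raw(), size = 2, endian = "little")
  ts <- charToRaw("1.2.840.10008.1.2.1")
  meta <- dcm_element(2, 0x0010, "UI", ts)
  body <- c(
    dcm_element(0x0020, 0x0032, "DS",
                charToRaw(paste(sprintf("%g", position), collapse = "\\"))),
    dcm_element(0x0020, 0x0037, "DS",
                charToRaw(paste(sprintf("%g", orientation),
                                collapse = "\\"))),
    dcm_element(0x0028, 0x0010, "US", dcm_raw_uint(rows, 2)),
    dcm_element(0x0028, 0x0011, "US", dcm_raw_uint(cols, 2)),
    dcm_element(0x0028, 0x0030, "DS",
                dcm_ds_val(pixel_spacing[1], pixel_spacing[2])),
    dcm_element(0x0028, 0x0100, "US", dcm_raw_uint(16, 2)),
    dcm_element(0x0028, 0x0103, "US", dcm_raw_uint(1, 2)),
    dcm_element(0x0028, 0x1052, "DS", dcm_ds_val(intercept)),
    dcm_element(0x0028, 0x1053, "DS", dcm_ds_val(slope)),
    dcm_element(0x7fe0, 0x0010, "OW", pix))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, body), con)
  invisible(path)
}

write_test_dicom_series <- function(dir, n_slices = 4, nx = 8, ny = 6,
                                    dz = 2.5, drop_slice = NULL,
                                    value = 1024) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  zs <- (seq_len(n_slices) - 1) * dz
  if (!is.null(drop_slice)) zs <- zs[-drop_slice]
  for (i in seq_along(zs)) {
    px <- matrix(value, nx, ny)
    write_test_dicom_slice(file.path(dir, sprintf("sl%02d.dcm", i)),
                           px, position = c(0, 0, zs[i]))
  }
  dir
}
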