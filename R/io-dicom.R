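# Minimal DICOM series reader: uncompressed Explicit VR Little Endian CT
# slices only. Covers the tags needed to reconstruct a calibrated HU grid
# with its patient-space pose; any other transfer syntax is rejected.

dcm_uint <- function(raw, size) {
  sum(as.integer(raw[seq_len(size)]) * 256^(seq_len(size) - 1))
}

read_dicom_file <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path, call. = FALSE)
  pos <- 133L
  long_vrs <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UT", "UN")
  elements <- list()
  ts <- NULL
  while (pos + 8 <= length(raw) + 1) {
    grp <- dcm_uint(raw[pos:(pos + 1)], 2)
    elt <- dcm_uint(raw[(pos + 2):(pos + 3)], 2)
    vr <- rawToChar(raw[(pos + 4):(pos + 5)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("implicit VR or unsupported encoding in ", path, call. = FALSE)
    if (vr %in% long_vrs) {
      len <- dcm_uint(raw[(pos + 8):(pos + 11)], 4)
      vstart <- pos + 12L
    } else {
      len <- dcm_uint(raw[(pos + 6):(pos + 7)], 2)
      vstart <- pos + 8L
    }
    if (len == 4294967295)
      stop("undefined-length element (sequence) not supported", call. = FALSE)
    value <- if (len > 0) raw[vstart:(vstart + len - 1)] else raw(0)
    key <- sprintf("%04x,%04x", grp, elt)
    elements[[key]] <- list(vr = vr, value = value)
    if (key == "0002,0010")
      ts <- sub("\\s+$", "", gsub("\\x00", "", rawToChar(value)))
    pos <- vstart + len
    if (grp > 2 && !is.null(ts) && ts != "1.2.840.10008.1.2.1")
      stop("unsupported DICOM transfer syntax: ", ts, call. = FALSE)
  }
  elements
}

dcm_str <- function(el, key) {
  e <- el[[key]]
  if (is.null(e)) return(NULL)
  sub("\\s+$", "", gsub("\\x00", "", rawToChar(e$value)))
}

dcm_ds <- function(el, key) {
  s <- dcm_str(el, key)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

dcm_us <- function(el, key) {
  e <- el[[key]]
  if (is.null(e)) return(NULL)
  dcm_uint(e$value, 2)
}

#' Read a DICOM CT series as a calibrated HU volume
#'
#' Reads every DICOM file in a directory, sorts slices along the slice
#' normal, verifies consistent orientation, in-plane spacing and uniform
#' slice stepping, and applies the per-slice RescaleSlope/RescaleIntercept
#' to obtain Hounsfield units. Only uncompressed Explicit VR Little Endian
#' files are supported.
#'
#' @param dir directory containing one series (.dcm files or all files).
#' @return a `ct_volume` in LPS world coordinates.
#' @export
read_dicom_series <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0) stop("no files in ", dir, call. = FALSE)
  slices <- lapply(files, read_dicom_file)

  iop <- lapply(slices, dcm_ds, "0020,0037")
  ps <- lapply(slices, dcm_ds, "0028,0030")
  if (any(vapply(iop, is.null, TRUE)) || any(vapply(ps, is.null, TRUE)))
    stop("missing orientation or pixel spacing", call. = FALSE)
  if (max(vapply(iop, function(v) max(abs(v - iop[[1]])), 0)) > 1e-6 ||
      max(vapply(ps, function(v) max(abs(v - ps[[1]])), 0)) > 1e-6)
    stop("geometry error: slices differ in orientation or in-plane spacing",
         call. = FALSE)
  row_dir <- iop[[1]][1:3]; col_dir <- iop[[1]][4:6]
  normal <- c(row_dir[2] * col_dir[3] - row_dir[3] * col_dir[2],
              row_dir[3] * col_dir[1] - row_dir[1] * col_dir[3],
              row_dir[1] * col_dir[2] - row_dir[2] * col_dir[1])
  ipp <- lapply(slices, dcm_ds, "0020,0032")
  z <- vapply(ipp, function(p) sum(p * normal), 0)
  ord <- order(z)
  slices <- slices[ord]; ipp <- ipp[ord]; z <- z[ord]
  dz <- diff(z)
  if (length(dz) > 0) {
    step <- stats::median(dz)
    if (any(abs(dz - step) > 0.25 * step))
      stop("gap error: non-uniform slice positions (missing slice?)",
           call. = FALSE)
  } else step <- 1

  rows <- dcm_us(slices[[1]], "0028,0010")
  cols <- dcm_us(slices[[1]], "0028,0011")
  bits <- dcm_us(slices[[1]], "0028,0100") %||% 16
  signed <- (dcm_us(slices[[1]], "0028,0103") %||% 1) == 1
  if (bits != 16) stop("only 16-bit pixel data supported", call. = FALSE)

  vox <- array(0, dim = c(cols, rows, length(slices)))
  for (k in seq_along(slices)) {
    el <- slices[[k]]
    pd <- el[["7fe0,0010"]]
    if (is.null(pd)) stop("missing pixel data", call. = FALSE)
    stored <- readBin(pd$value, "integer", n = rows * cols, size = 2,
                      signed = signed, endian = "little")
    slope <- dcm_ds(el, "0028,1053")
    intercept <- dcm_ds(el, "0028,1052")
    if (is.null(slope) || is.null(intercept)) {
      warning("missing rescale metadata; assuming slope 1, intercept 0",
              call. = FALSE)
      slope <- 1; intercept <- 0
    }
    vox[, , k] <- matrix(stored * slope + intercept, nrow = cols, ncol = rows)
  }
  spacing <- c(ps[[1]][2], ps[[1]][1], step)
  orientation <- cbind(row_dir, col_dir, normal)
  dimnames(orientation) <- NULL
  ct_volume(vox, spacing, origin = ipp[[1]], orientation = orientation,
            scan_id = basename(dir))
}
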