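# Minimal NRRD0004 reader/writer (raw encoding, little endian) used for
# fixtures and pipeline intermediates. Header fields follow the NRRD
# definitive spec; only the subset needed for 3D scalar volumes is handled.

nrrd_types <- c(int16 = "short", uint8 = "uchar", double = "double",
                float = "float", int32 = "int")

#' Write a CT volume or mask as NRRD
#'
#' Raw little-endian encoding. Integer-valued HU grids within int16 range
#' are stored as `short` so that write/read round-trips are bit-exact;
#' anything else is stored as `double`. Masks are stored as `uchar` with a
#' `rodmap_label` key.
#'
#' @param x a `ct_volume` or `ct_mask`.
#' @param path output file path (.nrrd).
#' @return `path`, invisibly.
#' @export
write_nrrd <- function(x, path) {
  v <- x$voxels
  is_mask <- inherits(x, "ct_mask")
  if (is_mask) {
    type <- "uchar"; data <- as.integer(v)
  } else if (all(v == round(v)) && max(abs(v)) <= 32767) {
    type <- "short"; data <- as.integer(v)
  } else {
    type <- "double"; data <- as.double(v)
  }
  dirs <- x$orientation %*% diag(x$spacing)
  hdr <- c(
    "NRRD0004",
    "# generated by rodmap",
    sprintf("type: %s", type),
    "dimension: 3",
    "space: left-posterior-superior",
    sprintf("sizes: %s", paste(dim(v), collapse = " ")),
    sprintf("space directions: %s",
            paste(apply(dirs, 2, function(col)
              sprintf("(%.12g,%.12g,%.12g)", col[1], col[2], col[3])),
              collapse = " ")),
    "kinds: domain domain domain",
    "endian: little",
    "encoding: raw",
    sprintf("space origin: (%.12g,%.12g,%.12g)",
            x$origin[1], x$origin[2], x$origin[3]))
  if (is_mask) hdr <- c(hdr, sprintf("rodmap_label:=%s", x$label))
  else {
    hdr <- c(hdr, sprintf("rodmap_scan_id:=%s", x$scan_id))
    if (!is.na(x$days_after_surgery))
      hdr <- c(hdr, sprintf("rodmap_days:=%d", x$days_after_surgery))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(hdr, ""), con, sep = "\n")
  size <- switch(type, short = 2L, uchar = 1L, double = 8L,
                 float = 4L, int = 4L)
  writeBin(data, con, size = size, endian = "little")
  invisible(path)
}

#' Read an NRRD volume or mask
#'
#' Supports 3D raw-encoded NRRD files (types uchar/short/ushort/int/float/
#' double). Files written by [write_nrrd()] round-trip exactly, including
#' geometry and labels.
#'
#' @param path NRRD file path.
#' @return a `ct_volume`, or a `ct_mask` when the file carries a
#'   `rodmap_label` key.
#' @export
read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!grepl("^NRRD000[1-9]", magic))
    stop("not an NRRD file: ", path, call. = FALSE)
  fields <- list(); keys <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0 || line == "") break
    if (grepl("^#", line)) next
    if (grepl(":=", line)) {
      kv <- strsplit(line, ":=", fixed = TRUE)[[1]]
      keys[[kv[1]]] <- kv[2]
    } else {
      kv <- regmatches(line, regexpr(": ", line), invert = TRUE)[[1]]
      fields[[tolower(kv[1])]] <- kv[2]
    }
  }
  if (!identical(fields[["encoding"]], "raw"))
    stop("only raw NRRD encoding is supported", call. = FALSE)
  sizes <- as.integer(strsplit(fields[["sizes"]], " +")[[1]])
  if (length(sizes) != 3L) stop("only 3D NRRD supported", call. = FALSE)
  type <- fields[["type"]]
  endian <- fields[["endian"]] %||% "little"
  rb <- switch(type,
    uchar = , `unsigned char` = , uint8 = , uint8_t =
      function(con, n) readBin(con, "integer", n, size = 1, signed = FALSE),
    short = , int16 = , int16_t = , `signed short` =
      function(con, n) readBin(con, "integer", n, size = 2, signed = TRUE,
                               endian = endian),
    ushort = , uint16 = , uint16_t =
      function(con, n) readBin(con, "integer", n, size = 2, signed = FALSE,
                               endian = endian),
    int = , int32 = , int32_t =
      function(con, n) readBin(con, "integer", n, size = 4, endian = endian),
    float = function(con, n) readBin(con, "double", n, size = 4,
                                     endian = endian),
    double = function(con, n) readBin(con, "double", n, size = 8,
                                      endian = endian),
    stop("unsupported NRRD type: ", type, call. = FALSE))
  n <- prod(sizes)
  data <- rb(con, n)
  if (length(data) != n) stop("truncated NRRD data block", call. = FALSE)
  vox <- array(as.double(data), dim = sizes)

  parse_vecs <- function(s) {
    m <- gregexpr("\\(([^)]*)\\)", s)[[1]]
    vecs <- regmatches(s, gregexpr("\\(([^)]*)\\)", s))[[1]]
    lapply(vecs, function(v)
      as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]]))
  }
  spacing <- c(1, 1, 1); orientation <- diag(3); origin <- c(0, 0, 0)
  if (!is.null(fields[["space directions"]])) {
    cols <- parse_vecs(fields[["space directions"]])
    dirs <- do.call(cbind, cols)
    spacing <- sqrt(colSums(dirs^2))
    orientation <- sweep(dirs, 2, spacing, `/`)
  }
  if (!is.null(fields[["space origin"]]))
    origin <- parse_vecs(fields[["space origin"]])[[1]]
  geom <- list(spacing = spacing, origin = origin, orientation = orientation)
  if (!is.null(keys[["rodmap_label"]]))
    return(ct_mask(vox != 0, geom, label = keys[["rodmap_label"]]))
  days <- if (!is.null(keys[["rodmap_days"]]))
    as.integer(keys[["rodmap_days"]]) else NA_integer_
  ct_volume(vox, spacing, origin, orientation,
            scan_id = keys[["rodmap_scan_id"]] %||%
              sub("\\.nrrd$", "", basename(path)),
            days_after_surgery = days)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
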