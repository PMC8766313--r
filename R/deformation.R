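#' Per-timepoint deformation record between mobile and fixed points
#'
#' The components are absolute per-axis distances between the mobile
#' point (L2 right pedicle screw tip) and the fixed point (caudal iliac
#' screw tip) in the common reference frame: `Xd = |dx|` (mediolateral,
#' displayed in the coronal/frontal plane), `Yd = |dy|` (anteroposterior,
#' axial plane), `Zd = |dz|` (craniocaudal, sagittal plane), and their
#' Euclidean combination `D3d = sqrt(Xd^2 + Yd^2 + Zd^2)`.
#'
#' @param centerline optional `centerline`; when given and
#'   `snap_mobile = TRUE` the mobile point is snapped to its nearest
#'   centerline point (the fixed point is a screw tip off the rod and is
#'   never snapped by default).
#' @param mobile_pt,fixed_pt world-mm points in the registered frame.
#' @param scan_id scan label.
#' @param days_after_surgery integer days.
#' @param snap_mobile snap the mobile point to the centerline
#'   (default TRUE when a centerline is supplied).
#' @return object of class `deformation_record` with fields `scan_id`,
#'   `days_after_surgery`, `Xd`, `Yd`, `Zd`, `D3d`.
#' @export
measure_deformation <- function(mobile_pt, fixed_pt, scan_id = "scan",
                                days_after_surgery = NA_integer_,
                                centerline = NULL, snap_mobile = TRUE) {
  mobile_pt <- as.numeric(mobile_pt); fixed_pt <- as.numeric(fixed_pt)
  if (!is.null(centerline) && snap_mobile)
    mobile_pt <- as.numeric(snap_to_centerline(centerline, mobile_pt))
  d <- abs(mobile_pt - fixed_pt)
  rec <- structure(list(scan_id = as.character(scan_id),
                        days_after_surgery = as.integer(days_after_surgery),
                        Xd = d[1], Yd = d[2], Zd = d[3],
                        D3d = sqrt(sum(d^2))),
                   class = "deformation_record")
  stopifnot(abs(rec$D3d - sqrt(rec$Xd^2 + rec$Yd^2 + rec$Zd^2)) < 1e-9)
  rec
}

#' @export
print.deformation_record <- function(x, ...) {
  cat(sprintf(
    "<deformation_record '%s' day %s> Xd=%.3f Yd=%.3f Zd=%.3f 3Dd=%.3f mm\n",
    x$scan_id, x$days_after_surgery, x$Xd, x$Yd, x$Zd, x$D3d))
  invisible(x)
}

#' Build a longitudinal deformation series
#'
#' Stacks per-timepoint records sorted by days after surgery and derives
#' deltas `|component(t) - component(t1)|` relative to the first record,
#' plus the mean and SD of each delta over the later timepoints.
#'
#' @param records list of `deformation_record` (>= 2), distinct days.
#' @return object of class `deformation_series`: a data.frame `table`
#'   (scan_id, days, Xd, Yd, Zd, D3d, dXd, dYd, dZd) and `summary`
#'   (mean/sd of each delta over timepoints 2..n).
#' @export
build_series <- function(records) {
  if (length(records) < 2)
    stop("need at least 2 records for a series", call. = FALSE)
  df <- do.call(rbind, lapply(records, function(r)
    data.frame(scan_id = r$scan_id, days = r$days_after_surgery,
               Xd = r$Xd, Yd = r$Yd, Zd = r$Zd, D3d = r$D3d)))
  if (anyDuplicated(df$days)) stop("duplicate days in series", call. = FALSE)
  df <- df[order(df$days), ]
  rownames(df) <- NULL
  df$dXd <- abs(df$Xd - df$Xd[1])
  df$dYd <- abs(df$Yd - df$Yd[1])
  df$dZd <- abs(df$Zd - df$Zd[1])
  later <- df[-1, ]
  summ <- data.frame(
    component = c("dXd", "dYd", "dZd"),
    mean = c(mean(later$dXd), mean(later$dYd), mean(later$dZd)),
    sd = c(stats::sd(later$dXd), stats::sd(later$dYd),
           stats::sd(later$dZd)))
  structure(list(table = df, summary = summ), class = "deformation_series")
}

#' @export
print.deformation_series <- function(x, ...) {
  cat(sprintf("<deformation_series> %d timepoints\n", nrow(x$table)))
  print(x$table, digits = 4)
  invisible(x)
}

#' Write a deformation series as CSV
#' @param series a `deformation_series`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_deformation_csv <- function(series, path) {
  utils::write.csv(series$table, path, row.names = FALSE)
  invisible(path)
}
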