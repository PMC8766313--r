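#' Run the full deformation + BMD mapping pipeline
#'
#' Orchestrates, from a structured config: volume loading, landmark-based
#' rigid registration into the reference scan's frame, implant
#' segmentation and centerline extraction, per-timepoint deformation
#' measurement, screw-body registration QC (Hausdorff distances),
#' calibration fitting, ROI-slice voxel FE BMD mapping, the longitudinal
#' per-category volume table, and the Spearman correlation panel. All
#' outputs are plain CSV/JSON/NRRD/STL files in `out_dir`; a rerun with
#' the same config and seed reproduces the CSVs bit-exact.
#'
#' @param config a list or a path to a JSON/YAML config with fields:
#'   `scans` (data.frame/list: `path`, `scan_id`, `days`), `landmarks_csv`,
#'   `reference_scan`, `metal_lo` (default 3000), `bone_lo`/`bone_hi`
#'   (default 226/3000), `mobile_landmark`, `fixed_landmark`,
#'   `roi_landmarks` (2 names), `calibration` (list: `scans` paths or
#'   `insertions_csv`, `densities`), `out_dir`, `seed`, optional `qc`
#'   (logical, default TRUE).
#' @return invisibly, a list with the deformation series, volume table,
#'   correlation panel, transforms and QC reports; files written to
#'   `out_dir`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) read_pipeline_config(config) else config
  need <- c("scans", "landmarks_csv", "reference_scan", "out_dir")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("config error: missing fields ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!file.exists(cfg$landmarks_csv))
    stop("config error: landmark file not found: ", cfg$landmarks_csv,
         call. = FALSE)
  scans <- as.data.frame(cfg$scans)
  if (!all(file.exists(scans$path)))
    stop("config error: missing scan file(s): ",
         paste(scans$path[!file.exists(scans$path)], collapse = ", "),
         call. = FALSE)
  if (!cfg$reference_scan %in% scans$scan_id)
    stop("config error: reference scan not in manifest", call. = FALSE)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- cfg$seed %||% 1L
  set.seed(seed)
  metal_lo <- cfg$metal_lo %||% 3000
  bone_lo <- cfg$bone_lo %||% 226
  bone_hi <- cfg$bone_hi %||% 3000
  logf <- file.path(cfg$out_dir, "pipeline.log")
  logline <- function(...) cat(sprintf(...), "\n", sep = "",
                               file = logf, append = TRUE)
  cat(sprintf("rodmap %s | seed %d | %d scans\n",
              as.character(utils::packageVersion("rodmap")), seed,
              nrow(scans)), file = logf)

  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    r <- tryCatch(force(expr), error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
           call. = FALSE))
    logline("stage %s: %.2f s", name, proc.time()[3] - t0)
    r
  }

  landmarks <- stage("landmarks", read_landmarks_csv(cfg$landmarks_csv))
  vols <- stage("load", lapply(seq_len(nrow(scans)), function(i)
    load_volume(scans$path[i], scan_id = scans$scan_id[i],
                days_after_surgery = scans$days[i])))
  names(vols) <- scans$scan_id

  ref_id <- cfg$reference_scan
  transforms <- stage("register", {
    anat <- cfg$anatomical_landmarks %||%
      grep("^screw", landmarks[[ref_id]]$names, invert = TRUE,
           value = TRUE)
    fixed <- subset_landmarks(landmarks[[ref_id]], anat)
    out <- lapply(scans$scan_id, function(id) {
      T <- fit_rigid_landmarks(subset_landmarks(landmarks[[id]], anat),
                               fixed)
      write_transform_json(T, file.path(cfg$out_dir,
                                        sprintf("transform_%s.json", id)))
      T
    })
    names(out) <- scans$scan_id
    out
  })

  records <- stage("deform", lapply(scans$scan_id, function(id) {
    T <- transforms[[id]]
    imask <- threshold_segment(vols[[id]], metal_lo, label = "implant")
    imask <- largest_components(imask, 1)[[1]]
    rmask <- apply_transform(T, imask, reference = vols[[ref_id]])
    cl <- extract_centerline(rmask)
    write_centerline_ply(cl, file.path(cfg$out_dir,
                                       sprintf("centerline_%s.ply", id)))
    lm <- apply_transform(T, landmarks[[id]])
    mobile <- lm$points[match(cfg$mobile_landmark, lm$names), ]
    fixedp <- lm$points[match(cfg$fixed_landmark, lm$names), ]
    measure_deformation(mobile, fixedp, scan_id = id,
                        days_after_surgery =
                          scans$days[scans$scan_id == id],
                        centerline = cl, snap_mobile = TRUE)
  }))
  series <- build_series(records)
  write_deformation_csv(series, file.path(cfg$out_dir, "deformation.csv"))

  qc <- NULL
  if (isTRUE(cfg$qc %||% TRUE))
    qc <- stage("qc", {
      ref_mask <- largest_components(
        threshold_segment(vols[[ref_id]], metal_lo, label = "implant"),
        1)[[1]]
      ref_mesh <- mesh_from_mask(ref_mask)
      reports <- lapply(scans$scan_id, function(id) {
        if (id == ref_id) return(NULL)
        m <- largest_components(
          threshold_segment(vols[[id]], metal_lo, label = "implant"),
          1)[[1]]
        mm <- apply_transform(transforms[[id]], mesh_from_mask(m))
        sd <- surface_distance(mm, ref_mesh, max_samples = 1500,
                               seed = seed)
        list(scan_id = id, hd_max = sd$hd_max, hd_mean = sd$hd_mean)
      })
      reports <- Filter(Negate(is.null), reports)
      jsonlite::write_json(reports, file.path(cfg$out_dir, "qc.json"),
                           auto_unbox = TRUE, digits = NA)
      reports
    })

  vt <- NULL
  if (!is.null(cfg$calibration)) {
    curve <- stage("calibrate", {
      cal <- cfg$calibration
      hu <- if (!is.null(cal$insertion_hu)) cal$insertion_hu
      else lapply(cal$scans, function(p) {
        cv <- load_volume(p)
        ins <- utils::read.csv(cal$insertions_csv)
        insertion_mean_hu(cv, ins)
      })
      fit_calibration(hu, densities = cal$densities %||%
                        c(0, 0.05, 0.10, 0.15, 0.20))
    })
    vt <- stage("bmd", {
      meshes <- lapply(scans$scan_id, function(id) {
        lm <- landmarks[[id]]
        tips <- lapply(cfg$roi_landmarks, function(nm)
          lm$points[match(nm, lm$names), ])
        sl <- select_roi_slice(vols[[id]], tips[[1]], tips[[2]])
        bone <- sl$values >= bone_lo & sl$values <= bone_hi
        build_bmd_mesh(sl, bone, curve)
      })
      category_volumes(meshes, scan_ids = scans$scan_id,
                       days = scans$days)
    })
    write_volume_table_csv(vt, file.path(cfg$out_dir, "volume_table.csv"))
  }

  panel <- NULL
  if (!is.null(vt)) {
    panel <- stage("stats", correlation_panel(vt, series))
    utils::write.csv(panel$panel, file.path(cfg$out_dir, "stats_panel.csv"),
                     row.names = FALSE)
  }
  logline("done")
  invisible(list(series = series, volume_table = vt, panel = panel,
                 transforms = transforms, qc = qc))
}

subset_landmarks <- function(ls, names) {
  landmark_set(ls$points[match(names, ls$names), , drop = FALSE], names)
}

#' Read a pipeline config from JSON or YAML
#' @param path config file path (.json, .yaml/.yml).
#' @return config list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config error: ", path, " not found",
                               call. = FALSE)
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML configs", call. = FALSE)
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
}
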