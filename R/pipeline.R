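#' Pipeline configuration
#'
#' One flat, serializable document of every tunable parameter of the
#' extraction pipeline; validated eagerly so misconfiguration fails before
#' any computation.
#'
#' @param scales_mm Vesselness scales (mm).
#' @param tau Jerman cutoff fraction in (0, 1].
#' @param threshold Vesselness segmentation threshold in (0, 1) or `"auto"`.
#' @param band_depth_mm Subcutaneous band depth (mm).
#' @param skin_margin_mm Skin shell excluded from the band (mm).
#' @param min_component_voxels Minimum vessel component size (voxels).
#' @param min_branch_mm Minimum centerline branch length (mm).
#' @param smooth_iterations Mesh smoothing iterations.
#' @param seed Integer seed for any stochastic stage.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(scales_mm = c(0.5, 0.75, 1, 1.5, 2),
                            tau = 0.5, threshold = 0.5, band_depth_mm = 15,
                            skin_margin_mm = 2.5,
                            min_component_voxels = 20L, min_branch_mm = 5,
                            smooth_iterations = 10L, seed = 1L) {
  if (length(scales_mm) == 0 || any(scales_mm <= 0)) {
    am_stop("`scales_mm` must be positive and non-empty",
            "arterymap_validation_error")
  }
  if (!is.numeric(tau) || tau <= 0 || tau > 1) {
    am_stop("`tau` must lie in (0, 1]", "arterymap_validation_error")
  }
  if (!identical(threshold, "auto") &&
      (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)) {
    am_stop("`threshold` must lie in (0, 1) or be \"auto\"",
            "arterymap_validation_error")
  }
  if (band_depth_mm <= 0 || min_branch_mm < 0 || min_component_voxels < 1 ||
      skin_margin_mm < 0 || skin_margin_mm >= band_depth_mm) {
    am_stop("band depth, branch length and component size must be positive and the skin margin below the band depth",
            "arterymap_validation_error")
  }
  structure(list(scales_mm = as.numeric(scales_mm), tau = tau,
                 threshold = threshold, band_depth_mm = band_depth_mm,
                 skin_margin_mm = skin_margin_mm,
                 min_component_voxels = as.integer(min_component_voxels),
                 min_branch_mm = min_branch_mm,
                 smooth_iterations = as.integer(smooth_iterations),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

stage_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf("[arterymap %s] %s", format(Sys.time(), "%H:%M:%S"),
                               sprintf(fmt, ...)))
}

#' Run the full extraction pipeline
#'
#' Enhancement, thresholding, band restriction, meshing, STL export,
#' centerline extraction and artery labeling, with every artifact written to
#' a run directory together with a manifest (effective configuration,
#' package version, content hash of every file). Deterministic given its
#' inputs: re-running with the same inputs reproduces identical hashes. If
#' `view_landmarks2d` and `camera` are supplied, the labeled centerlines are
#' registered into the view and written as a 2-D overlay.
#'
#' @param volume An [image_volume()].
#' @param landmarks3d 68-point landmark tibble/matrix in the volume's frame.
#' @param out_dir Run directory (created if needed).
#' @param config A [pipeline_config()].
#' @param view_landmarks2d Optional 68 x 2 tracked view landmarks (px).
#' @param camera Optional [camera_model()] for the overlay.
#' @param verbose Log per-stage progress to stderr.
#' @return Invisibly, a list with the run artifacts (`vesselness`, `mask`,
#'   `mesh`, `centerlines`, `labeled`, `overlay`, `manifest`).
#' @export
run_pipeline <- function(volume, landmarks3d, out_dir,
                         config = pipeline_config(),
                         view_landmarks2d = NULL, camera = NULL,
                         verbose = TRUE) {
  stopifnot(inherits(volume, "image_volume"), inherits(config, "pipeline_config"))
  lm <- check_landmark_count(as_landmark_matrix(landmarks3d))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  stage_log(verbose, "vesselness: %d scales on %s grid", length(config$scales_mm),
            paste(dim(volume$data), collapse = "x"))
  vness <- multiscale_vesselness(volume, config$scales_mm, config$tau)
  stage_log(verbose, "segmentation: threshold %s, band %.1f mm",
            format(config$threshold), config$band_depth_mm)
  vmask <- threshold_segment(vness, config$threshold)
  band <- subcutaneous_band_mask(volume, config$band_depth_mm,
                                 skin_margin_mm = config$skin_margin_mm)
  sup <- separate_superficial(vmask, band, config$min_component_voxels)
  stage_log(verbose, "meshing %d foreground voxels", sum(sup$data))
  mesh <- marching_cubes_mesh(sup, smooth_iterations = config$smooth_iterations)
  stage_log(verbose, "centerlines")
  cls <- skeletonize_centerlines(sup, config$min_branch_mm)
  atlas <- build_region_atlas(lm)
  labeled <- label_centerlines(cls, atlas)
  files <- list(
    vesselness = "vesselness.nii.gz", mask = "mask.nii.gz",
    stl = "arteries.stl", centerlines = "centerlines.json",
    report = "labels.csv"
  )
  paths <- lapply(files, function(f) file.path(out_dir, f))
  vness_vol <- image_volume(vness$response, volume$spacing, volume$origin,
                            volume$orientation)
  write_nifti(vness_vol, paths$vesselness, datatype = "float")
  mask_vol <- image_volume(array(as.integer(sup$data), dim(sup$data)),
                           volume$spacing, volume$origin, volume$orientation)
  write_nifti(mask_vol, paths$mask, datatype = "uint8")
  write_stl(mesh, paths$stl)
  write_centerlines_json(labeled, paths$centerlines)
  label_tbl <- tibble::tibble(
    curve = seq_along(labeled),
    label = vapply(labeled, function(cl) cl$label, character(1)),
    n_points = vapply(labeled, function(cl) nrow(cl$points), integer(1)),
    length_mm = vapply(labeled, polyline_length, numeric(1))
  )
  readr::write_csv(label_tbl, paths$report)
  overlay <- NULL
  if (!is.null(view_landmarks2d) && !is.null(camera)) {
    stage_log(verbose, "registration into camera view")
    reg <- register_model_to_view(lm, view_landmarks2d, camera,
                                  arterial_geometry = labeled)
    overlay <- reg$overlay
    paths$overlay <- file.path(out_dir, "overlay.json")
    jsonlite::write_json(overlay, paths$overlay, digits = NA)
  }
  manifest <- list(
    package = "arterymap",
    version = as.character(utils::packageVersion("arterymap")),
    config = unclass(config),
    files = lapply(paths, function(p) unname(tools::md5sum(p)))
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  stage_log(verbose, "done in %.1f s", as.numeric(Sys.time() - t0, units = "secs"))
  invisible(list(vesselness = vness, mask = sup, mesh = mesh,
                 centerlines = cls, labeled = labeled, overlay = overlay,
                 manifest = manifest, out_dir = out_dir))
}

write_centerlines_json <- function(centerlines, path) {
  payload <- lapply(centerlines, function(cl) {
    list(label = cl$label,
         points_mm = apply(cl$points, 1, identity, simplify = FALSE),
         radius_mm = cl$radius_mm)
  })
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read centerlines written by [run_pipeline()]
#' @param path `centerlines.json` path.
#' @return List of [centerline_polyline()].
#' @export
read_centerlines_json <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(payload, function(cl) {
    centerline_polyline(do.call(rbind, lapply(cl$points_mm, unlist)),
                        radius_mm = unlist(cl$radius_mm),
                        label = cl$label)
  })
}
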