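#' Analyse a tile set: detect, stitch, deduplicate, spatial statistics
#'
#' The per-droplet core of the pipeline: optional distortion correction,
#' per-tile spot detection, pair-offset estimation, global layout, mapping
#' to the droplet frame, overlap deduplication and the CSR check. Counting
#' is always per-tile followed by deduplication in global coordinates; the
#' stitched mosaic is never itself counted.
#'
#' @param tiles List of `eva_tile`s.
#' @param manifest Tile manifest data frame.
#' @param detector An [detector_params()].
#' @param distortion Optional `eva_distortion` correction applied to each
#'   tile before detection.
#' @param search_radius_px,confidence_floor Stitching controls.
#' @param dedup_radius_um Overlap merge radius.
#' @param csr_boot Bootstrap replicates for the CSR p-value (0 skips the
#'   test).
#' @param seed Seed for the CSR bootstrap substream.
#' @return List: `detections` (deduplicated, global coordinates), `layout`,
#'   `csr` (or NULL), `counts` (per-stage ledger: detected, deduplicated).
#' @export
analyze_tile_set <- function(tiles, manifest, detector = detector_params(),
                             distortion = NULL, search_radius_px = 14L,
                             confidence_floor = 0.3, dedup_radius_um = 2 *
                               attr(manifest, "pixel_size_um"),
                             csr_boot = 500L, seed = 1L) {
  ps <- attr(manifest, "pixel_size_um")
  if (!is.null(distortion))
    tiles <- lapply(tiles, undistort_image, model = distortion)
  det_list <- lapply(tiles, detect_spots, params = detector)
  detections <- do.call(rbind, det_list)
  if (length(tiles) > 1L) {
    optics_like <- list(step = step_from_manifest(manifest),
                        pixel_size = ps,
                        frame_size = ncol(tiles[[1]]$data) * ps)
    offs <- grid_pair_offsets_generic(tiles, optics_like, search_radius_px)
    layout <- solve_global_layout(offs, manifest, ps, confidence_floor)
  } else {
    layout <- structure(list(
      tiles = data.frame(row = manifest$row, col = manifest$col,
                         x_um = manifest$nominal_x_um,
                         y_um = manifest$nominal_y_um),
      anchor = c(row = manifest$row[1], col = manifest$col[1]),
      residual_rms_px = 0, pixel_size = ps), class = "eva_mosaic_layout")
  }
  n_detected <- nrow(detections)
  if (n_detected) {
    detections <- to_global(detections, layout, ps)
    detections <- deduplicate(detections, radius = dedup_radius_um)
  }
  csr <- NULL
  if (csr_boot > 0 && nrow(detections) >= 50)
    csr <- fit_csr(cbind(detections$x_um, detections$y_um),
                   n_boot = csr_boot, seed = seed)
  list(detections = detections, layout = layout, csr = csr,
       counts = c(detected = n_detected, deduplicated = nrow(detections)))
}

step_from_manifest <- function(manifest) {
  ux <- sort(unique(manifest$nominal_x_um))
  uy <- sort(unique(manifest$nominal_y_um))
  steps <- c(diff(ux), diff(uy))
  if (!length(steps)) return(NA_real_)
  median(steps)
}

grid_pair_offsets_generic <- function(tiles, optics_like, search_radius) {
  key <- vapply(tiles, function(t) paste(t$row, t$col), "")
  step_px <- optics_like$step / optics_like$pixel_size
  offs <- list()
  for (t in tiles) {
    for (d in list(c(0, 1), c(1, 0))) {
      i <- match(paste(t$row + d[1], t$col + d[2]), key)
      if (is.na(i)) next
      nominal <- c(d[2], d[1]) * step_px
      offs[[length(offs) + 1L]] <-
        estimate_pair_offset(t, tiles[[i]], nominal, search_radius)
    }
  }
  offs
}

#' Run the full EVA pipeline from a configuration
#'
#' Executes read -> (undistort) -> detect per tile -> stitch -> map to the
#' droplet frame -> deduplicate -> spatial statistics -> quantify, and
#' persists `detections.csv`, `layout.json` and `report.json` in the output
#' directory. The report is deterministic for a fixed configuration and
#' input (no timestamps).
#'
#' @param config An `eva_run_config` (see [read_run_config()]) or a path to
#'   a YAML file.
#' @return The run report (list), invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "eva_run_config"))
    config <- validate_run_config(config)
  stage <- "read"
  out_dir <- config$paths$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = config$seed)
  result <- tryCatch({
    ts <- read_tile_set(config$paths$tiles_dir, config$paths$manifest)
    distortion <- NULL
    if (!is.null(config$distortion_model))
      distortion <- read_distortion_model(config$distortion_model)
    stage <- "analyze"
    ana <- analyze_tile_set(
      ts$tiles, ts$manifest, detector = config$detector_params,
      distortion = distortion,
      search_radius_px = config$stitching$search_radius_px,
      confidence_floor = config$stitching$confidence_floor,
      dedup_radius_um = config$dedup_radius_um %||%
        (2 * attr(ts$manifest, "pixel_size_um")),
      seed = config$seed)
    stage <- "quantify"
    est <- concentration_estimate(nrow(ana$detections),
                                  config$sample_descriptor)
    lim <- detection_limits(
      sum(config$sample_descriptor$droplet_volumes_ul) * 1e-3,
      config$sample_descriptor$dilution_factor)
    stage <- "write"
    det_out <- cbind(droplet_id = config$droplet_id %||% 1L, ana$detections)
    write.csv(det_out, file.path(out_dir, "detections.csv"),
              row.names = FALSE)
    write_layout(ana$layout, file.path(out_dir, "layout.json"))
    report <- list(
      seed = config$seed,
      particle_ledger = as.list(ana$counts),
      concentration = list(
        c_mean_per_ml = est$c_mean,
        u_rel_combined = est$u_rel_combined,
        u_components = as.list(est$u_components),
        coverage_interval = as.list(est$coverage_interval),
        k = est$k,
        counts_per_droplet = est$counts_per_droplet),
      limits = list(lod_count = lim$lod_count, loq_count = lim$loq_count,
                    lod_conc_per_ml = lim$lod_conc,
                    loq_conc_per_ml = lim$loq_conc),
      csr_fit = if (!is.null(ana$csr)) list(
        density_rho_um2 = ana$csr$density_rho,
        ks_statistic = ana$csr$ks_statistic,
        ks_pvalue = ana$csr$ks_pvalue,
        n_points = ana$csr$n_points) else NULL,
      layout_residual_rms_px = ana$layout$residual_rms_px)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    report
  }, error = function(e) {
    jsonlite::write_json(list(error = conditionMessage(e), stage = stage),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
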