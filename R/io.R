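#' Write a tile set (16-bit TIFFs plus JSON manifest and truth CSV)
#'
#' Tiles are written as `tile_r{row}_c{col}.tif` (16-bit grayscale), the
#' manifest as `manifest.json`, and - if ground truth is supplied - the
#' particle table as `ground_truth.csv` with header
#' `x_um,y_um,intensity,is_aggregate`.
#'
#' @param grid Result of [generate_tile_grid()] (list with `tiles`,
#'   `manifest`).
#' @param dir Output directory (created if missing).
#' @param truth Optional `eva_ground_truth` to persist alongside.
#' @return `dir`, invisibly.
#' @export
write_tile_set <- function(grid, dir, truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- grid$manifest
  for (i in seq_along(grid$tiles)) {
    t <- grid$tiles[[i]]
    tiff::writeTIFF(t$data / 65535, file.path(dir, man$file[i]),
                    bits.per.sample = 16L, compression = "none")
  }
  g <- attr(man, "grid")
  jsonlite::write_json(list(
    grid = list(rows = g[["rows"]], cols = g[["cols"]]),
    pixel_size_um = attr(man, "pixel_size_um"),
    seed = attr(man, "seed"),
    coverage_warning = attr(man, "coverage_warning"),
    tiles = man), file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows", null = "null")
  if (!is.null(truth)) write_ground_truth(truth, file.path(dir,
                                                           "ground_truth.csv"))
  invisible(dir)
}

#' @rdname write_tile_set
#' @param truth_path CSV path for the ground-truth table.
#' @export
write_ground_truth <- function(truth, truth_path) {
  df <- data.frame(x_um = truth$positions[, 1], y_um = truth$positions[, 2],
                   intensity = truth$intensities,
                   is_aggregate = truth$is_aggregate)
  write.csv(df, truth_path, row.names = FALSE)
  invisible(truth_path)
}

#' Read a tile set written by [write_tile_set()]
#'
#' Validates that every referenced TIFF exists, that tile shapes agree, and
#' that the pixel size is consistent; errors name the offending tile. 8-bit
#' tiles are accepted, rescaled to the 16-bit count range, and reported with
#' a warning.
#'
#' @param dir Directory containing the tiles.
#' @param manifest Manifest filename within `dir`.
#' @return List with `tiles` (list of `eva_tile`) and `manifest` (data frame
#'   with attributes `grid`, `seed`, `pixel_size_um`).
#' @export
read_tile_set <- function(dir, manifest = "manifest.json") {
  mpath <- file.path(dir, manifest)
  if (!file.exists(mpath)) stop("manifest not found: ", mpath)
  j <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  man <- as.data.frame(j$tiles)
  tiles <- vector("list", nrow(man))
  shape <- NULL
  for (i in seq_len(nrow(man))) {
    f <- file.path(dir, man$file[i])
    if (!file.exists(f)) stop("missing tile file: ", man$file[i])
    raw <- tiff::readTIFF(f, as.is = TRUE)
    if (length(dim(raw)) == 3L) raw <- raw[, , 1]
    bits <- attr(raw, "bits.per.sample") %||%
      (if (max(raw) <= 255) 8L else 16L)
    if (bits == 8L) {
      warning("tile ", man$file[i], " is 8-bit; rescaled to 16-bit counts")
      raw <- raw * 257
    }
    data <- matrix(as.numeric(raw), nrow(raw), ncol(raw))
    if (is.null(shape)) shape <- dim(data)
    else if (!all(dim(data) == shape))
      stop("tile ", man$file[i], " has shape ", paste(dim(data),
           collapse = "x"), ", expected ", paste(shape, collapse = "x"))
    tiles[[i]] <- structure(list(
      data = data, row = man$row[i], col = man$col[i],
      nominal_position = c(man$nominal_x_um[i], man$nominal_y_um[i]),
      stage_position = NULL,
      pixel_size = j$pixel_size_um), class = "eva_tile")
  }
  if (!is.null(man$pixel_size_um) &&
      any(abs(man$pixel_size_um - j$pixel_size_um) >
          1e-9 * j$pixel_size_um))
    stop("pixel-size conflict between manifest entries")
  attr(man, "grid") <- c(rows = j$grid$rows, cols = j$grid$cols)
  attr(man, "seed") <- j$seed
  attr(man, "pixel_size_um") <- j$pixel_size_um
  list(tiles = tiles, manifest = man)
}

#' Read ground truth written by [write_ground_truth()]
#' @param path CSV path.
#' @return Data frame `x_um`, `y_um`, `intensity`, `is_aggregate`.
#' @export
read_ground_truth <- function(path) read.csv(path)

#' Read and validate a pipeline run configuration (YAML)
#'
#' A run is reproducible from configuration + inputs + seed. Recognised
#' blocks: `paths` (tiles_dir, manifest, output_dir), `optics` overrides,
#' `detector` overrides, `sample` (droplet_volumes_ul, u_volume_rel,
#' dilution_factor, u_dilution_rel), `stitching` (search_radius_px,
#' confidence_floor), `dedup_radius_um`, `distortion_model` (path), `seed`.
#'
#' @param path YAML file.
#' @return Validated config list (class `eva_run_config`).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg A configuration list.
#' @export
validate_run_config <- function(cfg) {
  if (is.null(cfg$paths$tiles_dir)) stop("config: paths.tiles_dir missing")
  if (is.null(cfg$paths$output_dir)) stop("config: paths.output_dir missing")
  cfg$paths$manifest <- cfg$paths$manifest %||% "manifest.json"
  sm <- cfg$sample %||% list()
  cfg$sample_descriptor <- sample_descriptor(
    droplet_volumes_ul = sm$droplet_volumes_ul %||% 2.5,
    u_volume_rel = sm$u_volume_rel %||% 0.025,
    dilution_factor = sm$dilution_factor %||% 1,
    u_dilution_rel = sm$u_dilution_rel %||% 0)
  det <- cfg$detector %||% list()
  cfg$detector_params <- detector_params(
    expected_fwhm_px = det$expected_fwhm_px %||% 1.8,
    threshold_k = det$threshold_k %||% 5,
    min_separation_px = det$min_separation_px %||% 2L,
    fit_window_px = det$fit_window_px %||% 7L)
  st <- cfg$stitching %||% list()
  cfg$stitching <- list(search_radius_px = st$search_radius_px %||% 14L,
                        confidence_floor = st$confidence_floor %||% 0.3)
  cfg$seed <- cfg$seed %||% 1L
  class(cfg) <- "eva_run_config"
  cfg
}

#' Serialize a mosaic layout as JSON
#' @param layout An `eva_mosaic_layout`.
#' @param path Output path.
#' @export
write_layout <- function(layout, path) {
  jsonlite::write_json(list(
    anchor = as.list(layout$anchor),
    residual_rms_px = layout$residual_rms_px,
    pixel_size = layout$pixel_size,
    tiles = layout$tiles), path, auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  invisible(path)
}
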