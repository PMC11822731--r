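#' Droplet specification for the synthetic-data generator
#'
#' Describes a dried droplet before imaging: its physical geometry, the
#' in-droplet number concentration of particles, the spatial placement model,
#' and the per-particle brightness distribution. The expected particle count
#' is `in_droplet_concentration * droplet_volume` (volume in mL); the realised
#' count is Poisson.
#'
#' @param droplet_radius Radius of the dried deposit in micrometres
#'   (default 1500, i.e. a ~3 mm droplet).
#' @param droplet_volume Deposited volume in microlitres (default 2.5).
#' @param in_droplet_concentration Particle number concentration of the
#'   dispensed (post-dilution) dispersion, per mL. The default gives an
#'   expected count of 4438 particles per droplet, the scale of a typical
#'   measurement.
#' @param placement_model `"csr"` for complete spatial randomness (uniform on
#'   the droplet disk) or `"edge_ring"` for a coffee-ring-like negative
#'   control whose density concentrates in a Gaussian annulus at the rim.
#' @param aggregate_fraction Fraction of particles flagged as aggregates;
#'   aggregates carry twice the drawn intensity (a two-particle cluster).
#' @param intensity_median Median of the lognormal single-particle intensity
#'   distribution, in integrated camera counts.
#' @param intensity_sigma_log Lognormal shape parameter (sd of log intensity).
#' @param ring_radius_frac,ring_width_frac Centre and width of the edge-ring
#'   annulus as fractions of `droplet_radius` (edge_ring model only).
#' @return An object of class `eva_droplet_spec`.
#' @export
droplet_spec <- function(droplet_radius = 1500,
                         droplet_volume = 2.5,
                         in_droplet_concentration = 4438 / 2.5e-3,
                         placement_model = c("csr", "edge_ring"),
                         aggregate_fraction = 0,
                         intensity_median = 8000,
                         intensity_sigma_log = 0.25,
                         ring_radius_frac = 0.9,
                         ring_width_frac = 0.06) {
  placement_model <- match.arg(placement_model)
  check_positive(droplet_radius, "droplet_radius")
  check_positive(droplet_volume, "droplet_volume")
  if (!is.finite(in_droplet_concentration) || in_droplet_concentration < 0)
    stop_domain("in_droplet_concentration must be finite and non-negative")
  if (aggregate_fraction < 0 || aggregate_fraction > 1)
    stop_domain("aggregate_fraction must lie in [0, 1]")
  check_positive(intensity_median, "intensity_median")
  structure(list(
    droplet_radius = droplet_radius,
    droplet_volume = droplet_volume,
    in_droplet_concentration = in_droplet_concentration,
    placement_model = placement_model,
    aggregate_fraction = aggregate_fraction,
    intensity_median = intensity_median,
    intensity_sigma_log = intensity_sigma_log,
    ring_radius_frac = ring_radius_frac,
    ring_width_frac = ring_width_frac
  ), class = "eva_droplet_spec")
}

#' Optical / camera specification for synthetic micrographs
#'
#' @param tile_px Pixels per tile side.
#' @param pixel_size Micrometres per pixel. The default, 674/1024, makes a
#'   1024 px tile exactly a 674 um field of view.
#' @param step Stage step between adjacent tiles, micrometres. Must be
#'   smaller than the frame so neighbours overlap.
#' @param psf_fwhm_px Full width at half maximum of the diffraction-limited
#'   spot image, in pixels.
#' @param background_offset Constant camera offset, counts.
#' @param read_noise_sd Gaussian read-noise standard deviation, counts.
#' @param shot_noise Apply Poisson shot noise to (signal + offset)?
#' @param distortion_k1,distortion_k2 Radial distortion coefficients (px^-2,
#'   px^-4) applied about the tile centre when rendering; positive k1 is
#'   pincushion.
#' @param stage_jitter_sd Standard deviation of the per-tile stage positioning
#'   error, micrometres.
#' @return An object of class `eva_optics_spec` with the derived `frame_size`
#'   (um) included.
#' @export
optics_spec <- function(tile_px = 1024L,
                        pixel_size = 674 / 1024,
                        step = 500,
                        psf_fwhm_px = 1.8,
                        background_offset = 100,
                        read_noise_sd = 10,
                        shot_noise = TRUE,
                        distortion_k1 = 0,
                        distortion_k2 = 0,
                        stage_jitter_sd = 2) {
  tile_px <- as.integer(tile_px)
  check_positive(tile_px, "tile_px")
  check_positive(pixel_size, "pixel_size")
  check_positive(psf_fwhm_px, "psf_fwhm_px")
  frame_size <- tile_px * pixel_size
  if (step >= frame_size)
    stop_domain("step (", step, " um) must be smaller than the frame (",
                signif(frame_size, 6), " um) so adjacent tiles overlap")
  if (read_noise_sd < 0 || background_offset < 0)
    stop_domain("noise parameters must be non-negative")
  structure(list(
    tile_px = tile_px, pixel_size = pixel_size, frame_size = frame_size,
    step = step, psf_fwhm_px = psf_fwhm_px,
    background_offset = background_offset, read_noise_sd = read_noise_sd,
    shot_noise = isTRUE(shot_noise),
    distortion_k1 = distortion_k1, distortion_k2 = distortion_k2,
    stage_jitter_sd = stage_jitter_sd
  ), class = "eva_optics_spec")
}

#' Generate ground-truth particle positions and intensities for one droplet
#'
#' The particle count is Poisson with mean
#' `in_droplet_concentration * droplet_volume` (mL). Under the `"csr"`
#' placement model positions are independent and uniform on the droplet disk
#' (the pattern the downstream spatial-randomness test should accept); the
#' `"edge_ring"` model concentrates particles in an annulus at the rim and
#' serves as a negative control. Intensities are lognormal; particles flagged
#' as aggregates carry twice the drawn intensity. Fully reproducible from
#' `seed`: count, positions, intensities and aggregate flags are drawn from
#' independent substreams.
#'
#' @param spec An [droplet_spec()] object.
#' @param seed Integer seed.
#' @return An object of class `eva_ground_truth`: list with `positions`
#'   (n x 2 matrix, um, droplet centred at the origin), `intensities`,
#'   `is_aggregate`, `seed`, `spec`.
#' @export
generate_droplet_truth <- function(spec, seed) {
  stopifnot(inherits(spec, "eva_droplet_spec"))
  mean_count <- spec$in_droplet_concentration * spec$droplet_volume * 1e-3
  if (!is.finite(mean_count) || mean_count < 0)
    stop_domain("expected particle count must be finite and non-negative")
  n <- with_substream(seed, "count", rpois(1L, mean_count))
  R <- spec$droplet_radius
  if (n == 0L) {
    pos <- matrix(numeric(0), ncol = 2,
                  dimnames = list(NULL, c("x_um", "y_um")))
    return(structure(list(positions = pos, intensities = numeric(0),
                          is_aggregate = logical(0), seed = seed,
                          spec = spec), class = "eva_ground_truth"))
  }
  pos <- with_substream(seed, "positions", {
    theta <- runif(n, 0, 2 * pi)
    r <- switch(spec$placement_model,
      csr = R * sqrt(runif(n)),
      edge_ring = {
        rr <- rnorm(n, spec$ring_radius_frac * R, spec$ring_width_frac * R)
        # resample draws falling outside the droplet
        bad <- which(rr < 0 | rr > R)
        while (length(bad)) {
          rr[bad] <- rnorm(length(bad), spec$ring_radius_frac * R,
                           spec$ring_width_frac * R)
          bad <- bad[rr[bad] < 0 | rr[bad] > R]
        }
        rr
      })
    cbind(x_um = r * cos(theta), y_um = r * sin(theta))
  })
  intens <- with_substream(seed, "intensities",
    rlnorm(n, log(spec$intensity_median), spec$intensity_sigma_log))
  aggr <- with_substream(seed, "aggregates",
    runif(n) < spec$aggregate_fraction)
  intens[aggr] <- 2 * intens[aggr]
  structure(list(positions = pos, intensities = intens, is_aggregate = aggr,
                 seed = seed, spec = spec), class = "eva_ground_truth")
}

# Nominal stage positions (um) of a rows x cols grid centred on the droplet.
# The stage position is the coordinate of the centre of pixel (0, 0).
nominal_stage_positions <- function(optics, rows, cols) {
  ex <- (cols - 1) * optics$step + optics$frame_size
  ey <- (rows - 1) * optics$step + optics$frame_size
  grid <- expand.grid(row = seq_len(rows), col = seq_len(cols))
  data.frame(
    row = grid$row, col = grid$col,
    x_um = -ex / 2 + optics$pixel_size / 2 + (grid$col - 1) * optics$step,
    y_um = -ey / 2 + optics$pixel_size / 2 + (grid$row - 1) * optics$step)
}

# Forward radial distortion about the tile centre, pixel coordinates.
apply_render_distortion <- function(xp, yp, optics) {
  if (optics$distortion_k1 == 0 && optics$distortion_k2 == 0)
    return(list(x = xp, y = yp))
  c0 <- (optics$tile_px - 1) / 2
  dx <- xp - c0; dy <- yp - c0
  r2 <- dx^2 + dy^2
  f <- 1 + optics$distortion_k1 * r2 + optics$distortion_k2 * r2^2
  list(x = c0 + dx * f, y = c0 + dy * f)
}

#' Render one micrograph tile from ground truth
#'
#' Particles whose positions fall inside the tile's field of view are drawn
#' as integrated symmetric 2-D Gaussians of the configured FWHM, scaled to
#' their intensity; the camera model then adds the constant offset, optional
#' Poisson shot noise, Gaussian read noise, and quantizes to 16 bits with
#' saturation clipping. Radial distortion, if configured, displaces the spots
#' as a real lens would; stitching and counting are expected to undo it.
#'
#' @param truth An [generate_droplet_truth()] result.
#' @param optics An [optics_spec()].
#' @param grid_row,grid_col 1-based grid indices of the tile.
#' @param seed Integer seed for the pixel-noise substream.
#' @param rows,cols Grid shape used to place the tile (defaults 6 x 6).
#' @param stage_position Optional true stage position (um) of pixel (0, 0);
#'   defaults to the nominal grid position (no jitter).
#' @return An object of class `eva_tile`: list with `data` (numeric matrix,
#'   counts, `data[y + 1, x + 1]`), `row`, `col`, `nominal_position`,
#'   `stage_position`, `pixel_size`.
#' @export
render_tile <- function(truth, optics, grid_row, grid_col, seed = 0L,
                        rows = 6L, cols = 6L, stage_position = NULL) {
  stopifnot(inherits(truth, "eva_ground_truth"),
            inherits(optics, "eva_optics_spec"))
  if (grid_row < 1 || grid_row > rows || grid_col < 1 || grid_col > cols)
    stop_domain("grid indices outside the ", rows, " x ", cols, " layout")
  nom <- nominal_stage_positions(optics, rows, cols)
  nom <- nom[nom$row == grid_row & nom$col == grid_col, ]
  nominal <- c(nom$x_um, nom$y_um)
  stage <- stage_position %||% nominal
  sigma <- optics$psf_fwhm_px / FWHM_SIGMA
  n <- optics$tile_px
  signal <- matrix(0, n, n)
  if (nrow(truth$positions)) {
    xp <- (truth$positions[, 1] - stage[1]) / optics$pixel_size
    yp <- (truth$positions[, 2] - stage[2]) / optics$pixel_size
    d <- apply_render_distortion(xp, yp, optics)
    margin <- 6 * sigma
    keep <- d$x > -margin & d$x < n - 1 + margin &
            d$y > -margin & d$y < n - 1 + margin
    if (any(keep))
      signal <- .cpp_add_spots(signal, d$x[keep], d$y[keep],
                               truth$intensities[keep], sigma,
                               as.integer(ceiling(6 * sigma) + 1))
  }
  data <- with_substream(seed, sprintf("noise_r%d_c%d", grid_row, grid_col),
    .cpp_camera_noise(signal, optics$background_offset, optics$shot_noise,
                      optics$read_noise_sd))
  structure(list(data = data, row = grid_row, col = grid_col,
                 nominal_position = nominal, stage_position = stage,
                 pixel_size = optics$pixel_size),
            class = "eva_tile")
}

#' Render a full tile grid covering the droplet
#'
#' Draws one stage-jitter offset per tile, renders every tile, and returns
#' the tiles together with a manifest recording nominal and true (jittered)
#' stage positions. The true positions exist for validation only; analysis
#' code must not read them.
#'
#' @inheritParams render_tile
#' @param rows,cols Grid shape (defaults 6 x 6).
#' @param seed Integer seed; jitter and per-tile pixel noise come from
#'   independent substreams so the same seed with noise disabled yields the
#'   same layout.
#' @return List with `tiles` (list of `eva_tile`) and `manifest` (data frame:
#'   row, col, file, nominal/true positions, pixel size) carrying attributes
#'   `grid`, `seed`, `pixel_size_um` and, if the grid does not cover the
#'   droplet disk, `coverage_warning`.
#' @export
generate_tile_grid <- function(truth, optics, rows = 6L, cols = 6L, seed) {
  stopifnot(rows >= 1, cols >= 1)
  nom <- nominal_stage_positions(optics, rows, cols)
  jit <- with_substream(seed, "jitter",
    matrix(rnorm(2L * nrow(nom), 0, optics$stage_jitter_sd), ncol = 2))
  manifest <- data.frame(
    row = nom$row, col = nom$col,
    file = sprintf("tile_r%d_c%d.tif", nom$row, nom$col),
    nominal_x_um = nom$x_um, nominal_y_um = nom$y_um,
    true_x_um = nom$x_um + jit[, 1], true_y_um = nom$y_um + jit[, 2],
    pixel_size_um = optics$pixel_size)
  tiles <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    tiles[[i]] <- render_tile(
      truth, optics, manifest$row[i], manifest$col[i], seed = seed,
      rows = rows, cols = cols,
      stage_position = c(manifest$true_x_um[i], manifest$true_y_um[i]))
  }
  ex <- (cols - 1) * optics$step + optics$frame_size
  ey <- (rows - 1) * optics$step + optics$frame_size
  attr(manifest, "grid") <- c(rows = rows, cols = cols)
  attr(manifest, "seed") <- seed
  attr(manifest, "pixel_size_um") <- optics$pixel_size
  if (min(ex, ey) / 2 < truth$spec$droplet_radius)
    attr(manifest, "coverage_warning") <- sprintf(
      "grid extent %.0f x %.0f um does not cover the droplet (radius %.0f um)",
      ex, ey, truth$spec$droplet_radius)
  list(tiles = tiles, manifest = manifest)
}
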