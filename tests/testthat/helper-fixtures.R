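# Shared fixtures: all synthetic, generated in code.

FW <- 2 * sqrt(2 * log(2))   # FWHM / sigma for a Gaussian

# Noiseless optics for photometric tests.
quiet_optics <- function(tile_px = 64L, read_noise_sd = 0, ...) {
  optics_spec(tile_px = tile_px, step = 0.5 * tile_px * 674 / 1024,
              shot_noise = FALSE, read_noise_sd = read_noise_sd,
              stage_jitter_sd = 0, ...)
}

# A raw tile matrix holding pixel-integrated Gaussian spots plus offset.
spot_image <- function(n_px, x, y, intensity, fwhm_px = 1.8, offset = 100,
                       read_noise_sd = 0, seed = NULL) {
  sigma <- fwhm_px / FW
  sig <- evacount:::.cpp_add_spots(matrix(0, n_px, n_px), x, y,
                                   rep_len(intensity, length(x)), sigma, 8L)
  if (!is.null(seed)) set.seed(seed)
  evacount:::.cpp_camera_noise(sig, offset, FALSE, read_noise_sd)
}

# Small droplet spec with a target expected count.
small_droplet <- function(mean_count, radius = 300, ...) {
  droplet_spec(droplet_radius = radius, droplet_volume = 2.5,
               in_droplet_concentration = mean_count / 2.5e-3, ...)
}

# Greedy matching of detections to ground truth within a radius; returns the
# number of matched truth points.
greedy_match <- function(truth_xy, det_xy, radius) {
  if (!NROW(det_xy) || !NROW(truth_xy)) return(0L)
  used <- rep(FALSE, NROW(det_xy))
  m <- 0L
  for (i in seq_len(NROW(truth_xy))) {
    d2 <- (det_xy[, 1] - truth_xy[i, 1])^2 + (det_xy[, 2] - truth_xy[i, 2])^2
    d2[used] <- Inf
    j <- which.min(d2)
    if (d2[j] <= radius^2) { used[j] <- TRUE; m <- m + 1L }
  }
  m
}

# Brute-force O(n^2) nearest-neighbour oracle.
nn_oracle <- function(p) {
  dm <- as.matrix(dist(p))
  diag(dm) <- Inf
  unname(apply(dm, 1, min))
}
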