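#' Study design for synthetic end-to-end validation
#'
#' The reduced-scale counting study used for self-validation: seven droplets
#' at a known stock concentration, each dried deposit imaged in a single
#' frame, analysed by the full detection pipeline and quantified with the
#' standard uncertainty budget. The uncertainty composition mirrors a
#' typical absolute-counting measurement: a shared volume-calibration
#' component of 2.5%, a dilution component of 0.65%, and a counting
#' component from the between-droplet scatter (about 400 particles per
#' droplet). The particle surface density is kept low enough
#' (about 4e-4 px^-2) that spot-merge undercounting stays well below the
#' counting noise.
#'
#' @param concentration_per_ml True stock number concentration.
#' @param n_droplets Droplets per measurement.
#' @param droplet_volume_ul Nominal droplet volume.
#' @param u_volume_rel,u_dilution_rel Relative standard uncertainties of the
#'   (shared) volume calibration and dilution.
#' @param dilution_factor Fold-dilution of the stock before deposition.
#' @param droplet_radius_um Radius of the dried deposit.
#' @param tile_px Frame side in pixels (single-frame imaging).
#' @return A list of class `eva_study_design`.
#' @export
study_design <- function(concentration_per_ml = 1.6e5,
                         n_droplets = 7L,
                         droplet_volume_ul = 2.5,
                         u_volume_rel = 0.025,
                         u_dilution_rel = 0.0065,
                         dilution_factor = 1,
                         droplet_radius_um = 371,
                         tile_px = 1160L) {
  optics <- optics_spec(tile_px = tile_px, step = 0.7 * tile_px * 674 / 1024,
                        shot_noise = FALSE, stage_jitter_sd = 0)
  structure(list(concentration_per_ml = concentration_per_ml,
                 n_droplets = as.integer(n_droplets),
                 droplet_volume_ul = droplet_volume_ul,
                 u_volume_rel = u_volume_rel,
                 u_dilution_rel = u_dilution_rel,
                 dilution_factor = dilution_factor,
                 droplet_radius_um = droplet_radius_um,
                 optics = optics), class = "eva_study_design")
}

#' Simulate one complete counting measurement
#'
#' Draws the shared volume and dilution errors, generates and images
#' `n_droplets` droplets, detects and counts the spots in each, and runs the
#' concentration estimator with the nominal descriptor. The analyst never
#' sees the true errors - only the nominal volumes and the stated
#' uncertainties - so the result tests whether the reported interval covers
#' the true concentration at its stated level.
#'
#' @param design An [study_design()].
#' @param seed Integer seed.
#' @param detector An [detector_params()].
#' @return List: `estimate` (an `eva_concentration`), `counts`,
#'   `true_concentration`, `covered` (true value inside the interval).
#' @export
simulate_measurement <- function(design = study_design(), seed,
                                 detector = detector_params()) {
  stopifnot(inherits(design, "eva_study_design"))
  err <- with_substream(seed, "calibration", {
    c(dv = rnorm(1, 0, design$u_volume_rel),
      dd = rnorm(1, 0, design$u_dilution_rel))
  })
  v_true_ml <- design$droplet_volume_ul * 1e-3 * (1 + err[["dv"]])
  d_true <- design$dilution_factor * (1 + err[["dd"]])
  counts <- integer(design$n_droplets)
  for (i in seq_len(design$n_droplets)) {
    dseed <- substream_seed(seed, paste0("droplet", i))
    spec <- droplet_spec(
      droplet_radius = design$droplet_radius_um,
      droplet_volume = v_true_ml * 1e3,
      in_droplet_concentration = design$concentration_per_ml / d_true,
      intensity_median = 8000, intensity_sigma_log = 0.25)
    truth <- generate_droplet_truth(spec, dseed)
    tile <- render_tile(truth, design$optics, 1L, 1L, seed = dseed,
                        rows = 1L, cols = 1L)
    counts[i] <- nrow(detect_spots(tile, detector))
  }
  sample <- sample_descriptor(
    rep(design$droplet_volume_ul, design$n_droplets),
    u_volume_rel = design$u_volume_rel,
    dilution_factor = design$dilution_factor,
    u_dilution_rel = design$u_dilution_rel)
  est <- concentration_estimate(counts, sample)
  covered <- design$concentration_per_ml >= est$coverage_interval["low"] &&
             design$concentration_per_ml <= est$coverage_interval["high"]
  list(estimate = est, counts = counts,
       true_concentration = design$concentration_per_ml, covered = covered)
}

#' Coverage calibration of the uncertainty budget
#'
#' Repeats [simulate_measurement()] and reports the fraction of repetitions
#' in which the true concentration lies inside the reported 95% coverage
#' interval - the end-to-end calibration check of the whole pipeline.
#'
#' @param n_reps Number of simulated measurements.
#' @param seed Base seed; repetition r uses substream `rep{r}`.
#' @param design An [study_design()].
#' @return List: `coverage` (fraction covered), `n_reps`, `rel_error`
#'   (signed relative error of each estimate), `mean_u_rel`.
#' @export
simulate_recovery_study <- function(n_reps = 500L, seed = 1L,
                                    design = study_design()) {
  covered <- logical(n_reps)
  rel_err <- numeric(n_reps)
  u_rel <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    m <- simulate_measurement(design, substream_seed(seed, paste0("rep", r)))
    covered[r] <- m$covered
    rel_err[r] <- m$estimate$c_mean / m$true_concentration - 1
    u_rel[r] <- m$estimate$u_rel_combined
  }
  list(coverage = mean(covered), n_reps = n_reps, rel_error = rel_err,
       mean_u_rel = mean(u_rel))
}

#' Simulate a dilution series measured by absolute counting
#'
#' For each mass concentration, particles are counted in `n_droplets`
#' Poisson-sampled droplets and converted to a number concentration; the
#' series is then fitted through the origin. The mass-to-number conversion
#' uses `particles_per_ng` so the true relationship is exactly proportional.
#'
#' @param mass_conc_ng_ml Mass concentrations, ng/mL.
#' @param particles_per_ng True number of particles per ng.
#' @param n_droplets Droplets per concentration.
#' @param droplet_volume_ul Droplet volume.
#' @param extra_rel_noise Additional multiplicative noise per measurement
#'   (volume/dilution scatter between preparations).
#' @param seed Integer seed.
#' @return List: `data` (x, y), `fit` (an `eva_dilution_fit`),
#'   `true_slope`.
#' @export
simulate_dilution_series <- function(mass_conc_ng_ml = 10^seq(-0.5, 2.5,
                                                              length.out = 8),
                                     particles_per_ng = 1.68e6,
                                     n_droplets = 2L,
                                     droplet_volume_ul = 2.5,
                                     extra_rel_noise = 0.02,
                                     seed = 1L) {
  v_ml <- n_droplets * droplet_volume_ul * 1e-3
  y <- with_substream(seed, "dilution_series", {
    vapply(mass_conc_ng_ml, function(x) {
      lambda <- x * particles_per_ng * v_ml
      n <- rpois(1, lambda * exp(rnorm(1, 0, extra_rel_noise)))
      n / v_ml
    }, 0)
  })
  fit <- fit_dilution_series(mass_conc_ng_ml, y)
  list(data = data.frame(mass_ng_ml = mass_conc_ng_ml, number_per_ml = y),
       fit = fit, true_slope = particles_per_ng)
}
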