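#' Sample descriptor: droplet volumes and dilution with uncertainties
#'
#' @param droplet_volumes_ul Deposited volume of each analysed droplet,
#'   microlitres.
#' @param u_volume_rel Relative standard uncertainty of the total analysed
#'   volume (a shared calibration component).
#' @param dilution_factor Fold-dilution D >= 1 of the stock before
#'   deposition; the estimated concentration is scaled back by D.
#' @param u_dilution_rel Relative standard uncertainty of D.
#' @return Object of class `eva_sample`.
#' @export
sample_descriptor <- function(droplet_volumes_ul, u_volume_rel = 0.025,
                              dilution_factor = 1, u_dilution_rel = 0) {
  check_positive(droplet_volumes_ul, "droplet volumes")
  if (dilution_factor < 1) stop_domain("dilution_factor must be >= 1")
  if (u_volume_rel < 0 || u_dilution_rel < 0)
    stop_domain("uncertainties must be >= 0")
  structure(list(droplet_volumes_ul = droplet_volumes_ul,
                 u_volume_rel = u_volume_rel,
                 dilution_factor = dilution_factor,
                 u_dilution_rel = u_dilution_rel),
            class = "eva_sample")
}

#' Number concentration with a full uncertainty budget
#'
#' The absolute-counting estimator `C = sum(N) * D / sum(V)` (V in mL). The
#' counting relative uncertainty is the between-droplet scatter
#' `sd(N) / (mean(N) sqrt(n))` when at least three droplets were counted,
#' otherwise the Poisson bound `sqrt(sum N) / sum N`. Counting, volume and
#' dilution components combine in quadrature; the coverage interval is
#' `C (1 +/- k u)` with `k = 1.96` (normal 95%).
#'
#' @param counts Integer particle counts, one per droplet.
#' @param sample An [sample_descriptor()].
#' @param k Coverage factor.
#' @return Object of class `eva_concentration`: `c_mean` (per mL),
#'   `u_rel_combined`, `u_components` (counting, volume, dilution),
#'   `coverage_interval`, `k`, `n_droplets`, `counts_per_droplet`,
#'   `all_zero` flag (zero counts give a one-sided upper bound at the
#'   Poisson 95% limit).
#' @export
concentration_estimate <- function(counts, sample, k = 1.96) {
  stopifnot(inherits(sample, "eva_sample"))
  if (!length(counts)) stop_domain("need at least one droplet count")
  if (any(counts < 0) || any(counts != round(counts)))
    stop_domain("counts must be non-negative integers")
  n <- length(counts)
  total <- sum(counts)
  v_ml <- sum(sample$droplet_volumes_ul) * 1e-3
  D <- sample$dilution_factor
  if (total == 0) {
    upper <- -log(0.05) * D / v_ml   # one-sided Poisson 95% bound
    return(structure(list(
      c_mean = 0, u_rel_combined = NA_real_,
      u_components = c(counting = NA_real_, volume = sample$u_volume_rel,
                       dilution = sample$u_dilution_rel),
      coverage_interval = c(low = 0, high = upper), k = k,
      n_droplets = n, counts_per_droplet = counts, all_zero = TRUE),
      class = "eva_concentration"))
  }
  c_mean <- total * D / v_ml
  u_count <- if (n >= 3) sd(counts) / (mean(counts) * sqrt(n))
             else sqrt(total) / total
  u <- sqrt(u_count^2 + sample$u_volume_rel^2 + sample$u_dilution_rel^2)
  structure(list(
    c_mean = c_mean, u_rel_combined = u,
    u_components = c(counting = u_count, volume = sample$u_volume_rel,
                     dilution = sample$u_dilution_rel),
    coverage_interval = coverage_interval(c_mean, u, k), k = k,
    n_droplets = n, counts_per_droplet = counts, all_zero = FALSE),
    class = "eva_concentration")
}

#' Symmetric coverage interval
#'
#' `c_mean * (1 -/+ k * u_rel)`, optionally rounded to a number of
#' significant figures for reporting.
#'
#' @param c_mean Mean value.
#' @param u_rel Relative standard uncertainty (>= 0).
#' @param k Coverage factor (1.96 for normal 95%).
#' @param signif_digits Optional significant figures for reporting.
#' @return Named numeric `c(low, high)`.
#' @export
coverage_interval <- function(c_mean, u_rel, k = 1.96, signif_digits = NULL) {
  if (u_rel < 0) stop_domain("u_rel must be >= 0")
  out <- c(low = c_mean * (1 - k * u_rel), high = c_mean * (1 + k * u_rel))
  if (!is.null(signif_digits)) out <- signif(out, signif_digits)
  out
}

#' Theoretical detection and quantification limits of absolute counting
#'
#' The limit of detection is the concentration at which at least one
#' particle appears in the overall evaporated volume with the stated
#' probability; from the Poisson law the required mean is
#' `lambda_LOD = -ln(1 - confidence)` (4.6 particles at 99%). The limit of
#' quantification is the mean at which the Poisson counting noise equals
#' `noise_target`: `N_LOQ = 1 / noise_target^2` (100 particles at 10%).
#' Counts convert to concentrations as `count * D / total_volume`.
#'
#' @param total_volume_ml Overall evaporated (analysed) volume, mL.
#' @param dilution Fold-dilution D.
#' @param confidence Detection probability (in (0, 1)).
#' @param noise_target Relative Poisson noise defining the LOQ.
#' @return Object of class `eva_limits`: `lod_count`, `loq_count`,
#'   `lod_conc`, `loq_conc` (per mL of stock).
#' @export
detection_limits <- function(total_volume_ml, dilution = 1,
                             confidence = 0.99, noise_target = 0.10) {
  check_positive(total_volume_ml, "total_volume_ml")
  if (confidence <= 0 || confidence >= 1)
    stop_domain("confidence must be in (0, 1)")
  check_positive(noise_target, "noise_target")
  lod <- -log(1 - confidence)
  loq <- 1 / noise_target^2
  structure(list(lod_count = lod, loq_count = loq,
                 lod_conc = lod * dilution / total_volume_ml,
                 loq_conc = loq * dilution / total_volume_ml,
                 confidence = confidence, noise_target = noise_target,
                 total_volume_ml = total_volume_ml, dilution = dilution),
            class = "eva_limits")
}

#' Optimal working range of the counting assay
#'
#' The lower bound keeps the Poisson counting noise at or below `u_target`:
#' at least `1 / u_target^2` particles in the overall analysed volume. The
#' upper bound limits the undercount from spot overlaps: a particle pair
#' closer than `r_min` merges into one detected spot, losing one of its two
#' members, so the expected undercount fraction is
#' `0.5 (1 - exp(-rho pi r_min^2))` at deposited surface density rho. The
#' largest admissible density solves undercount = `u_target` in closed form:
#' `rho_max = -ln(1 - 2 u_target) / (pi r_min^2)`.
#'
#' @param u_target Target relative uncertainty (in (0, 0.5)).
#' @param total_volume_ml Overall analysed volume, mL.
#' @param droplet_area_um2 Deposit area of one droplet, um^2.
#' @param droplets_per_run Number of droplets composing the total volume.
#' @param r_min_um Merge distance of two spots, micrometres (the spot FWHM
#'   scale).
#' @param dilution Fold-dilution D.
#' @return Named numeric `c(c_min, c_max)` (per mL of stock), with
#'   attributes `n_min` (minimum total count) and `rho_max_um2`.
#' @export
working_range <- function(u_target, total_volume_ml,
                          droplet_area_um2 = pi * 1500^2,
                          droplets_per_run = 7, r_min_um = 1.2,
                          dilution = 1) {
  check_positive(c(u_target, total_volume_ml, droplet_area_um2,
                   droplets_per_run, r_min_um), "working_range inputs")
  if (2 * u_target >= 1) stop_domain("u_target must be below 0.5")
  n_min <- 1 / u_target^2
  c_min <- n_min * dilution / total_volume_ml
  rho_max <- -log(1 - 2 * u_target) / (pi * r_min_um^2)
  v_droplet_ml <- total_volume_ml / droplets_per_run
  n_max_per_droplet <- rho_max * droplet_area_um2
  c_max <- n_max_per_droplet * dilution / v_droplet_ml
  out <- c(c_min = c_min, c_max = c_max)
  attr(out, "n_min") <- n_min
  attr(out, "rho_max_um2") <- rho_max
  out
}

#' Proportional (zero-intercept) fit of a dilution series
#'
#' Least-squares fit of `y = k x` with constant relative variance (weights
#' `1 / x^2`, i.e. `k = mean(y / x)`) - the error structure of a series
#' spanning decades, and the weighting a zero-intercept fit on the log-log
#' scale implies. `R^2 = 1 - SS_res / SS_tot` is reported on the linear
#' scale (SS_tot about the mean of y), and per-point relative deviations
#' are `(y - kx) / kx`. Points deviating below `-3 u_expected` are flagged
#' as overlap-suppressed (outside the linear range).
#'
#' @param x Mass concentrations (all > 0, length >= 3).
#' @param y Estimated number concentrations (all > 0).
#' @param u_expected Expected relative scatter of a point.
#' @return Object of class `eva_dilution_fit`: `slope`, `r_squared`,
#'   `rel_deviation`, `out_of_range` flags.
#' @export
fit_dilution_series <- function(x, y, u_expected = 0.025) {
  if (length(x) != length(y)) stop_domain("x and y differ in length")
  if (length(x) < 3) stop_domain("need at least 3 points")
  if (any(x <= 0) || any(y <= 0) || any(!is.finite(c(x, y))))
    stop_domain("all concentrations must be positive and finite")
  k <- mean(y / x)
  ss_res <- sum((y - k * x)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- 1 - ss_res / ss_tot
  dev <- (y - k * x) / (k * x)
  structure(list(slope = k, r_squared = r2, rel_deviation = dev,
                 out_of_range = dev < -3 * u_expected,
                 u_expected = u_expected, n = length(x)),
            class = "eva_dilution_fit")
}

#' Gravimetric / single-particle-mass reference concentration
#'
#' `C = mass_concentration / particle_mass`, with 1 mg = 1e15 ag.
#'
#' @param mass_concentration_mg_ml Stock mass concentration, mg/mL.
#' @param particle_mass_ag Average single-particle mass, attograms.
#' @return Number concentration, per mL.
#' @export
gravimetric_reference <- function(mass_concentration_mg_ml,
                                  particle_mass_ag) {
  check_positive(mass_concentration_mg_ml, "mass_concentration_mg_ml")
  check_positive(particle_mass_ag, "particle_mass_ag")
  mass_concentration_mg_ml * 1e15 / particle_mass_ag
}

#' Average nanoparticle mass from geometry and densities
#'
#' Core-shell particle: core volume times core density plus shell-shell
#' volume times shell density. `sphere`: core radius `d/2`, shell a uniform
#' `t`-thick layer. `hex_prism`: regular hexagonal prism with across-vertex
#' diameter `d` (edge `a = d/2`), height `h = d`, volume
#' `(3 sqrt(3) / 2) a^2 h`; the shell offsets the edge by `t` and each face
#' by `t`.
#'
#' @param core_diameter_nm Core diameter (across vertices for the prism), nm.
#' @param shell_thickness_nm Uniform shell thickness, nm.
#' @param core_density,shell_density Densities, g/cm^3.
#' @param shape `"sphere"` or `"hex_prism"`.
#' @return Mass in attograms (1 nm^3 * 1 g/cm^3 = 1e-3 ag).
#' @export
particle_mass <- function(core_diameter_nm, shell_thickness_nm = 0,
                          core_density, shell_density = 0,
                          shape = c("sphere", "hex_prism")) {
  shape <- match.arg(shape)
  check_positive(core_diameter_nm, "core_diameter_nm")
  check_positive(core_density, "core_density")
  if (shell_thickness_nm < 0) stop_domain("shell thickness must be >= 0")
  vol <- switch(shape,
    sphere = function(d) 4 / 3 * pi * (d / 2)^3,
    hex_prism = function(d) {
      a <- d / 2
      3 * sqrt(3) / 2 * a^2 * d
    })
  v_core <- vol(core_diameter_nm)
  v_outer <- switch(shape,
    sphere = vol(core_diameter_nm + 2 * shell_thickness_nm),
    hex_prism = {
      a <- core_diameter_nm / 2 + shell_thickness_nm
      h <- core_diameter_nm + 2 * shell_thickness_nm
      3 * sqrt(3) / 2 * a^2 * h
    })
  (v_core * core_density + (v_outer - v_core) * shell_density) * 1e-3
}

#' Relative deviation of a reference method from the counting estimate
#'
#' `100 (c_reference - c_eva) / c_eva`, reported to the nearest percent.
#'
#' @param c_reference Reference concentration.
#' @param c_eva Counting (EVA) concentration (> 0).
#' @return Percent deviation, rounded to the nearest integer.
#' @export
method_deviation <- function(c_reference, c_eva) {
  check_positive(c_eva, "c_eva")
  round(100 * (c_reference - c_eva) / c_eva)
}
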