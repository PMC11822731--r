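#' Nearest-neighbour distances of a 2-D point pattern
#'
#' For each point, the Euclidean distance to the closest other point.
#' Computed with a uniform-grid spatial index whose result is exactly the
#' brute-force all-pairs answer.
#'
#' @param points n x 2 matrix (n >= 2) of coordinates, micrometres.
#' @return Numeric vector of length n.
#' @export
nearest_neighbor_distances <- function(points) {
  p <- as.matrix(points)
  if (nrow(p) < 2) stop_domain("need at least 2 points")
  if (any(!is.finite(p))) stop_domain("non-finite coordinates")
  .cpp_nn_distances(p[, 1], p[, 2])
}

#' Nearest-neighbour distance CDF under complete spatial randomness
#'
#' For a homogeneous Poisson point process of intensity `density_rho` in the
#' plane, the distance from a point to its nearest neighbour has CDF
#' `F(r) = 1 - exp(-rho * pi * r^2)`.
#'
#' @param r Distance(s), micrometres (>= 0).
#' @param density_rho Point density, per square micrometre (> 0).
#' @return Probability vector.
#' @export
csr_cdf <- function(r, density_rho) {
  if (any(r < 0)) stop_domain("r must be non-negative")
  check_positive(density_rho, "density_rho")
  1 - exp(-density_rho * pi * r^2)
}

#' Test a point pattern against complete spatial randomness
#'
#' Estimates the density `rho = n / area`, compares the empirical
#' nearest-neighbour distance CDF with the CSR model
#' `1 - exp(-rho pi r^2)` via the Kolmogorov-Smirnov statistic, and obtains
#' the p-value by parametric bootstrap (the classical KS tables do not apply
#' because rho is estimated from the same data): CSR patterns of the same
#' size are resimulated on a disk of equal area and analysed identically.
#'
#' By default the area is that of the convex hull of the points; passing
#' `droplet_radius` uses the fixed droplet disk instead. Points within
#' `edge_buffer_um` of the disk boundary are excluded from the empirical CDF
#' but remain available as neighbours (only meaningful with
#' `droplet_radius`).
#'
#' @param points n x 2 matrix of positions, micrometres (n >= 50).
#' @param area_um2 Optional observation-window area; overrides the hull.
#' @param droplet_radius Optional disk radius (um) defining the window.
#' @param edge_buffer_um Guard buffer at the disk boundary (default 0).
#' @param n_boot Bootstrap replicates for the p-value.
#' @param seed Optional seed for the bootstrap substream.
#' @return Object of class `eva_csr_fit`: `density_rho` (per um^2),
#'   `ks_statistic`, `ks_pvalue`, `n_points`, `area_um2`, `edge_buffer_um`,
#'   and the empirical-vs-model CDF table `cdf` (r, F_emp, F_theory).
#' @export
fit_csr <- function(points, area_um2 = NULL, droplet_radius = NULL,
                    edge_buffer_um = 0, n_boot = 500L, seed = NULL) {
  p <- as.matrix(points)
  n <- nrow(p)
  if (n < 50) stop_domain("need at least 50 points for a meaningful test")
  use_hull <- is.null(area_um2) && is.null(droplet_radius)
  area <- area_um2 %||% (if (is.null(droplet_radius)) NULL
                         else pi * droplet_radius^2)
  if (use_hull) area <- hull_area(p)
  if (!is.numeric(area) || area <= 0) stop_domain("area must be positive")
  stat <- csr_ks_stat(p, area, droplet_radius, edge_buffer_um)
  boot_radius <- if (is.null(droplet_radius)) sqrt(area / pi) else
    droplet_radius
  boot <- with_substream(seed, "csr_bootstrap", {
    vapply(seq_len(n_boot), function(b) {
      theta <- runif(n, 0, 2 * pi)
      r <- boot_radius * sqrt(runif(n))
      q <- cbind(r * cos(theta), r * sin(theta))
      a <- if (use_hull) hull_area(q) else area
      csr_ks_stat(q, a, droplet_radius, edge_buffer_um)$stat
    }, 0)
  })
  pval <- (1 + sum(boot >= stat$stat)) / (1 + n_boot)
  structure(list(density_rho = stat$rho, ks_statistic = stat$stat,
                 ks_pvalue = pval, n_points = n, area_um2 = area,
                 edge_buffer_um = edge_buffer_um, cdf = stat$cdf),
            class = "eva_csr_fit")
}

hull_area <- function(p) {
  h <- chull(p)
  x <- p[h, 1]; y <- p[h, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

csr_ks_stat <- function(p, area, droplet_radius, edge_buffer_um) {
  n <- nrow(p)
  rho <- n / area
  d <- nearest_neighbor_distances(p)
  if (!is.null(droplet_radius) && edge_buffer_um > 0) {
    rad <- sqrt(rowSums(p^2))
    d <- d[rad <= droplet_radius - edge_buffer_um]
    if (length(d) < 10) stop_domain("edge buffer removed nearly all points")
  }
  ds <- sort(d)
  theor <- csr_cdf(ds, rho)
  list(stat = ks_statistic(theor), rho = rho,
       cdf = data.frame(r = ds, F_emp = seq_along(ds) / length(ds),
                        F_theory = theor))
}
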