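#' Radial distortion model
#'
#' Two-coefficient radial model about a centre `(cx, cy)`:
#' `r_obs = r_ideal * (1 + k1 * r_ideal^2 + k2 * r_ideal^4)`. With
#' `k1 = k2 = 0` the model is the identity. Positive `k1` is pincushion
#' (magnification grows with field radius).
#'
#' @param center Length-2 numeric, distortion centre in pixels.
#' @param k1,k2 Radial coefficients (px^-2, px^-4).
#' @param residual_rms_px Fit residual RMS recorded by
#'   [fit_radial_distortion()].
#' @return Object of class `eva_distortion`.
#' @export
distortion_model <- function(center = c(0, 0), k1 = 0, k2 = 0,
                             residual_rms_px = NA_real_) {
  stopifnot(length(center) == 2, is.finite(k1), is.finite(k2))
  structure(list(center = as.numeric(center), k1 = k1, k2 = k2,
                 residual_rms_px = residual_rms_px),
            class = "eva_distortion")
}

#' Fit the radial distortion from point correspondences
#'
#' Least-squares fit of the forward model
#' `observed = center + d * (1 + k1 |d|^2 + k2 |d|^4)`, `d = nominal - center`,
#' with the centre fitted jointly with the coefficients
#' (Levenberg-Marquardt via [minpack.lm::nls.lm]).
#'
#' @param observed_points,nominal_points n x 2 matrices of pixel coordinates
#'   (n >= 12, not collinear, spanning more than one radius).
#' @param center_init Optional starting centre; defaults to the nominal
#'   centroid.
#' @return An `eva_distortion` with the residual RMS of the fit.
#' @export
fit_radial_distortion <- function(observed_points, nominal_points,
                                  center_init = NULL) {
  obs <- as.matrix(observed_points)
  nom <- as.matrix(nominal_points)
  if (nrow(obs) != nrow(nom)) stop_domain("point sets differ in length")
  if (nrow(obs) < 12) stop_domain("need at least 12 point correspondences")
  sv <- svd(scale(nom, scale = FALSE))$d
  if (sv[2] < 1e-8 * sv[1]) stop_domain("nominal points are collinear")
  ctr0 <- center_init %||% colMeans(nom)
  radii <- sqrt(rowSums(sweep(nom, 2, ctr0)^2))
  if (diff(range(radii)) < 1e-6 * max(radii, 1))
    stop_domain("ill-conditioned fit: all points at a single radius")
  resid_fun <- function(p) {
    d <- sweep(nom, 2, p[1:2])
    r2 <- rowSums(d^2)
    f <- 1 + p[3] * r2 + p[4] * r2^2
    pred <- sweep(d * f, 2, p[1:2], "+")
    as.vector(pred - obs)
  }
  fit <- minpack.lm::nls.lm(par = c(ctr0, 0, 0), fn = resid_fun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-14, ptol = 1e-14))
  p <- fit$par
  rms <- sqrt(mean(matrix(resid_fun(p), ncol = 2)^2) * 2)
  distortion_model(center = p[1:2], k1 = p[3], k2 = p[4],
                   residual_rms_px = rms)
}

#' Apply the forward (distorting) radial mapping to points
#'
#' @param points n x 2 matrix of ideal pixel coordinates.
#' @param model An `eva_distortion`.
#' @return n x 2 matrix of distorted coordinates.
#' @export
distort_points <- function(points, model) {
  stopifnot(inherits(model, "eva_distortion"))
  p <- as.matrix(points)
  if (!nrow(p)) return(p)
  d <- sweep(p, 2, model$center)
  r2 <- rowSums(d^2)
  f <- 1 + model$k1 * r2 + model$k2 * r2^2
  sweep(d * f, 2, model$center, "+")
}

#' Invert the radial mapping (undistort points)
#'
#' Fixed-point inversion of the radial polynomial: iterate
#' `r_ideal <- r_obs / (1 + k1 r_ideal^2 + k2 r_ideal^4)` from
#' `r_ideal = r_obs`. Converges in a few iterations for the small distortions
#' this model targets; failure to converge within `max_iter` raises an error
#' naming the first offending point.
#'
#' @param points n x 2 matrix of observed (distorted) pixel coordinates.
#' @param model An `eva_distortion`.
#' @param max_iter,tol Iteration cap and radial convergence tolerance (px).
#' @return n x 2 matrix of undistorted coordinates.
#' @export
undistort_points <- function(points, model, max_iter = 50L, tol = 1e-8) {
  stopifnot(inherits(model, "eva_distortion"))
  p <- as.matrix(points)
  if (!nrow(p)) return(p)
  if (model$k1 == 0 && model$k2 == 0) return(p)
  d <- sweep(p, 2, model$center)
  r_obs <- sqrt(rowSums(d^2))
  r <- r_obs
  converged <- r_obs == 0
  for (it in seq_len(max_iter)) {
    f <- 1 + model$k1 * r^2 + model$k2 * r^4
    r_new <- r_obs / f
    converged <- converged | abs(r_new - r) <= tol
    r <- r_new
    if (all(converged)) break
  }
  if (!all(converged)) {
    bad <- which(!converged)[1]
    stop("undistort_points did not converge for point ", bad,
         " at (", p[bad, 1], ", ", p[bad, 2], ")")
  }
  scale_f <- ifelse(r_obs > 0, r / r_obs, 1)
  sweep(d * scale_f, 2, model$center, "+")
}

#' Correct a tile image for radial distortion
#'
#' Inverse-mapped resampling: each output (ideal) pixel looks up its source
#' at the forward-distorted position and bilinearly interpolates the input.
#' Pixels whose source falls outside the input are set to the robust
#' background estimate (median). Dimensions are preserved.
#'
#' @param tile An `eva_tile` or plain numeric matrix.
#' @param model An `eva_distortion`; its centre defaults to the tile centre
#'   when `NA`.
#' @return Same type as the input with corrected pixel data.
#' @export
undistort_image <- function(tile, model) {
  stopifnot(inherits(model, "eva_distortion"))
  img <- tile_data(tile)
  if (model$k1 == 0 && model$k2 == 0) return(tile)
  nr <- nrow(img); nc <- ncol(img)
  # output pixel grid (0-based, x = col, y = row)
  xy <- cbind(x = rep(0:(nc - 1), each = nr), y = rep(0:(nr - 1), nc))
  src <- distort_points(xy, model)
  sx <- src[, 1]; sy <- src[, 2]
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  inside <- x0 >= 0 & x0 <= nc - 2 & y0 >= 0 & y0 <= nr - 2
  bg <- median(img)
  out <- rep(bg, nr * nc)
  i0 <- y0[inside] + 1; j0 <- x0[inside] + 1
  v00 <- img[cbind(i0, j0)];     v01 <- img[cbind(i0, j0 + 1)]
  v10 <- img[cbind(i0 + 1, j0)]; v11 <- img[cbind(i0 + 1, j0 + 1)]
  wfx <- fx[inside]; wfy <- fy[inside]
  out[inside] <- (1 - wfy) * ((1 - wfx) * v00 + wfx * v01) +
                 wfy * ((1 - wfx) * v10 + wfx * v11)
  res <- matrix(out, nr, nc)  # filled column-major: x varies with `each = nr`
  # xy was built with x varying slowly (each = nr), i.e. column-major layout
  if (is_eva_tile(tile)) { tile$data <- res; tile } else res
}

#' Serialize / read a distortion model as JSON
#'
#' @param model An `eva_distortion`.
#' @param path File path.
#' @return `write_distortion_model` returns `path` invisibly;
#'   `read_distortion_model` returns the model.
#' @export
write_distortion_model <- function(model, path) {
  stopifnot(inherits(model, "eva_distortion"))
  jsonlite::write_json(list(center_x = model$center[1],
                            center_y = model$center[2],
                            k1 = model$k1, k2 = model$k2,
                            residual_rms_px = model$residual_rms_px),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_distortion_model
#' @export
read_distortion_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  distortion_model(center = c(j$center_x, j$center_y), k1 = j$k1, k2 = j$k2,
                   residual_rms_px = j$residual_rms_px %||% NA_real_)
}
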