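#' Detection parameters for the classical spot detector
#'
#' @param expected_fwhm_px Expected spot FWHM in pixels; sets the matched
#'   filter width and the Gaussian-fit initialisation.
#' @param threshold_k Detection threshold in units of the background noise
#'   standard deviation (propagated through the matched filter).
#' @param min_separation_px Non-maximum-suppression radius in pixels.
#' @param fit_window_px Side of the square fitting window (odd).
#' @return Object of class `eva_detector_params`.
#' @export
detector_params <- function(expected_fwhm_px = 1.8, threshold_k = 5,
                            min_separation_px = 2L, fit_window_px = 7L) {
  check_positive(threshold_k, "threshold_k")
  check_positive(expected_fwhm_px, "expected_fwhm_px")
  fit_window_px <- as.integer(fit_window_px)
  if (fit_window_px %% 2L != 1L) stop_domain("fit_window_px must be odd")
  structure(list(expected_fwhm_px = expected_fwhm_px,
                 threshold_k = threshold_k,
                 min_separation_px = as.integer(min_separation_px),
                 fit_window_px = fit_window_px),
            class = "eva_detector_params")
}

# Robust background level and noise SD (median / MAD); estimated on a regular
# subsample for large tiles - spots occupy a small pixel fraction so the
# subsample is equally robust.
estimate_background <- function(img, max_px = 65536L) {
  v <- as.vector(img)
  if (length(v) > max_px) v <- v[seq(1L, length(v), length.out = max_px)]
  c(level = median(v), sd = mad(v))
}

#' Detect diffraction-limited spots in a tile
#'
#' Classical matched-filter pipeline: robust background estimate
#' (median + MAD), correlation with a unit-sum Gaussian kernel of sigma =
#' `expected_fwhm_px` / 2.3548, local maxima above
#' `background + threshold_k * noise` (noise SD propagated through the
#' filter), non-maximum suppression at `min_separation_px`, then subpixel
#' refinement of every candidate with the [fit_spot()] Gaussian model
#' (batched). Candidates whose fit fails fall back to a centre-of-mass /
#' aperture-sum estimate and are flagged in `fit_converged`.
#'
#' @param tile An `eva_tile` or numeric matrix.
#' @param params An [detector_params()].
#' @return A detection data frame (one row per spot): `tile_row`, `tile_col`,
#'   `x_px`, `y_px` (0-based subpixel), `x_um`, `y_um` (NA until
#'   [to_global()]), `intensity` (background-subtracted integrated counts),
#'   `fwhm_px`, `snr`, `is_aggregate`, `fit_converged`. If >= 1% of pixels
#'   are saturated the attribute `saturation_warning` is set.
#' @export
detect_spots <- function(tile, params = detector_params()) {
  img <- tile_data(tile)
  stopifnot(is.matrix(img), all(is.finite(img)))
  row <- if (is_eva_tile(tile)) tile$row else NA_integer_
  col <- if (is_eva_tile(tile)) tile$col else NA_integer_
  sigma <- params$expected_fwhm_px / FWHM_SIGMA
  bg <- estimate_background(img)
  kern <- gaussian_kernel(sigma)
  filt <- .cpp_sep_convolve(img, kern)
  noise_filt <- bg["sd"] * sum(kern^2)   # separable: sum of 2-D kernel^2
  thr <- bg["level"] + params$threshold_k * noise_filt
  cand <- .cpp_local_maxima(filt, thr, params$min_separation_px)
  empty <- data.frame(tile_row = integer(0), tile_col = integer(0),
                      x_px = numeric(0), y_px = numeric(0),
                      x_um = numeric(0), y_um = numeric(0),
                      intensity = numeric(0), fwhm_px = numeric(0),
                      snr = numeric(0), is_aggregate = logical(0),
                      fit_converged = logical(0))
  sat <- max(img) >= 65535 && mean(img >= 65535) >= 0.01
  if (!nrow(cand)) {
    if (sat) attr(empty, "saturation_warning") <- TRUE
    return(empty)
  }
  x0 <- cand[, 2] - 1; y0 <- cand[, 1] - 1        # to 0-based x/y
  fits <- .cpp_fit_spots(img, x0, y0, params$fit_window_px, sigma,
                         bg["level"], 30L)
  x <- fits[, 1]; y <- fits[, 2]; itot <- fits[, 3]
  sig <- fits[, 4]; base <- fits[, 5]
  ok <- fits[, 6] > 0 & is.finite(itot) & itot > 0 &
        abs(x - x0) <= params$fit_window_px & abs(y - y0) <= params$fit_window_px
  # fallback: centre of mass + aperture sum on the window
  if (any(!ok)) {
    h <- params$fit_window_px %/% 2
    for (i in which(!ok)) {
      jc <- round(x0[i]); ic <- round(y0[i])
      js <- max(0, jc - h):min(ncol(img) - 1, jc + h)
      is_ <- max(0, ic - h):min(nrow(img) - 1, ic + h)
      w <- img[is_ + 1, js + 1, drop = FALSE] - bg["level"]
      w[w < 0] <- 0
      tot <- sum(w)
      if (tot <= 0) { x[i] <- x0[i]; y[i] <- y0[i]; itot[i] <- 0; next }
      x[i] <- sum(rep(js, each = length(is_)) * w) / tot
      y[i] <- sum(rep(is_, times = length(js)) * w) / tot
      itot[i] <- tot
      sig[i] <- sigma
      base[i] <- bg["level"]
    }
  }
  intensity <- itot
  keep <- intensity > 0 & x >= 0 & x <= ncol(img) - 1 &
          y >= 0 & y <= nrow(img) - 1
  out <- data.frame(
    tile_row = rep(row, sum(keep)), tile_col = rep(col, sum(keep)),
    x_px = x[keep], y_px = y[keep],
    x_um = NA_real_, y_um = NA_real_,
    intensity = intensity[keep],
    fwhm_px = FWHM_SIGMA * sig[keep],
    snr = intensity[keep] / (2 * pi * sig[keep]^2) / as.numeric(bg["sd"]),
    is_aggregate = FALSE,
    fit_converged = ok[keep])
  if (sat) attr(out, "saturation_warning") <- TRUE
  out
}

#' Fit a single spot with a symmetric Gaussian plus constant
#'
#' Least-squares fit of
#' `v = b + A exp(-((x - x0)^2 + (y - y0)^2) / (2 sigma^2))` on a square
#' window (clipped at the tile border and flagged if so). The integrated
#' intensity is `2 pi A sigma^2` and the FWHM is `2.3548 sigma`. If the fit
#' does not converge the function falls back to centre of mass plus aperture
#' sum and flags the result.
#'
#' @param tile An `eva_tile` or numeric matrix.
#' @param x0,y0 Starting centre, 0-based pixel coordinates.
#' @param window Window side in pixels (odd).
#' @param expected_fwhm_px Initial FWHM guess.
#' @return List with `x`, `y`, `intensity`, `fwhm_px`, `amplitude`,
#'   `background`, `converged`, `clipped`.
#' @export
fit_spot <- function(tile, x0, y0, window = 7L, expected_fwhm_px = 1.8) {
  img <- tile_data(tile)
  window <- as.integer(window)
  if (window %% 2L != 1L) stop_domain("window must be odd")
  h <- window %/% 2L
  clipped <- round(x0) - h < 0 || round(x0) + h > ncol(img) - 1 ||
             round(y0) - h < 0 || round(y0) + h > nrow(img) - 1
  bg <- estimate_background(img)
  f <- .cpp_fit_spots(img, x0, y0, window, expected_fwhm_px / FWHM_SIGMA,
                      bg["level"], 50L)
  converged <- f[1, 6] > 0 && is.finite(f[1, 3]) && f[1, 3] > 0
  if (!converged) {
    jc <- round(x0); ic <- round(y0)
    js <- max(0, jc - h):min(ncol(img) - 1, jc + h)
    is_ <- max(0, ic - h):min(nrow(img) - 1, ic + h)
    w <- img[is_ + 1, js + 1, drop = FALSE] - bg["level"]
    w[w < 0] <- 0
    tot <- sum(w)
    cx <- if (tot > 0) sum(rep(js, each = length(is_)) * w) / tot else x0
    cy <- if (tot > 0) sum(rep(is_, times = length(js)) * w) / tot else y0
    return(list(x = cx, y = cy, intensity = tot,
                fwhm_px = expected_fwhm_px, amplitude = max(w),
                background = as.numeric(bg["level"]),
                converged = FALSE, clipped = clipped))
  }
  list(x = f[1, 1], y = f[1, 2], intensity = f[1, 3],
       fwhm_px = FWHM_SIGMA * f[1, 4],
       amplitude = f[1, 3] / (2 * pi * f[1, 4]^2),
       background = f[1, 5], converged = TRUE, clipped = clipped)
}

#' Intensity histogram with Poisson counting errors and a modality report
#'
#' Bins the detected spot intensities, attaches the per-bin counting error
#' `sqrt(count)`, and reports the number of modes (local maxima of the 3-bin
#' moving average). A second mode whose height exceeds the intervening valley
#' by more than `3 * sqrt(valley)` raises the `aggregates_suspected` flag -
#' a single major maximum is the signature of an aggregate-free dispersion.
#'
#' @param detections A detection data frame (or numeric intensity vector).
#' @param n_bins Number of bins (>= 1).
#' @param range Optional length-2 intensity range; defaults to the data range.
#' @return Data frame with `mid`, `lower`, `upper`, `count`, `error`, plus
#'   attributes `n_modes`, `mode_mids`, `aggregates_suspected`.
#' @export
intensity_histogram <- function(detections, n_bins = 30L, range = NULL) {
  intens <- if (is.data.frame(detections)) detections$intensity
            else as.numeric(detections)
  if (n_bins < 1) stop_domain("n_bins must be >= 1")
  if (!length(intens)) {
    out <- data.frame(mid = numeric(0), lower = numeric(0),
                      upper = numeric(0), count = integer(0),
                      error = numeric(0))
    attr(out, "n_modes") <- NA_integer_
    return(out)
  }
  rng <- range %||% base::range(intens)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  idx <- findInterval(intens, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  count <- tabulate(idx, nbins = n_bins)
  out <- data.frame(mid = (head(breaks, -1) + breaks[-1]) / 2,
                    lower = head(breaks, -1), upper = breaks[-1],
                    count = count, error = sqrt(count))
  sm <- if (n_bins >= 3)
    as.numeric(stats::filter(count, rep(1 / 3, 3), sides = 2)) else count
  sm[is.na(sm)] <- count[is.na(sm)]
  is_max <- logical(n_bins)
  for (i in seq_len(n_bins)) {
    is_max[i] <- sm[i] > 0 &&
      (i == 1 || sm[i] > sm[i - 1]) &&
      (i == n_bins || sm[i] >= sm[i + 1]) &&
      !(i > 1 && sm[i] == sm[i - 1])   # plateaus count once
  }
  cand <- which(is_max)
  # a local maximum is a significant mode when it rises above the deepest
  # valley separating it from a higher mode by more than 3 sqrt(valley)
  # (Poisson counting noise); the global maximum is always a mode
  modes <- integer(0)
  if (length(cand)) {
    top <- cand[which.max(sm[cand])]
    modes <- top
    for (i in setdiff(cand, top)) {
      higher <- cand[sm[cand] > sm[i]]
      sep <- vapply(higher, function(h) min(sm[min(i, h):max(i, h)]), 0)
      valley <- min(sep)
      if (sm[i] - valley > 3 * sqrt(max(valley, 1)))
        modes <- c(modes, i)
    }
    modes <- sort(modes)
  }
  attr(out, "n_modes") <- length(modes)
  attr(out, "mode_mids") <- out$mid[modes]
  attr(out, "aggregates_suspected") <- length(modes) >= 2
  out
}

#' Flag unusually bright detections as aggregates
#'
#' Per-spot rule: a detection is flagged when its intensity exceeds `factor`
#' times the median intensity of the main population. With a lognormal
#' single-particle brightness distribution, doublets (2x intensity) are
#' separated from the main mode at the default factor 1.6.
#'
#' @param detections Detection data frame.
#' @param factor Multiple of the main-mode median.
#' @return The data frame with `is_aggregate` filled in.
#' @export
flag_aggregates <- function(detections, factor = 1.6) {
  if (!nrow(detections)) return(detections)
  detections$is_aggregate <-
    detections$intensity > factor * median(detections$intensity)
  detections
}

#' Neural spot segmentation (optional path)
#'
#' The encoder-decoder segmentation path requires a deep-learning backend
#' (torch or keras); none ships with this package, so this entry point
#' reports the capability gap and directs callers to the classical
#' matched-filter detector, which is the reference implementation of the
#' same task.
#'
#' @param tiles,truth_masks Training pairs (unused without a backend).
#' @param backend Backend package name to probe.
#' @export
train_and_segment <- function(tiles, truth_masks, backend = "torch") {
  if (!requireNamespace(backend, quietly = TRUE))
    stop("the neural detection path requires the '", backend,
         "' package, which is not installed; use detect_spots(), the ",
         "classical matched-filter path", call. = FALSE)
  stop("neural path backend found but no trained model is shipped; ",
       "use detect_spots()", call. = FALSE)
}
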