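#' Estimate the translation between two overlapping tiles
#'
#' Normalized cross-correlation of the overlap region over integer offsets
#' within `nominal_offset` +/- `search_radius`, with the peak refined to
#' subpixel precision by quadratic interpolation of its 3 x 3 neighbourhood.
#' The offset is the position of tile B's pixel (0, 0) in tile A's pixel
#' frame. A featureless overlap (undefined or weak correlation) returns the
#' nominal offset with confidence 0 rather than failing.
#'
#' @param tile_a,tile_b `eva_tile`s or numeric matrices.
#' @param nominal_offset Length-2 numeric, nominal (dx, dy) in pixels.
#' @param search_radius Search half-width in pixels.
#' @return Object of class `eva_pair_offset`: list with `tile_a`, `tile_b`
#'   (grid indices or NULL), `offset` (dx, dy, px, subpixel), `confidence`
#'   (peak correlation clamped to `[0, 1]`).
#' @export
estimate_pair_offset <- function(tile_a, tile_b, nominal_offset,
                                 search_radius = 14L) {
  a <- tile_data(tile_a); b <- tile_data(tile_b)
  n0 <- round(nominal_offset)
  best <- c(NA_real_, NA_real_); best_cor <- -Inf
  shifts <- expand.grid(dx = (n0[1] - search_radius):(n0[1] + search_radius),
                        dy = (n0[2] - search_radius):(n0[2] + search_radius))
  cors <- .cpp_overlap_corr(a, b, as.integer(shifts$dx),
                            as.integer(shifts$dy), 8L)
  if (all(!is.finite(cors))) {
    return(structure(list(tile_a = tile_id(tile_a), tile_b = tile_id(tile_b),
                          offset = as.numeric(nominal_offset),
                          confidence = 0, nominal = TRUE),
                     class = "eva_pair_offset"))
  }
  k <- which.max(cors)
  best <- c(shifts$dx[k], shifts$dy[k]); best_cor <- cors[k]
  # subpixel: 1-D parabola through the peak and its neighbours per axis
  refine <- function(cm, c0, cp) {
    den <- cm - 2 * c0 + cp
    if (!is.finite(den) || den >= 0) return(0)
    d <- 0.5 * (cm - cp) / den
    max(-0.5, min(0.5, d))
  }
  cx <- vapply(c(-1, 0, 1), function(d)
    overlap_correlation(a, b, best[1] + d, best[2]), 0)
  cy <- vapply(c(-1, 0, 1), function(d)
    overlap_correlation(a, b, best[1], best[2] + d), 0)
  off <- c(best[1] + refine(cx[1], cx[2], cx[3]),
           best[2] + refine(cy[1], cy[2], cy[3]))
  conf <- max(0, min(1, best_cor))
  if (conf < 0.2) {
    return(structure(list(tile_a = tile_id(tile_a), tile_b = tile_id(tile_b),
                          offset = as.numeric(nominal_offset),
                          confidence = conf, nominal = TRUE),
                     class = "eva_pair_offset"))
  }
  structure(list(tile_a = tile_id(tile_a), tile_b = tile_id(tile_b),
                 offset = off, confidence = conf, nominal = FALSE),
            class = "eva_pair_offset")
}

tile_id <- function(tile) {
  if (is_eva_tile(tile)) c(row = tile$row, col = tile$col) else NULL
}

# Pearson correlation of the overlap of a and b at integer offset (dx, dy):
# b's pixel (x, y) aligns with a's pixel (x + dx, y + dy).
overlap_correlation <- function(a, b, dx, dy) {
  as.numeric(.cpp_overlap_corr(a, b, as.integer(dx), as.integer(dy), 8L))
}

#' Measure all adjacent pair offsets of a tile grid
#'
#' Runs [estimate_pair_offset()] for every horizontally and vertically
#' adjacent pair, using the nominal stage geometry as the search centre.
#'
#' @param tiles List of `eva_tile`s (any order; located by grid indices).
#' @param optics The [optics_spec()] used for nominal offsets.
#' @param search_radius Search half-width in pixels.
#' @return List of `eva_pair_offset`.
#' @export
grid_pair_offsets <- function(tiles, optics, search_radius = 14L) {
  key <- vapply(tiles, function(t) paste(t$row, t$col), "")
  lookup <- function(r, c) {
    i <- match(paste(r, c), key)
    if (is.na(i)) NULL else tiles[[i]]
  }
  step_px <- optics$step / optics$pixel_size
  offs <- list()
  for (t in tiles) {
    for (d in list(c(0, 1), c(1, 0))) {
      nb <- lookup(t$row + d[1], t$col + d[2])
      if (is.null(nb)) next
      nominal <- c(d[2], d[1]) * step_px
      offs[[length(offs) + 1L]] <-
        estimate_pair_offset(t, nb, nominal, search_radius)
    }
  }
  offs
}

#' Solve a globally consistent mosaic layout
#'
#' Tile translations minimise the confidence-weighted squared inconsistency
#' with the measured pair offsets; pairs below `confidence_floor` are
#' replaced by their nominal offsets at a small weight so the system stays
#' connected. The top-left tile is the gauge anchor, fixed at its nominal
#' stage position. x and y are separable linear least-squares problems.
#'
#' @param offsets List of `eva_pair_offset` (from [grid_pair_offsets()]).
#' @param manifest Tile manifest (data frame with `row`, `col`,
#'   `nominal_x_um`, `nominal_y_um`) as produced by [generate_tile_grid()]
#'   or [read_tile_set()].
#' @param pixel_size Micrometres per pixel.
#' @param confidence_floor Offsets below this confidence are demoted to
#'   nominal (weight `fallback_weight`).
#' @param fallback_weight Weight assigned to nominal fallback constraints.
#' @return Object of class `eva_mosaic_layout`: data frame `tiles` with
#'   refined global stage positions (`x_um`, `y_um`), `anchor`, and
#'   `residual_rms_px`.
#' @export
solve_global_layout <- function(offsets, manifest, pixel_size,
                                confidence_floor = 0.3,
                                fallback_weight = 0.05) {
  n <- nrow(manifest)
  key <- paste(manifest$row, manifest$col)
  anchor <- which.min(manifest$row * 1e6 + manifest$col)
  idx <- function(id) match(paste(id[1], id[2]), key)
  nom_px <- cbind(manifest$nominal_x_um, manifest$nominal_y_um) / pixel_size
  rows_i <- integer(0); rows_j <- integer(0)
  wts <- numeric(0); rhs_x <- numeric(0); rhs_y <- numeric(0)
  used <- logical(0)
  for (o in offsets) {
    i <- idx(o$tile_a); j <- idx(o$tile_b)
    if (is.na(i) || is.na(j)) stop("pair offset references unknown tile")
    accepted <- o$confidence >= confidence_floor
    off <- if (accepted) o$offset else nom_px[j, ] - nom_px[i, ]
    w <- if (accepted) o$confidence else fallback_weight
    rows_i <- c(rows_i, i); rows_j <- c(rows_j, j)
    wts <- c(wts, w); rhs_x <- c(rhs_x, off[1]); rhs_y <- c(rhs_y, off[2])
    used <- c(used, accepted)
  }
  if (!length(wts)) stop("no pair offsets supplied")
  m <- length(wts)
  A <- matrix(0, m, n)
  A[cbind(seq_len(m), rows_j)] <- 1
  A[cbind(seq_len(m), rows_i)] <- A[cbind(seq_len(m), rows_i)] - 1
  free <- setdiff(seq_len(n), anchor)
  Af <- A[, free, drop = FALSE] * sqrt(wts)
  solve_axis <- function(rhs, nom_axis) {
    b <- (rhs - A[, anchor] * nom_axis[anchor]) * sqrt(wts)
    fit <- tryCatch(qr.solve(Af, b), error = function(e)
      stop("mosaic constraint graph is disconnected", call. = FALSE))
    out <- numeric(n); out[anchor] <- nom_axis[anchor]; out[free] <- fit
    out
  }
  tx <- solve_axis(rhs_x, nom_px[, 1])
  ty <- solve_axis(rhs_y, nom_px[, 2])
  res <- sqrt(sum(wts * ((tx[rows_j] - tx[rows_i] - rhs_x)^2 +
                         (ty[rows_j] - ty[rows_i] - rhs_y)^2)) /
              (2 * sum(wts)))
  tiles <- data.frame(row = manifest$row, col = manifest$col,
                      x_um = tx * pixel_size, y_um = ty * pixel_size)
  structure(list(tiles = tiles, anchor = c(row = manifest$row[anchor],
                                           col = manifest$col[anchor]),
                 residual_rms_px = res, pixel_size = pixel_size),
            class = "eva_mosaic_layout")
}

#' Map per-tile detections into the global droplet frame
#'
#' Adds `x_um`, `y_um` as tile translation + pixel position * pixel size;
#' per-tile pixel coordinates are preserved.
#'
#' @param detections Detection data frame with `tile_row`, `tile_col`.
#' @param layout An `eva_mosaic_layout`.
#' @param pixel_size Micrometres per pixel; defaults to the layout's.
#' @return The detection data frame with global coordinates filled in.
#' @export
to_global <- function(detections, layout, pixel_size = NULL) {
  stopifnot(inherits(layout, "eva_mosaic_layout"))
  ps <- pixel_size %||% layout$pixel_size
  if (!nrow(detections)) return(detections)
  key <- paste(layout$tiles$row, layout$tiles$col)
  i <- match(paste(detections$tile_row, detections$tile_col), key)
  if (anyNA(i)) {
    bad <- which(is.na(i))[1]
    stop("detection references tile r", detections$tile_row[bad], "_c",
         detections$tile_col[bad], " absent from the layout")
  }
  detections$x_um <- layout$tiles$x_um[i] + detections$x_px * ps
  detections$y_um <- layout$tiles$y_um[i] + detections$y_px * ps
  detections
}

#' Remove duplicate detections from tile overlaps
#'
#' Detections of the same physical particle seen in two overlapping tiles
#' sit within a spot diameter of each other in global coordinates. Among any
#' such group originating from different tiles, the brightest detection is
#' kept (ties: lowest tile index). Detections from the same tile are never
#' merged, so on non-overlapping data the operation is the identity; it is
#' idempotent.
#'
#' @param detections Detection data frame with global coordinates.
#' @param radius Merge radius, micrometres. The default, 2 px at the standard
#'   pixel size (~1.3 um), matches the spot FWHM scale.
#' @return The deduplicated data frame (attribute `n_removed`).
#' @export
deduplicate <- function(detections, radius = 2 * 674 / 1024) {
  n <- nrow(detections)
  if (n < 2) { attr(detections, "n_removed") <- 0L; return(detections) }
  if (anyNA(detections$x_um) || anyNA(detections$y_um))
    stop("global coordinates required; run to_global() first")
  tid <- detections$tile_row * 1e6 + detections$tile_col
  ord <- order(-detections$intensity, tid)
  x <- detections$x_um; y <- detections$y_um
  cell <- radius
  cx <- floor(x / cell); cy <- floor(y / cell)
  bins <- new.env(hash = TRUE, parent = emptyenv())
  keep <- logical(n)
  for (i in ord) {
    dup <- FALSE
    for (dx in -1:1) {
      for (dy in -1:1) {
        k <- paste(cx[i] + dx, cy[i] + dy)
        for (j in bins[[k]] %||% integer(0)) {
          if (tid[j] != tid[i] &&
              (x[j] - x[i])^2 + (y[j] - y[i])^2 <= radius^2) {
            dup <- TRUE; break
          }
        }
        if (dup) break
      }
      if (dup) break
    }
    if (!dup) {
      keep[i] <- TRUE
      k <- paste(cx[i], cy[i])
      bins[[k]] <- c(bins[[k]] %||% integer(0), i)
    }
  }
  out <- detections[sort(which(keep)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- n - nrow(out)
  out
}
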