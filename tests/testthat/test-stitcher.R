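# Two overlapping tiles cut from one textured scene, offset by `shift` px.
shifted_pair <- function(n = 256L, shift = c(7, -3), seed = 1) {
  set.seed(seed)
  big <- spot_image(as.integer(n + 64), runif(120, 5, n + 58),
                    runif(120, 5, n + 58), 15000, read_noise_sd = 5,
                    seed = seed)
  base <- 20L
  a <- big[base + 1:n, base + 1:n]
  b <- big[base + shift[2] + 1:n, base + shift[1] + 1:n]
  list(a = a, b = b)
}

test_that("a shifted copy is recovered to subpixel accuracy", {
  p <- shifted_pair(shift = c(7, -3))
  off <- estimate_pair_offset(p$a, p$b, nominal_offset = c(0, 0),
                              search_radius = 10L)
  expect_lt(abs(off$offset[1] - 7), 0.1)
  expect_lt(abs(off$offset[2] - (-3)), 0.1)
  expect_gt(off$confidence, 0.9)
})

test_that("offsets of jittered adjacent tiles are recovered within 0.5 px", {
  spec <- small_droplet(1500, radius = 300)
  op <- optics_spec(tile_px = 400L, step = 180, stage_jitter_sd = 2)
  tr <- generate_droplet_truth(spec, 31)
  g <- generate_tile_grid(tr, op, 2L, 2L, seed = 31)
  offs <- grid_pair_offsets(g$tiles, op)
  man <- g$manifest
  key <- paste(man$row, man$col)
  for (o in offs) {
    i <- match(paste(o$tile_a[1], o$tile_a[2]), key)
    j <- match(paste(o$tile_b[1], o$tile_b[2]), key)
    true_off <- c(man$true_x_um[j] - man$true_x_um[i],
                  man$true_y_um[j] - man$true_y_um[i]) / op$pixel_size
    expect_lt(max(abs(o$offset - true_off)), 0.5)
    # antisymmetry: measuring the pair the other way negates the offset
    rev <- estimate_pair_offset(g$tiles[[j]], g$tiles[[i]], -true_off)
    expect_lt(max(abs(rev$offset + o$offset)), 0.3)
  }
})

test_that("featureless overlaps fall back to the nominal offset", {
  set.seed(4)
  a <- matrix(100 + rnorm(128 * 128, 0, 5), 128)
  b <- matrix(100 + rnorm(128 * 128, 0, 5), 128)
  off <- estimate_pair_offset(a, b, nominal_offset = c(90, 0),
                              search_radius = 6L)
  expect_lt(off$confidence, 0.2)
  expect_identical(off$offset, c(90, 0))
  # constant tiles have undefined correlation -> confidence 0
  cst <- matrix(100, 128, 128)
  off2 <- estimate_pair_offset(cst, cst, c(90, 0), 4L)
  expect_identical(off2$confidence, 0)
})

test_that("perfectly consistent offsets reproduce the layout exactly", {
  man <- expand.grid(row = 1:3, col = 1:3)
  man$nominal_x_um <- (man$col - 1) * 100
  man$nominal_y_um <- (man$row - 1) * 100
  truth <- man
  set.seed(9)
  truth$x <- man$nominal_x_um + rnorm(9, 0, 3)
  truth$y <- man$nominal_y_um + rnorm(9, 0, 3)
  ps <- 1
  offs <- list()
  for (i in 1:9) for (j in 1:9) {
    dr <- man$row[j] - man$row[i]; dc <- man$col[j] - man$col[i]
    if ((dr == 0 && dc == 1) || (dr == 1 && dc == 0)) {
      offs[[length(offs) + 1]] <- structure(list(
        tile_a = c(man$row[i], man$col[i]), tile_b = c(man$row[j], man$col[j]),
        offset = c(truth$x[j] - truth$x[i], truth$y[j] - truth$y[i]),
        confidence = 1), class = "eva_pair_offset")
    }
  }
  lay <- solve_global_layout(offs, man, ps)
  expect_lt(lay$residual_rms_px, 1e-9)
  # exact up to the gauge (anchor pinned at its nominal position)
  gx <- lay$tiles$x_um - truth$x
  expect_lt(diff(range(gx)), 1e-9)
  gy <- lay$tiles$y_um - truth$y
  expect_lt(diff(range(gy)), 1e-9)
  # one corrupted low-confidence offset is suppressed by the weighting
  offs_bad <- offs
  offs_bad[[1]]$offset <- offs_bad[[1]]$offset + c(20, 0)
  offs_bad[[1]]$confidence <- 0.05
  lay2 <- solve_global_layout(offs_bad, man, ps)
  gx2 <- lay2$tiles$x_um - truth$x; gy2 <- lay2$tiles$y_um - truth$y
  err <- sqrt((gx2 - gx2[1])^2 + (gy2 - gy2[1])^2)
  expect_lt(max(err), 1)
})

test_that("gauge invariance: shifting nominal positions shifts the layout", {
  spec <- small_droplet(600, radius = 120)
  op <- optics_spec(tile_px = 160L, step = 70, stage_jitter_sd = 1)
  tr <- generate_droplet_truth(spec, 13)
  g <- generate_tile_grid(tr, op, 2L, 2L, seed = 13)
  offs <- grid_pair_offsets(g$tiles, op)
  lay1 <- solve_global_layout(offs, g$manifest, op$pixel_size)
  man2 <- g$manifest
  man2$nominal_x_um <- man2$nominal_x_um + 50
  man2$nominal_y_um <- man2$nominal_y_um - 30
  lay2 <- solve_global_layout(offs, man2, op$pixel_size)
  expect_equal(lay2$tiles$x_um, lay1$tiles$x_um + 50, tolerance = 1e-9)
  expect_equal(lay2$tiles$y_um, lay1$tiles$y_um - 30, tolerance = 1e-9)
})

test_that("to_global maps the anchor origin to its stage position", {
  lay <- structure(list(
    tiles = data.frame(row = 1L, col = 1L, x_um = -100, y_um = 40),
    anchor = c(row = 1L, col = 1L), residual_rms_px = 0, pixel_size = 0.5),
    class = "eva_mosaic_layout")
  det <- data.frame(tile_row = 1L, tile_col = 1L, x_px = c(0, 10),
                    y_px = c(0, 4), x_um = NA_real_, y_um = NA_real_,
                    intensity = c(5, 6))
  g <- to_global(det, lay)
  expect_equal(g$x_um, c(-100, -95))
  expect_equal(g$y_um, c(40, 42))
  # unknown tile is a referential-integrity error
  det$tile_row <- 2L
  expect_error(to_global(det, lay), "absent")
  # empty table passes through
  expect_identical(nrow(to_global(det[0, ], lay)), 0L)
})

test_that("deduplicate keeps one spot per overlap group and is idempotent", {
  det <- data.frame(
    tile_row = c(1, 1, 1, 2, 2), tile_col = c(1, 2, 1, 1, 1),
    x_px = 0, y_px = 0,
    x_um = c(10, 10.2, 50, 50.3, 80), y_um = c(10, 10.1, 50, 50.2, 80),
    intensity = c(100, 250, 300, 200, 50))
  out <- deduplicate(det, radius = 1.3)
  # the 10-um pair spans two tiles: brightest survives
  expect_identical(sum(out$x_um < 20), 1L)
  expect_equal(out$intensity[out$x_um < 20], 250)
  # the 50-um pair spans different tiles -> merged; 80-um singleton kept
  expect_identical(sum(out$x_um > 40 & out$x_um < 60), 1L)
  expect_identical(sum(out$x_um == 80), 1L)
  expect_identical(nrow(deduplicate(out, radius = 1.3)), nrow(out))
  # distant detections and same-tile neighbours are never merged
  det2 <- data.frame(tile_row = 1, tile_col = 1, x_px = 0, y_px = 0,
                     x_um = c(0, 0.2, 10), y_um = c(0, 0, 0),
                     intensity = c(1, 2, 3))
  expect_identical(nrow(deduplicate(det2, radius = 1.3)), 3L)
  det3 <- det2; det3$tile_col <- c(1, 2, 3)
  out3 <- deduplicate(det3, radius = 1.3)
  expect_identical(nrow(out3), 2L)
})

test_that("full grid dedup count agrees with truth-matching oracle", {
  spec <- small_droplet(1200, radius = 280)
  op <- optics_spec(tile_px = 400L, step = 180, stage_jitter_sd = 2)
  tr <- generate_droplet_truth(spec, 17)
  g <- generate_tile_grid(tr, op, 3L, 3L, seed = 17)
  ana <- analyze_tile_set(g$tiles, g$manifest, csr_boot = 0L)
  det <- ana$detections
  # remove the gauge (anchor jitter) before matching to truth
  shift <- c(g$manifest$true_x_um[1] - g$manifest$nominal_x_um[1],
             g$manifest$true_y_um[1] - g$manifest$nominal_y_um[1])
  m <- greedy_match(tr$positions, cbind(det$x_um + shift[1],
                                        det$y_um + shift[2]), 1.3)
  expect_gt(m / nrow(det), 0.99)              # detections are real particles
  expect_gt(m / nrow(tr$positions), 0.96)     # nearly all particles counted
  # no cross-tile duplicate pairs remain within the merge radius
  r <- 2 * op$pixel_size
  close <- which(as.matrix(dist(cbind(det$x_um, det$y_um))) <= r,
                 arr.ind = TRUE)
  close <- close[close[, 1] < close[, 2], , drop = FALSE]
  if (nrow(close)) {
    cross <- det$tile_row[close[, 1]] != det$tile_row[close[, 2]] |
             det$tile_col[close[, 1]] != det$tile_col[close[, 2]]
    expect_false(any(cross))
  } else expect_identical(nrow(close), 0L)
})
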