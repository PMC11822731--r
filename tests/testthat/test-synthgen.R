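test_that("ground truth is reproducible and validates its inputs", {
  spec <- small_droplet(200)
  t1 <- generate_droplet_truth(spec, 7)
  t2 <- generate_droplet_truth(spec, 7)
  expect_identical(t1$positions, t2$positions)
  expect_identical(t1$intensities, t2$intensities)
  expect_false(identical(t1$positions,
                         generate_droplet_truth(spec, 8)$positions))
  # all positions inside the droplet disk, list lengths agree
  expect_true(all(rowSums(t1$positions^2) <= spec$droplet_radius^2))
  expect_length(t1$intensities, nrow(t1$positions))
  expect_length(t1$is_aggregate, nrow(t1$positions))
  # zero concentration -> empty truth
  empty <- generate_droplet_truth(small_droplet(0), 1)
  expect_identical(nrow(empty$positions), 0L)
  # invalid concentration rejected
  expect_error(droplet_spec(in_droplet_concentration = -5), "concentration")
  expect_error(droplet_spec(in_droplet_concentration = NaN), "concentration")
})

test_that("realized counts follow the Poisson law over many seeds", {
  lambda <- 200
  spec <- small_droplet(lambda)
  counts <- vapply(1:300, function(s)
    nrow(generate_droplet_truth(spec, s)$positions), 0L)
  expect_lt(abs(mean(counts) - lambda), 3 * sqrt(lambda / 300))
  expect_gt(var(counts) / mean(counts), 0.8)
  expect_lt(var(counts) / mean(counts), 1.2)
})

test_that("CSR placement matches the closed-form NN distance CDF", {
  # ~10,000 points on the full-size droplet disk; empirical NN CDF vs
  # 1 - exp(-rho pi r^2) with rho = N / (pi R^2)
  spec <- droplet_spec(in_droplet_concentration = 10000 / 2.5e-3)
  ks <- vapply(1:10, function(s) {
    tr <- generate_droplet_truth(spec, s)
    rho <- nrow(tr$positions) / (pi * spec$droplet_radius^2)
    d <- sort(nearest_neighbor_distances(tr$positions))
    evacount:::ks_statistic(csr_cdf(d, rho))
  }, 0)
  crit <- 1.63 / sqrt(10000)          # alpha = 0.01 critical value
  expect_lt(ks[1], crit)
  expect_gte(mean(ks < crit), 0.9)    # law holds for the large majority
})

test_that("edge-ring placement concentrates at the rim", {
  spec <- small_droplet(500, placement_model = "edge_ring")
  tr <- generate_droplet_truth(spec, 3)
  rad <- sqrt(rowSums(tr$positions^2))
  expect_gt(median(rad) / spec$droplet_radius, 0.8)
  expect_true(all(rad <= spec$droplet_radius))
})

test_that("rendered spots integrate to their intensity and are photometric", {
  op <- quiet_optics()
  tr <- generate_droplet_truth(small_droplet(0), 1)
  tr$positions <- matrix(c(0, 0), 1, 2,
                         dimnames = list(NULL, c("x_um", "y_um")))
  tr$intensities <- 20000
  tr$is_aggregate <- FALSE
  tile <- render_tile(tr, op, 1L, 1L, seed = 1, rows = 1L, cols = 1L)
  # background-subtracted sum over a 6 sigma window equals the intensity
  ctr <- (tr$positions[1, ] - tile$stage_position) / op$pixel_size
  w <- 6
  js <- round(ctr[1]) + (-w:w); is <- round(ctr[2]) + (-w:w)
  s1 <- sum(tile$data[is + 1, js + 1] - op$background_offset)
  expect_lt(abs(s1 / 20000 - 1), 0.005)
  # doubling the intensity doubles the noiseless sum (linearity)
  tr$intensities <- 40000
  tile2 <- render_tile(tr, op, 1L, 1L, seed = 1, rows = 1L, cols = 1L)
  s2 <- sum(tile2$data[is + 1, js + 1] - op$background_offset)
  expect_lt(abs(s2 / s1 - 2), 0.005)
})

test_that("a rendered spot re-measures at the nominal 1.8 px FWHM", {
  set.seed(21)
  for (i in 1:5) {
    x <- 30 + runif(1); y <- 31 + runif(1)
    img <- spot_image(64L, x, y, 20000)
    f <- fit_spot(img, round(x), round(y))
    expect_lt(abs(f$fwhm_px - 1.8), 0.02)
  }
})

test_that("empty truth renders pure background", {
  op <- quiet_optics(read_noise_sd = 5)
  op$shot_noise <- FALSE
  tr <- generate_droplet_truth(small_droplet(0), 1)
  tile <- render_tile(tr, op, 1L, 1L, seed = 2, rows = 1L, cols = 1L)
  se <- 5 / sqrt(length(tile$data))
  expect_lt(abs(mean(tile$data) - op$background_offset), 3 * se)
})

test_that("tiles are deterministic and noise does not shift positions", {
  op <- optics_spec(tile_px = 96L, step = 40)
  spec <- small_droplet(100, radius = 60)
  tr <- generate_droplet_truth(spec, 5)
  g1 <- generate_tile_grid(tr, op, 2L, 2L, seed = 5)
  g2 <- generate_tile_grid(tr, op, 2L, 2L, seed = 5)
  expect_identical(g1$tiles[[1]]$data, g2$tiles[[1]]$data)
  expect_identical(g1$manifest, g2$manifest)
  # same seed, noise disabled: identical jittered layout
  op0 <- op; op0$shot_noise <- FALSE; op0$read_noise_sd <- 0
  g3 <- generate_tile_grid(tr, op0, 2L, 2L, seed = 5)
  expect_equal(g3$manifest$true_x_um, g1$manifest$true_x_um)
})

test_that("grid geometry: default 6 x 6 overlaps by 174 um and covers", {
  op <- optics_spec()
  nom <- evacount:::nominal_stage_positions(op, 6L, 6L)
  expect_identical(nrow(nom), 36L)
  expect_equal(op$frame_size - op$step, 174, tolerance = 1e-6)
  spec <- droplet_spec()  # ~3 mm droplet
  tr <- generate_droplet_truth(small_droplet(0, radius = 1500), 1)
  ex <- 5 * op$step + op$frame_size
  expect_gte(ex / 2, 1500)  # grid covers the droplet disk
  # undersized grid records a warning in the manifest, not an error
  tr2 <- generate_droplet_truth(small_droplet(5, radius = 1500), 1)
  op2 <- optics_spec(tile_px = 64L, step = 20)
  g <- generate_tile_grid(tr2, op2, 1L, 1L, seed = 1)
  expect_false(is.null(attr(g$manifest, "coverage_warning")))
})

test_that("every particle lands in exactly one tile's assignment region", {
  # brute-force point-in-rectangle assignment: unique regions plus
  # once-counted overlaps partition the covered truth
  op <- quiet_optics(tile_px = 128L)
  op$step <- 60
  spec <- small_droplet(300, radius = 70)
  tr <- generate_droplet_truth(spec, 11)
  g <- generate_tile_grid(tr, op, 2L, 2L, seed = 11)
  man <- g$manifest
  half <- op$pixel_size / 2
  in_tile <- sapply(seq_len(nrow(man)), function(i) {
    x0 <- man$true_x_um[i] - half
    y0 <- man$true_y_um[i] - half
    tr$positions[, 1] >= x0 & tr$positions[, 1] < x0 + op$frame_size &
    tr$positions[, 2] >= y0 & tr$positions[, 2] < y0 + op$frame_size
  })
  covered <- rowSums(in_tile) >= 1
  expect_identical(sum(covered), nrow(tr$positions))  # grid covers droplet
  # counting each covered particle once reproduces the total
  expect_identical(sum(apply(in_tile, 1, function(r) any(r))),
                   nrow(tr$positions))
})

test_that("single-tile grid yields one manifest entry", {
  op <- quiet_optics()
  tr <- generate_droplet_truth(small_droplet(10, radius = 15), 2)
  g <- generate_tile_grid(tr, op, 1L, 1L, seed = 2)
  expect_identical(nrow(g$manifest), 1L)
  expect_length(g$tiles, 1L)
})
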