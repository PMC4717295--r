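# Midget mosaic, center-surround resampling, logistic output, and the
# cortical map.

test_that("mosaic cell count scales linearly with resolution factor and density falls", {
  m1 <- build_mosaic(resolution_factor = 0.5, geom = fx_geom())
  m5 <- build_mosaic(resolution_factor = 0.1, geom = fx_geom())
  expect_lt(abs((nrow(m5$cells) / nrow(m1$cells)) / 0.2 - 1), 0.05)
  expect_gt(midget_density()(2), midget_density()(20))
  # local cell density realised in the mosaic drops with eccentricity
  n_in <- sum(m1$cells$ecc < 5); n_out <- sum(m1$cells$ecc > 22)
  area_in <- pi * (5^2 - 0.5^2) / 2; area_out <- pi * (27^2 - 22^2) / 2
  expect_gt(n_in / area_in, n_out / area_out)
  expect_error(build_mosaic(midget_density(d0 = 1e-4), 1, fx_geom()),
               "fewer than 10")
  # off-cells: constructed on request (smaller centers, hence more cells),
  # never wired into the signal path
  m_off <- build_mosaic(resolution_factor = 0.05, geom = fx_geom(),
                        include_off = TRUE)
  expect_gt(nrow(m_off$off_cells$cells), 1.5 * nrow(m_off$cells))
})

test_that("segments tile the field: random points map to exactly one cell", {
  mosaic <- fx_pop()$mosaic
  set.seed(12)
  ecc <- runif(1e4, 0.5, 27)
  phi <- runif(1e4, -pi / 2, pi / 2)
  id <- asfnet:::mosaic_cell_at(mosaic, ecc, phi)
  expect_false(any(is.na(id)))
  expect_true(all(id >= 1 & id <= nrow(mosaic$cells)))
  # just outside the sector: no cell
  expect_true(is.na(asfnet:::mosaic_cell_at(mosaic, 27.4, 0)))
  expect_true(is.na(asfnet:::mosaic_cell_at(mosaic, 5, 0.6 * pi)))
})

test_that("uniform images produce zero net input and a flat rate field", {
  mosaic <- fx_pop()$mosaic
  img <- asfnet:::field_canvas(fx_geom(), background = 0.7)
  inp <- resample_image_to_retina(img, mosaic)
  expect_lt(max(abs(inp$net)), 1e-12)
  r <- retina_output(inp)
  expect_equal(unique(round(r, 12)), 0.5)
  r_on <- retina_output(inp, midpoint = 0.15)
  expect_equal(unique(round(r_on, 12)), 0.15)
})

test_that("a bright spot drives its cell positive and its neighbors negative", {
  mosaic <- fx_pop()$mosaic
  img <- asfnet:::field_canvas(fx_geom())
  cells <- mosaic$cells
  target <- which.min(abs(cells$ecc - 10) + abs(cells$phi))
  xs <- asfnet:::vf_x(img); ys <- asfnet:::vf_y(img)
  img$values[which.min(abs(ys - cells$y[target])),
             which.min(abs(xs - cells$x[target]))] <- 1
  inp <- resample_image_to_retina(img, mosaic)
  expect_gt(inp$net[target], 0)
  # every cell whose surround neighborhood contains the spotted cell is
  # suppressed (the discrete polar 8-neighborhood is not exactly symmetric)
  nbmat <- asfnet:::mosaic_neighbors(mosaic)
  affected <- which(apply(nbmat, 1, function(x) any(x == target, na.rm = TRUE)))
  expect_gte(length(affected), 6)
  expect_true(all(inp$net[affected] < 0))
  # linearity: doubling the increment doubles the pre-normalization input
  img2 <- img
  img2$values <- 0.5 + 2 * (img$values - 0.5)
  inp2 <- resample_image_to_retina(img2, mosaic)
  expect_equal(inp2$net[target], 2 * inp$net[target], tolerance = 1e-10)
})

test_that("logistic output is bounded, monotone, and hits its calibration points", {
  x <- c(-1, -0.3, 0, 0.3, 1)
  r <- retina_output(x)
  expect_true(all(r > 0 & r < 1))
  expect_true(all(diff(r) > 0))
  expect_equal(r[1], 0.05)
  expect_equal(r[3], 0.5)
  expect_equal(r[5], 0.95)
})

test_that("cortical map: analytic magnification, fovea-periphery ordering, invertibility", {
  map <- cortical_map()
  # small angular separation at fixed eccentricity vs analytic |dw/dz|
  for (e in c(2, 10, 20)) {
    dphi <- 1e-3
    w <- map_deg_to_cortex(map, c(e, e), c(0, dphi))
    dist_mm <- sqrt(diff(w$u)^2 + diff(w$v)^2)
    expect_equal(dist_mm / (e * dphi), cortical_magnification(map, e),
                 tolerance = 0.02)
  }
  # equal eccentricity step spans more cortex at the fovea
  w_f <- map_deg_to_cortex(map, c(1, 2), c(0, 0))
  w_p <- map_deg_to_cortex(map, c(20, 21), c(0, 0))
  expect_gt(diff(w_f$u), diff(w_p$u))
  # round trip to machine precision
  set.seed(3)
  ecc <- runif(50, 0.5, 27); phi <- runif(50, -pi / 2, pi / 2)
  w <- map_deg_to_cortex(map, ecc, phi)
  back <- map_cortex_to_deg(map, w$u, w$v)
  expect_equal(back$ecc, ecc, tolerance = 1e-12)
  expect_equal(back$phi, phi, tolerance = 1e-12)
})

test_that("low-resolution retina yields a smoothed version of the full-resolution drive", {
  geom <- fx_geom()
  img <- fx_image_low()
  m_hi <- build_mosaic(resolution_factor = 0.06, geom = geom)
  m_lo <- build_mosaic(resolution_factor = 0.012, geom = geom)
  i_hi <- resample_image_to_retina(img, m_hi)
  i_lo <- resample_image_to_retina(img, m_lo)
  # compare the luminance-integration stage on the low-res lattice: average
  # the high-res center inputs within each low-res cell (spatial blurring),
  # then correlate.  The center-surround difference stage is genuinely
  # band-pass at each mosaic's own scale, so blurring commutes with the
  # center integration, not with the difference.
  id <- asfnet:::mosaic_cell_at(m_lo, m_hi$cells$ecc, m_hi$cells$phi)
  ok <- !is.na(id)
  blurred <- tapply(i_hi$center[ok], id[ok], mean)
  expect_gt(cor(blurred, i_lo$center[as.integer(names(blurred))]), 0.9)
})
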