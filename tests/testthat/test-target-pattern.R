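# Target activation patterns: disk-integral consistency, linearity,
# impulse response, coverage saturation, and border masking.

test_that("uniform contrast energy yields c * R(7) per neuron within 0.5%", {
  pop <- fx_pop()
  ring_params <- fx_ring_params()
  cvals <- 2.3
  ce <- asfnet:::field_canvas(fx_geom(), background = 1)
  ce$values[] <- cvals
  tp <- compute_target(ce, pop, ring_params)
  inner <- which(!tp$neurons$border_affected)
  expect_gt(length(inner), 50)
  for (n in sample(inner, 25)) {
    p <- ring_params[[as.character(asfnet:::ring_of(tp$neurons$ecc[n]))]]
    expect_equal(tp$neurons$target[n], cvals * eval_asf(p, 7),
                 tolerance = 0.005)
  }
})

test_that("zero contrast energy gives a zero target everywhere", {
  pop <- fx_pop()
  ce <- asfnet:::field_canvas(fx_geom(), background = 0)
  tp <- compute_target(ce, pop, fx_ring_params())
  expect_true(all(tp$neurons$target[!tp$neurons$border_affected] == 0))
})

test_that("a contrast-energy point mass contributes f(d) * pixel_area", {
  pop <- fx_pop()
  ring_params <- fx_ring_params()
  ce <- asfnet:::field_canvas(fx_geom(), background = 0)
  xs <- asfnet:::vf_x(ce); ys <- asfnet:::vf_y(ce)
  tp0 <- compute_target(ce, pop, ring_params)
  nrn <- which(!tp0$neurons$border_affected & abs(tp0$neurons$ecc - 14) < 2)[1]
  # impulse at a known offset from this neuron's (pixel-snapped) RF center
  cx <- xs[round((tp0$neurons$x[nrn] - xs[1]) / ce$deg_per_px) + 1]
  cy <- ys[round((tp0$neurons$y[nrn] - ys[1]) / ce$deg_per_px) + 1]
  off_px <- 9
  ce$values[which(ys == cy), which(xs == cx) + off_px] <- 5
  tp <- compute_target(ce, pop, ring_params)
  p <- ring_params[[as.character(asfnet:::ring_of(tp$neurons$ecc[nrn]))]]
  d <- off_px * ce$deg_per_px
  # the kernel averages the density over each cell, so the direct evaluation
  # at the cell center agrees to the sub-pixel averaging error
  expect_equal(tp$neurons$target[nrn],
               5 * derivative_weight(p, d, 0) * ce$deg_per_px^2,
               tolerance = 0.005)
})

test_that("targets are linear in the contrast energy", {
  pop <- fx_pop()
  ring_params <- fx_ring_params()
  bank <- fx_bank()
  img <- fx_image_low()
  ce1 <- contrast_energy_image(img, bank)
  ce2 <- asfnet:::field_canvas(fx_geom(), background = 0.8)
  mix <- ce1; mix$values <- 2 * ce1$values + 3 * ce2$values
  t1 <- compute_target(ce1, pop, ring_params)$neurons$target
  t2 <- compute_target(ce2, pop, ring_params)$neurons$target
  tm <- compute_target(mix, pop, ring_params)$neurons$target
  ok <- !is.na(tm)
  expect_equal(tm[ok], (2 * t1 + 3 * t2)[ok], tolerance = 1e-10)
})

test_that("enlarging the integration disk from 7 to 9 degrees changes mid-field targets under 1%", {
  pop <- fx_pop()
  ring_params <- fx_ring_params()
  ce <- contrast_energy_image(fx_image_low(), fx_bank())
  t7 <- compute_target(ce, pop, ring_params, disk_deg = 7)$neurons
  t9 <- compute_target(ce, pop, ring_params, disk_deg = 9)$neurons
  sel <- !t7$border_affected & !t9$border_affected & t7$ecc < 20
  expect_gt(sum(sel), 30)
  rel <- abs(t9$target[sel] - t7$target[sel]) / pmax(abs(t7$target[sel]), 1e-12)
  expect_lt(stats::median(rel), 0.01)
})

test_that("border mask keeps everyone at margin 0, errs when nothing survives, and excludes a positive count at the default", {
  pop <- fx_pop()
  expect_true(all(exclude_border(pop, margin = 0)))
  expect_error(exclude_border(pop, margin = 40), "margin")
  keep <- exclude_border(pop)
  expect_gt(sum(!keep), 0)
  expect_gt(sum(keep), 0)
})
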