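# Ratio-of-Gaussians area summation model: curve shape, the derivative
# weighting density, eccentricity regressions, fitting, and variants.

test_that("eval_asf limits: zero at zero, closed-form asymptote at infinity", {
  p <- asf_params(k_c = 2, k_s = 0.4, w_c = 1.2, w_s = 3.1)
  expect_identical(eval_asf(p, 0), 0)
  asym <- p$k_c * p$w_c^2 / (1 + p$k_s * p$w_s^2)
  expect_equal(eval_asf(p, 100 * p$w_s), asym, tolerance = 1e-10)
  expect_error(eval_asf(p, -1), "non-negative")
  expect_error(eval_asf(p, NaN), "finite")
})

test_that("natural 14-degree curve is unimodal: rises, peaks, falls to a lower asymptote", {
  p <- fx_params14()
  xs <- seq(0.01, 7, length.out = 800)
  r <- eval_asf(p, xs)
  expect_true(all(r >= 0))
  ipk <- which.max(r)
  expect_gt(ipk, 10)            # interior peak, not at either edge
  expect_lt(ipk, length(xs) - 10)
  expect_true(all(diff(r[1:ipk]) > 0))
  expect_true(all(diff(r[ipk:length(r)]) < 0))
  asym <- p$k_c * p$w_c^2 / (1 + p$k_s * p$w_s^2)
  expect_gt(r[ipk], asym)
})

test_that("derivative weighting is rotationally symmetric and decays past the surround", {
  p <- fx_params14()
  expect_equal(derivative_weight(p, 0.7, 1.1), derivative_weight(p, -0.7, 1.1))
  expect_equal(derivative_weight(p, 0.7, 1.1), derivative_weight(p, 1.1, 0.7))
  rr <- seq(0.02, 7, length.out = 500)
  fmax <- max(abs(derivative_weight(p, rr)))
  expect_lt(abs(derivative_weight(p, 5 * p$w_s)), 1e-6 * fmax)
})

test_that("disk integral of the derivative weighting recovers the ASF (2-D quadrature)", {
  skip_if_not_installed("pracma")
  p <- fx_params14()
  f <- function(r, th) r * derivative_weight(p, r * cos(th), r * sin(th))
  for (D in c(0.5, 2, 7)) {
    mid <- min(1, D / 4)   # split where the density concentrates
    polar <- pracma::integral2(f, 0, mid, 0, 2 * pi, reltol = 1e-9)$Q +
      pracma::integral2(f, mid, D / 2, 0, 2 * pi, reltol = 1e-9)$Q
    expect_equal(polar, eval_asf(p, D), tolerance = 1e-3)
  }
})

test_that("eccentricity regressions evaluate linearly and guard their domain", {
  cf <- asf_regression(summation_field = c(1, 0), surround_diameter = c(3, 0),
                       suppression = c(0.2, 0))
  ch <- characteristics_at_eccentricity(cf, 21)
  expect_equal(ch$summation_field, 1)
  expect_equal(ch$surround_diameter, 3)
  expect_equal(ch$suppression, 0.2)
  cf2 <- asf_regression()
  sf <- vapply(c(1, 8, 15, 27), function(e)
    characteristics_at_eccentricity(cf2, e)$summation_field, numeric(1))
  expect_true(all(diff(sf) > 0))
  expect_error(characteristics_at_eccentricity(cf2, 31), "eccentricity")
  # suppression is clamped into [0, 1)
  cf3 <- asf_regression(suppression = c(0.9, 0.05))
  expect_lt(characteristics_at_eccentricity(cf3, 27)$suppression, 1)
})

test_that("fit_asf_params round-trips synthetic characteristics within 2%", {
  set.seed(99)
  for (i in 1:6) {
    ecc <- runif(1, 1, 26)
    ch <- characteristics_at_eccentricity(asf_regression(), ecc)
    p <- fit_asf_params(ch)
    m <- measure_asf(p)
    expect_lt(abs(m$summation_field / ch$summation_field - 1), 0.02)
    expect_lt(abs(m$surround_diameter / ch$surround_diameter - 1), 0.02)
    expect_lt(abs(m$suppression / ch$suppression - 1), 0.02)
    expect_true(all(eval_asf(p, seq(0, 7, by = 0.05)) >= 0))
  }
})

test_that("a zero-suppression target drives the surround term toward zero", {
  ch <- structure(list(eccentricity = 10, summation_field = 1.2,
                       surround_diameter = 4, suppression = 0),
                  class = "asf_characteristics")
  p <- suppressWarnings(fit_asf_params(ch))
  expect_lt(p$k_s * p$w_s^2 / (p$k_c * p$w_c^2), 0.05)
})

test_that("artificial variants shift suppression in the documented directions", {
  p <- fx_params14()
  m0 <- measure_asf(p)
  no_sup <- measure_asf(make_variant_asf(p, 4, 0.25))
  strong <- measure_asf(make_variant_asf(p, 0.25, 4))
  expect_lt(no_sup$suppression, m0$suppression)
  expect_gt(no_sup$summation_field, m0$summation_field)
  expect_gt(strong$suppression, m0$suppression)
  expect_lt(strong$summation_field, m0$summation_field)
  id <- make_variant_asf(p, 1, 1)
  expect_equal(unclass(id)[1:4], unclass(p)[1:4])
})
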