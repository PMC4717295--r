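# Synthetic inputs: natural-image surrogates with 1/f^alpha amplitude
# spectra in two spectral groups, circular grating patches for the area
# summation probe, and the bundled small-scale fixture set that exercises
# every pipeline stage without any external data.

#' Surrogate image specification
#'
#' Random-phase noise images with amplitude spectrum proportional to
#' `1/f^alpha`, emulating the second-order statistics of natural scenes.
#' The "low" spectral group uses `alpha = 1.4` (predominantly low spatial
#' frequencies) and the "mixed" group `alpha = 0.9` (closer-to-even spectral
#' content); the two groups separate cleanly in the 5-bin Gabor frequency
#' signature.
#'
#' @param alpha Amplitude spectral exponent.
#' @param intensity_range Output intensity range (min, max) in `[0, 1]`.
#' @param group Label, `"low"` or `"mixed"`.
#' @return List of class `surrogate_image_spec`.
#' @export
surrogate_image_spec <- function(alpha = 1.4,
                                 intensity_range = c(0.05, 0.95),
                                 group = if (alpha >= 1.15) "low" else "mixed") {
  stopifnot(alpha >= 0, length(intensity_range) == 2,
            intensity_range[1] < intensity_range[2])
  structure(list(alpha = alpha, intensity_range = intensity_range,
                 group = group),
            class = "surrogate_image_spec")
}

#' Generate a surrogate natural image
#'
#' White Gaussian noise is filtered in the Fourier domain by `1/f^alpha`
#' (DC removed) and linearly rescaled to the requested intensity range.
#'
#' @param spec A [surrogate_image_spec()].
#' @param seed Integer seed; identical seeds give identical images.
#' @param geom A [field_geometry()]; the image covers the field canvas.
#' @return A [vf_image()].
#' @export
generate_surrogate <- function(spec, seed, geom = field_geometry()) {
  canvas <- field_canvas(geom)
  nr <- nrow(canvas$values); nc <- ncol(canvas$values)
  set.seed(seed)
  white <- matrix(stats::rnorm(nr * nc), nr, nc)
  fy <- c(0:(nr %/% 2), -((nr - nr %/% 2 - 1):1)) / (nr * canvas$deg_per_px)
  fx <- c(0:(nc %/% 2), -((nc - nc %/% 2 - 1):1)) / (nc * canvas$deg_per_px)
  f <- sqrt(outer(fy^2, fx^2, "+"))
  amp <- ifelse(f > 0, f^(-spec$alpha), 0)
  img <- Re(stats::fft(stats::fft(white) * amp, inverse = TRUE)) / (nr * nc)
  lo <- spec$intensity_range[1]; hi <- spec$intensity_range[2]
  img <- lo + (hi - lo) * (img - min(img)) / (max(img) - min(img))
  vf_image(img, canvas$deg_per_px, canvas$origin)
}

#' Measure the amplitude-spectrum slope of an image
#'
#' Radially averaged log-log regression of the amplitude spectrum over the
#' central frequency decade; for a `1/f^alpha` image the slope is `-alpha`.
#'
#' @param img A [vf_image()].
#' @param f_range Frequency band (cycles/degree) used for the regression.
#' @return Fitted log-log slope.
#' @export
spectral_slope <- function(img, f_range = c(0.15, 1.5)) {
  v <- img$values - mean(img$values)
  nr <- nrow(v); nc <- ncol(v)
  a <- Mod(stats::fft(v))
  fy <- c(0:(nr %/% 2), -((nr - nr %/% 2 - 1):1)) / (nr * img$deg_per_px)
  fx <- c(0:(nc %/% 2), -((nc - nc %/% 2 - 1):1)) / (nc * img$deg_per_px)
  f <- sqrt(outer(fy^2, fx^2, "+"))
  sel <- f >= f_range[1] & f <= f_range[2]
  bins <- cut(log10(f[sel]), breaks = 24)
  mf <- tapply(log10(f[sel]), bins, mean)
  ma <- tapply(log10(a[sel]), bins, mean)
  ok <- is.finite(mf) & is.finite(ma)
  unname(stats::coef(stats::lm(ma[ok] ~ mf[ok]))[2])
}

#' Grating patch specification
#'
#' @param diameter Patch diameter in degrees (0 = blank).
#' @param sf_cpd Spatial frequency, cycles per degree.
#' @param orientation Radians.
#' @param contrast Michelson contrast in `[0, 1]`.
#' @param phase_deg Carrier phase at the patch center; 90 centers a
#'   luminance peak on the probe location.
#' @param center Patch center `c(x, y)` in degrees.
#' @param background Background gray level.
#' @return List of class `grating_patch_spec`.
#' @export
grating_patch_spec <- function(diameter, sf_cpd = 0.5, orientation = 0,
                               contrast = 0.9, phase_deg = 0,
                               center = c(-14, 0), background = 0.5) {
  stopifnot(diameter >= 0, sf_cpd > 0, contrast >= 0, contrast <= 1,
            background > 0, background < 1)
  structure(list(diameter = diameter, sf_cpd = sf_cpd,
                 orientation = orientation, contrast = contrast,
                 phase_deg = phase_deg, center = center,
                 background = background),
            class = "grating_patch_spec")
}

#' Generate a circular grating patch on a gray background
#'
#' Zero-mean sinusoid windowed by a hard circular aperture; the stimulus
#' equals the background everywhere outside the patch.
#'
#' @param spec A [grating_patch_spec()].
#' @param geom A [field_geometry()].
#' @return A [vf_image()].
#' @export
generate_grating_patch <- function(spec, geom = field_geometry()) {
  canvas <- field_canvas(geom, background = spec$background)
  if (spec$diameter <= 0 || spec$contrast <= 0) return(canvas)
  xs <- vf_x(canvas); ys <- vf_y(canvas)
  px <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  py <- matrix(ys, length(ys), length(xs))
  inside <- (px - spec$center[1])^2 + (py - spec$center[2])^2 <=
    (spec$diameter / 2)^2
  carrier <- sin(2 * pi * spec$sf_cpd *
                 ((px - spec$center[1]) * cos(spec$orientation) +
                  (py - spec$center[2]) * sin(spec$orientation)) +
                 spec$phase_deg * pi / 180)
  v <- canvas$values
  v[inside] <- spec$background * (1 + spec$contrast * carrier[inside])
  vf_image(v, canvas$deg_per_px, canvas$origin)
}

#' Fixture input bundle
#'
#' The complete small-scale input set the analysis and acceptance runs use:
#' six surrogate images (three per spectral group), a 5 x 5 log-spaced beta
#' grid, a ~1.3%-scale network geometry (about 3,900 neurons over the five
#' groups), and per-ring ASF parameters for the natural curve and both
#' artificial variants.  Everything regenerates bit-identically from the
#' seed.
#'
#' @param seed Integer master seed.
#' @param geom Fixture [field_geometry()] (8.2 px/degree).
#' @param scale_factor Network scale.
#' @param grid_n Beta-grid points per axis.
#' @return List of class `fixture_bundle`.
#' @export
fixture_bundle <- function(seed = 1L, geom = field_geometry(px_per_deg = 8.2),
                           scale_factor = 0.0129, grid_n = 5) {
  image_specs <- c(lapply(1:3, function(i) surrogate_image_spec(alpha = 1.4)),
                   lapply(1:3, function(i) surrogate_image_spec(alpha = 0.9)))
  names(image_specs) <- c(paste0("low", 1:3), paste0("mixed", 1:3))
  images <- lapply(seq_along(image_specs), function(i)
    generate_surrogate(image_specs[[i]], seed = seed * 131L + i, geom = geom))
  names(images) <- names(image_specs)
  bank_cfg <- gabor_bank_config(pixels_per_5deg = round(5 * geom$px_per_deg))
  regression <- asf_regression()
  ring_params <- fit_ring_params(regression)
  variants <- list(
    natural = ring_params,
    no_suppression = lapply(ring_params, make_variant_asf,
                            factor_c = 4, factor_s = 0.25),
    strong_suppression = lapply(ring_params, make_variant_asf,
                                factor_c = 0.25, factor_s = 4))
  structure(list(seed = seed, geom = geom, scale_factor = scale_factor,
                 image_specs = image_specs, images = images,
                 bank_config = bank_cfg, regression = regression,
                 asf_variants = variants, grid = beta_grid(grid_n),
                 connectivity = connectivity_spec(), config = sim_config()),
            class = "fixture_bundle")
}

#' Write the fixture specification (not the pixel data) as YAML
#'
#' Serializes the reproducible description of a fixture bundle — seed,
#' geometry, image specs, beta grid, connectivity table, simulation
#' parameters — so a run's provenance can be stored alongside its outputs.
#'
#' @param bundle A [fixture_bundle()].
#' @param path Output file.
#' @export
write_bundle_config <- function(bundle, path) {
  cfg <- list(
    seed = bundle$seed,
    geometry = list(ecc_range = bundle$geom$ecc_range,
                    px_per_deg = bundle$geom$px_per_deg,
                    map = unclass(bundle$geom$map)),
    scale_factor = bundle$scale_factor,
    reference_counts = as.list(reference_counts()),
    images = lapply(bundle$image_specs, unclass),
    gabor_bank = unclass(bundle$bank_config),
    asf_regression = unclass(bundle$regression),
    beta_grid = list(n = sqrt(nrow(bundle$grid)), ranges = beta_ranges()),
    connectivity = as.list(as.data.frame(bundle$connectivity)),
    simulation = unclass(bundle$config))
  yaml::write_yaml(cfg, path)
  invisible(path)
}
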