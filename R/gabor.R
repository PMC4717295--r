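# Broad-band contrast energy via a fixed Gabor filter bank.
#
# Five spatial frequencies (1, 2, 4, 8, 16 cycles per 5 degrees of visual
# field), eight orientations, and two phases (0/90 degrees) give 80 filters.
# The 0/90 pair at each (frequency, orientation) forms a quadrature pair whose
# pooled squared response is the local contrast energy in that band,
# independent of the phase of the underlying luminance pattern.

#' Gabor bank configuration
#'
#' @param frequencies Spatial frequencies in cycles per 5 degrees of field,
#'   strictly increasing.
#' @param n_orientations Number of orientations, evenly spaced over
#'   `[0, 180)` degrees.
#' @param phase_offsets Phases in degrees (the default quadrature pair).
#' @param pixels_per_5deg Pixels covering 5 degrees of visual field.
#' @param bandwidth Envelope width as a fraction of the wavelength
#'   (`sigma = bandwidth * lambda`; 0.56 gives a bandwidth of about one
#'   octave).
#' @param energy_mode `"quadrature"` pools the squared 0/90 responses per
#'   (frequency, orientation); `"rectified"` sums absolute responses instead.
#' @param norm_mode Per-filter normalization of the response field before
#'   summation: `"max"` divides by the field's maximum, `"l2"` by its root
#'   mean square.
#' @return Object of class `gabor_bank_config`.
#' @export
gabor_bank_config <- function(frequencies = c(1, 2, 4, 8, 16),
                              n_orientations = 8,
                              phase_offsets = c(0, 90),
                              pixels_per_5deg = 82,
                              bandwidth = 0.56,
                              energy_mode = c("quadrature", "rectified"),
                              norm_mode = c("max", "l2")) {
  stopifnot(all(diff(frequencies) > 0), all(frequencies > 0),
            n_orientations >= 1, pixels_per_5deg > 0, bandwidth > 0)
  structure(list(frequencies = frequencies,
                 n_orientations = as.integer(n_orientations),
                 phase_offsets = phase_offsets,
                 pixels_per_5deg = pixels_per_5deg,
                 bandwidth = bandwidth,
                 energy_mode = match.arg(energy_mode),
                 norm_mode = match.arg(norm_mode)),
            class = "gabor_bank_config")
}

gabor_kernel <- function(lambda_px, theta, phase_deg, bandwidth) {
  sigma <- bandwidth * lambda_px
  half <- ceiling(2.5 * sigma)
  g <- seq(-half, half)
  xx <- matrix(g, 2 * half + 1, 2 * half + 1, byrow = TRUE)   # column offset
  yy <- matrix(g, 2 * half + 1, 2 * half + 1)                 # row offset
  env <- exp(-(xx^2 + yy^2) / (2 * sigma^2))
  carrier <- cos(2 * pi * (xx * cos(theta) + yy * sin(theta)) / lambda_px +
                 phase_deg * pi / 180)
  k <- env * carrier
  k <- k - env * (sum(k) / sum(env))   # remove DC while keeping locality
  k / sqrt(sum(k^2))
}

#' Build the Gabor filter bank
#'
#' @param config A [gabor_bank_config()].
#' @return Object of class `gabor_bank`: a list of zero-DC, unit-norm kernels
#'   with a `meta` data frame (frequency, orientation, phase per kernel).
#' @export
build_gabor_bank <- function(config = gabor_bank_config()) {
  thetas <- seq(0, pi, length.out = config$n_orientations + 1)[-(config$n_orientations + 1)]
  meta <- expand.grid(phase = config$phase_offsets,
                      orientation = thetas,
                      frequency = config$frequencies,
                      KEEP.OUT.ATTRS = FALSE)[, 3:1]
  kernels <- lapply(seq_len(nrow(meta)), function(i) {
    gabor_kernel(config$pixels_per_5deg / meta$frequency[i],
                 meta$orientation[i], meta$phase[i], config$bandwidth)
  })
  structure(list(kernels = kernels, meta = meta, config = config),
            class = "gabor_bank")
}

#' @export
print.gabor_bank <- function(x, ...) {
  cat(sprintf("Gabor bank: %d filters (%d freq x %d orient x %d phases), %g px / 5 deg\n",
              length(x$kernels), length(x$config$frequencies),
              x$config$n_orientations, length(x$config$phase_offsets),
              x$config$pixels_per_5deg))
  invisible(x)
}

# band energies: list of (frequency, orientation) energy fields, raw scale
band_energies <- function(img, bank) {
  cfg <- bank$config
  pairs <- unique(bank$meta[, c("frequency", "orientation")])
  lapply(seq_len(nrow(pairs)), function(i) {
    sel <- which(bank$meta$frequency == pairs$frequency[i] &
                 bank$meta$orientation == pairs$orientation[i])
    resp <- lapply(sel, function(k) conv2_reflect(img$values, bank$kernels[[k]]))
    e <- if (cfg$energy_mode == "quadrature")
      Reduce(`+`, lapply(resp, function(r) r^2))
    else
      Reduce(`+`, lapply(resp, abs))
    list(frequency = pairs$frequency[i], orientation = pairs$orientation[i],
         energy = e)
  })
}

#' Contrast energy image
#'
#' Convolves the image with every filter in the bank, pools the quadrature
#' pair per (frequency, orientation) into a band energy, normalizes each band
#' by its own maximum (or RMS), and sums the normalized bands into a single
#' non-negative contrast-energy field carrying the image geometry.
#'
#' @param img A [vf_image()] grayscale image.
#' @param bank A [build_gabor_bank()] bank whose `pixels_per_5deg` matches the
#'   image resolution.
#' @return A `vf_image` of non-negative contrast energy.
#' @export
contrast_energy_image <- function(img, bank = build_gabor_bank()) {
  stopifnot(inherits(img, "vf_image"))
  if (any(!is.finite(img$values))) stop("image contains non-finite values")
  bands <- band_energies(img, bank)
  norm <- function(e) {
    s <- if (bank$config$norm_mode == "max") max(e) else sqrt(mean(e^2))
    if (s <= 1e-12 * (1 + max(abs(e)))) e * 0 else e / s
  }
  ce <- Reduce(`+`, lapply(bands, function(b) norm(b$energy)))
  ce[ce < 0] <- 0   # rectified mode can leave tiny negative round-off
  vf_image(ce, img$deg_per_px, img$origin)
}

#' Spatial-frequency signature of an image
#'
#' Sums the raw (pre-normalization) band energies over space and orientation
#' into one value per bank frequency, normalized to sum to 1.  A degenerate
#' (all-zero) image yields a uniform signature flagged with
#' `attr(, "degenerate")`.
#'
#' @inheritParams contrast_energy_image
#' @return Named numeric vector of length `length(frequencies)` summing to 1.
#' @export
frequency_signature <- function(img, bank = build_gabor_bank()) {
  bands <- band_energies(img, bank)
  freqs <- bank$config$frequencies
  tot <- vapply(freqs, function(f) {
    sum(vapply(bands, function(b) if (b$frequency == f) sum(b$energy) else 0,
               numeric(1)))
  }, numeric(1))
  names(tot) <- paste0("f", freqs)
  # a constant image leaves only round-off in the zero-DC filter responses
  if (sum(tot) <= 1e-16 * prod(dim(img$values))) {
    out <- rep(1 / length(tot), length(tot))
    names(out) <- names(tot)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- tot / sum(tot)
  attr(out, "degenerate") <- FALSE
  out
}
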